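#' Estimate task-engagement and task-performance probabilities
#'
#' Engagement is the probability of any response initiation (correct or
#' failed attempt); performance is the probability of a correct response
#' only, so performance never exceeds engagement. The default estimator is
#' a centered sliding window of `n_trials` trials evaluated on a regular
#' 1-s grid, with Wilson 95% confidence bounds; a causal
#' exponentially-weighted variant is available via `method = "ewma"`.
#'
#' @param trials data frame with `start_s` (strictly increasing) and
#'   `outcome` in `correct`, `failed_attempt`, `no_response`.
#' @param n_trials sliding-window width in trials (default 20).
#' @param grid_dt_s grid resolution in seconds (default 1, aligning with
#'   the state-space module).
#' @param t_end_s grid end; defaults to the last trial time.
#' @param method `"sliding"` (centered window) or `"ewma"` (causal,
#'   exponential weights with a half-life of `n_trials / 2` trials).
#' @param ci_level Wilson confidence level for the sliding estimator.
#' @return data frame of class `probability_series`: `times_s`,
#'   `p_engage`, `p_perform`, `engage_lo`, `engage_hi`, `perform_lo`,
#'   `perform_hi`, with attribute `window_s` (median time spanned by the
#'   estimator window).
#' @export
estimate_probabilities <- function(trials, n_trials = 20, grid_dt_s = 1,
                                   t_end_s = NULL, method = c("sliding", "ewma"),
                                   ci_level = 0.95) {
  method <- match.arg(method)
  if (is.null(trials) || nrow(trials) < 1L) stop("trial log is empty")
  if (is.unsorted(trials$start_s, strictly = TRUE)) {
    stop("trial start times must be strictly increasing")
  }
  n <- nrow(trials)
  eng <- trials$outcome != "no_response"
  cor_ <- trials$outcome == "correct"
  if (is.null(t_end_s)) t_end_s <- max(trials$start_s)
  times <- seq(0, t_end_s, by = grid_dt_s)
  k <- findInterval(times, trials$start_s)

  if (method == "sliding") {
    half_lo <- floor(n_trials / 2) - 1L
    half_hi <- n_trials - 1L - half_lo
    lo <- pmin(pmax(k - half_lo, 1L), max(n - n_trials + 1L, 1L))
    hi <- pmin(lo + n_trials - 1L, n)
    ce <- c(0, cumsum(eng)); cc <- c(0, cumsum(cor_))
    m <- hi - lo + 1L
    x_eng <- ce[hi + 1L] - ce[lo]
    x_cor <- cc[hi + 1L] - cc[lo]
    p_eng <- x_eng / m
    p_cor <- x_cor / m
    wil <- function(x, m) {
      z <- stats::qnorm(1 - (1 - ci_level) / 2)
      ctr <- (x + z^2 / 2) / (m + z^2)
      hw <- z * sqrt(x * (m - x) / m + z^2 / 4) / (m + z^2)
      list(lo = pmax(ctr - hw, 0), hi = pmin(ctr + hw, 1))
    }
    we <- wil(x_eng, m); wc <- wil(x_cor, m)
    ## typical time span of the window, used as the endpoint error scale
    span <- stats::median(trials$start_s[hi] - trials$start_s[lo])
    out <- data.frame(times_s = times, p_engage = p_eng, p_perform = p_cor,
                      engage_lo = we$lo, engage_hi = we$hi,
                      perform_lo = wc$lo, perform_hi = wc$hi)
  } else {
    half_life <- n_trials / 2
    lam <- log(2) / half_life
    p_eng <- p_cor <- numeric(length(times))
    for (i in seq_along(times)) {
      idx <- seq_len(max(k[i], 1L))
      w <- exp(-lam * (max(k[i], 1L) - idx))
      w <- w / sum(w)
      p_eng[i] <- sum(w * eng[idx])
      p_cor[i] <- sum(w * cor_[idx])
    }
    span <- 2 * half_life * stats::median(diff(trials$start_s))
    out <- data.frame(times_s = times, p_engage = p_eng, p_perform = p_cor,
                      engage_lo = NA_real_, engage_hi = NA_real_,
                      perform_lo = NA_real_, perform_hi = NA_real_)
  }
  attr(out, "window_s") <- span
  class(out) <- c("probability_series", class(out))
  out
}

#' Endpoint detection configuration
#'
#' @param loc_threshold engagement threshold below which LOC is declared.
#' @param roc_threshold engagement threshold above which ROC is declared.
#' @param ropap_threshold performance threshold for ROPAP.
#' @param ropap_hold_s time performance must stay above `ropap_threshold`.
#' @param anesthetic_start_s earliest time LOC may be declared.
#' @return list of class `endpoint_config`.
#' @export
endpoint_config <- function(loc_threshold = 0.3, roc_threshold = 0.3,
                            ropap_threshold = 0.9, ropap_hold_s = 180,
                            anesthetic_start_s = 0) {
  th <- c(loc_threshold, roc_threshold, ropap_threshold)
  if (any(th <= 0 | th >= 1)) stop("thresholds must lie in (0, 1)")
  if (ropap_hold_s < 0) stop("ropap_hold_s must be >= 0")
  structure(list(loc_threshold = loc_threshold, roc_threshold = roc_threshold,
                 ropap_threshold = ropap_threshold, ropap_hold_s = ropap_hold_s,
                 anesthetic_start_s = anesthetic_start_s),
            class = "endpoint_config")
}

#' Detect LOC, ROC and ROPAP
#'
#' LOC is the first grid time (after the anesthetic start) at which the
#' engagement probability falls below `loc_threshold` coming from at or
#' above it; ROC is the first time after LOC at which engagement rises
#' above `roc_threshold` coming from at or below it (values exactly at
#' threshold never trigger). ROPAP is the start of the first run after LOC
#' during which performance exceeds `ropap_threshold` for at least
#' `ropap_hold_s` seconds; a single sub-threshold grid point resets the
#' hold. Missing endpoints are returned as `NA`, never fabricated.
#'
#' @param probs a [estimate_probabilities()] result.
#' @param cfg an [endpoint_config()].
#' @return list of class `endpoint_set` with `loc_s`, `roc_s`, `ropap_s`.
#' @export
detect_endpoints <- function(probs, cfg = endpoint_config()) {
  stopifnot(inherits(probs, "probability_series"),
            inherits(cfg, "endpoint_config"))
  t <- probs$times_s
  pe <- probs$p_engage
  pp <- probs$p_perform
  after <- which(t >= cfg$anesthetic_start_s)

  loc_s <- NA_real_
  for (i in after) {
    if (i > 1L && pe[i] < cfg$loc_threshold && pe[i - 1L] >= cfg$loc_threshold) {
      loc_s <- t[i]; break
    }
  }
  roc_s <- NA_real_
  if (!is.na(loc_s)) {
    for (i in which(t > loc_s)) {
      if (pe[i] > cfg$roc_threshold && pe[i - 1L] <= cfg$roc_threshold) {
        roc_s <- t[i]; break
      }
    }
  }
  ropap_s <- NA_real_
  if (!is.na(loc_s)) {
    above <- pp > cfg$ropap_threshold & t > loc_s
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dt <- if (length(t) > 1L) t[2L] - t[1L] else 1
    need <- ceiling(cfg$ropap_hold_s / dt) + 1L
    hit <- which(r$values & r$lengths >= need)
    if (length(hit) > 0L) ropap_s <- t[starts[hit[1L]]]
  }
  structure(list(loc_s = loc_s, roc_s = roc_s, ropap_s = ropap_s),
            class = "endpoint_set")
}

#' @export
print.endpoint_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f s", v)
  cat("Behavioral endpoints:\n",
      "  LOC:   ", fmt(x$loc_s), "\n",
      "  ROC:   ", fmt(x$roc_s), "\n",
      "  ROPAP: ", fmt(x$ropap_s), "\n", sep = "")
  invisible(x)
}
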