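#' Bonferroni-corrected pairwise threshold
#'
#' With `k` conditions the post hoc family has `choose(k, 2)` pairwise
#' comparisons and the corrected threshold is `0.05 / choose(k, 2)`
#' (0.0083 for 4 conditions, 0.017 for 3).
#'
#' @param n_conditions number of conditions.
#' @param alpha family-wise level (default 0.05).
#' @return corrected per-comparison threshold.
#' @export
bonferroni_threshold <- function(n_conditions, alpha = 0.05) {
  stopifnot(n_conditions >= 2L)
  alpha / choose(n_conditions, 2L)
}

## Greenhouse-Geisser epsilon from the units x conditions matrix
gg_epsilon <- function(X) {
  k <- ncol(X)
  S <- stats::cov(X)
  ## double-centered covariance
  rm_ <- rowMeans(S); gm <- mean(S)
  D <- S - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + gm
  tr <- sum(diag(D))
  eps <- tr^2 / ((k - 1) * sum(D^2))
  min(max(eps, 1 / (k - 1)), 1)
}

## one-way repeated-measures ANOVA with Greenhouse-Geisser correction
rm_anova_gg <- function(X) {
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  ss_cond <- n * sum((colMeans(X) - grand)^2)
  ss_subj <- k * sum((rowMeans(X) - grand)^2)
  ss_tot <- sum((X - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  eps <- gg_epsilon(X)
  list(statistic = f,
       p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
       p = stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE),
       epsilon = eps)
}

#' Frequency-wise condition comparison
#'
#' For every frequency bin, compares conditions across units (channels or
#' channel pairs) in a complete within-subject layout: a repeated-measures
#' ANOVA with Greenhouse-Geisser-corrected p (parametric), or Friedman's
#' test (nonparametric), followed by pairwise post hoc comparisons at the
#' Bonferroni-corrected threshold `0.05 / choose(k, 2)`. `mode = "auto"`
#' picks the parametric branch only when a Kolmogorov-Smirnov normality
#' check passes in every condition (pooled over frequencies).
#'
#' @param data numeric array `units x conditions x frequencies` (power or
#'   coherence values), with dimnames on the condition margin encouraged.
#' @param freq_hz optional frequency axis (length = 3rd dimension).
#' @param mode `"parametric"`, `"nonparametric"` or `"auto"`.
#' @param alpha family-wise level (default 0.05).
#' @param paired_posthoc paired (within-unit) post hoc contrasts when TRUE
#'   (default), unpaired otherwise.
#' @return list of class `frequencywise_test`: `omnibus` (data frame per
#'   frequency: statistic, p, significant), `posthoc` (per frequency and
#'   condition pair), `mode_used`, `corrected_threshold`, `family_size`.
#' @export
frequencywise_condition_test <- function(data, freq_hz = NULL,
                                         mode = c("auto", "parametric",
                                                  "nonparametric"),
                                         alpha = 0.05, paired_posthoc = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(dim(data)) == 3L)
  if (anyNA(data)) stop("within-subject layout must be complete (no missing cells)")
  n_u <- dim(data)[1L]; k <- dim(data)[2L]; n_f <- dim(data)[3L]
  if (k < 2L || n_u < 3L) stop("need >= 2 conditions and >= 3 units")
  if (is.null(freq_hz)) freq_hz <- seq_len(n_f)
  cond_names <- dimnames(data)[[2L]]
  if (is.null(cond_names)) cond_names <- paste0("cond", seq_len(k))

  if (mode == "auto") {
    normal <- all(vapply(seq_len(k), function(j) {
      v <- as.numeric(data[, j, ])
      v <- v[seq_len(min(length(v), 5000L))]
      if (stats::sd(v) == 0) return(FALSE)
      ks_normality(v)$p > 0.05
    }, logical(1)))
    mode <- if (normal) "parametric" else "nonparametric"
  }

  thr <- bonferroni_threshold(k, alpha)
  pairs <- utils::combn(k, 2L)
  omni <- data.frame(freq_hz = freq_hz, statistic = NA_real_, p = NA_real_,
                     epsilon = NA_real_, significant = FALSE)
  ph <- list()
  for (f in seq_len(n_f)) {
    X <- data[, , f]
    if (mode == "parametric") {
      res <- rm_anova_gg(X)
      omni$statistic[f] <- res$statistic
      omni$p[f] <- res$p
      omni$epsilon[f] <- res$epsilon
    } else {
      fr <- stats::friedman.test(X)
      omni$statistic[f] <- unname(fr$statistic)
      omni$p[f] <- fr$p.value
    }
    omni$significant[f] <- omni$p[f] < alpha
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      p_ab <- if (mode == "parametric") {
        stats::t.test(X[, a], X[, b], paired = paired_posthoc)$p.value
      } else {
        suppressWarnings(
          stats::wilcox.test(X[, a], X[, b], paired = paired_posthoc,
                             exact = FALSE)$p.value)
      }
      ph[[length(ph) + 1L]] <- data.frame(
        freq_hz = freq_hz[f], cond_a = cond_names[a], cond_b = cond_names[b],
        p = p_ab, significant = omni$significant[f] && p_ab < thr)
    }
  }
  structure(list(omnibus = omni, posthoc = do.call(rbind, ph),
                 mode_used = mode, corrected_threshold = thr,
                 family_size = ncol(pairs)),
            class = "frequencywise_test")
}

#' Bootstrap confidence interval
#'
#' Percentile or bias-corrected (BC) percentile bootstrap CI of a
#' statistic (default the mean).
#'
#' @param x numeric sample.
#' @param statistic function of a numeric vector (default `mean`).
#' @param level confidence level (default 0.95).
#' @param method `"percentile"` or `"bias_corrected"`.
#' @param n_boot number of resamples (default 1000; below 100 a warning is
#'   issued).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(x, statistic = mean, level = 0.95,
                         method = c("percentile", "bias_corrected"),
                         n_boot = 1000) {
  method <- match.arg(method)
  if (length(x) == 0L) stop("empty sample")
  if (n_boot < 100L) warning("n_boot < 100: interval will be unstable")
  obs <- statistic(x)
  if (length(x) < 2L || stats::sd(x) == 0) return(c(obs, obs))
  boots <- vapply(seq_len(n_boot), function(b) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  a <- (1 - level) / 2
  if (method == "percentile") {
    stats::quantile(boots, probs = c(a, 1 - a), names = FALSE)
  } else {
    frac <- mean(boots < obs)
    z0 <- stats::qnorm(pmin(pmax(frac, 1 / n_boot), 1 - 1 / n_boot))
    p_lo <- stats::pnorm(2 * z0 + stats::qnorm(a))
    p_hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
    stats::quantile(boots, probs = c(p_lo, p_hi), names = FALSE)
  }
}

#' Kolmogorov-Smirnov normality check (limiting form)
#'
#' KS statistic of the sample against a normal distribution with the
#' sample mean and SD, with the asymptotic (limiting-form) p-value. Because
#' the reference parameters are estimated from the same sample, this p is
#' conservative; the parameter-estimated Lilliefors variant is available
#' via `method = "lilliefors"`.
#'
#' @param x numeric sample (>= 8 values, non-constant).
#' @param method `"limiting"` (default) or `"lilliefors"`.
#' @return list with `statistic` (in `[0, 1]`) and `p`.
#' @export
ks_normality <- function(x, method = c("limiting", "lilliefors")) {
  method <- match.arg(method)
  if (length(x) < 8L) stop("need at least 8 samples")
  if (stats::sd(x) == 0) stop("constant sample")
  if (method == "limiting") {
    kt <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = FALSE))
    list(statistic = unname(kt$statistic), p = kt$p.value)
  } else {
    lt <- nortest::lillie.test(x)
    list(statistic = unname(lt$statistic), p = lt$p.value)
  }
}
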