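#' Spindle detection parameters
#'
#' Events are detected on the 9-17 Hz analytic envelope z-scored against a
#' baseline interval: the event spans the super-threshold run around a peak
#' (`onset_z`), must attain `peak_z` at its peak, must last between the
#' duration bounds (inclusive), and is discarded as an artifact when its
#' peak exceeds `artifact_z`.
#'
#' @param band band-pass edges in Hz.
#' @param onset_z start/end threshold (z-scores above baseline).
#' @param peak_z minimum peak threshold.
#' @param artifact_z peak amplitude above which events are rejected.
#' @param duration_ms inclusive duration gate, ms.
#' @param baseline `c(start_s, end_s)` interval whose envelope mean/SD
#'   define the z-score (typically the awake baseline).
#' @param merge_gap_ms sub-threshold gaps shorter than this are merged
#'   before the duration gate (prevents double-counting envelope ripple).
#' @param filter_order band-pass Butterworth order (zero-phase).
#' @return list of class `spindle_params`.
#' @export
spindle_params <- function(band = c(9, 17), onset_z = 4, peak_z = 6,
                           artifact_z = 15, duration_ms = c(500, 2500),
                           baseline, merge_gap_ms = 100, filter_order = 4) {
  if (!(onset_z < peak_z && peak_z < artifact_z)) {
    stop("thresholds must satisfy onset_z < peak_z < artifact_z")
  }
  if (diff(duration_ms) <= 0) stop("duration bounds must be increasing")
  stopifnot(length(baseline) == 2L, baseline[2L] > baseline[1L])
  structure(list(band = band, onset_z = onset_z, peak_z = peak_z,
                 artifact_z = artifact_z, duration_ms = duration_ms,
                 baseline = baseline, merge_gap_ms = merge_gap_ms,
                 filter_order = filter_order),
            class = "spindle_params")
}

#' Detect spindle events on one channel
#'
#' Band-pass filters the (line-noise-free) trace to 9-17 Hz, z-scores the
#' analytic envelope against the baseline interval, and extracts
#' non-overlapping events passing all gates of [spindle_params()].
#'
#' @param x numeric vector (one channel, already line-noise filtered).
#' @param fs sampling rate in Hz.
#' @param params a [spindle_params()].
#' @return data frame with `start_s`, `end_s`, `peak_s`, `peak_z`,
#'   `duration_ms`, sorted and non-overlapping.
#' @export
detect_spindles <- function(x, fs = 1000, params) {
  stopifnot(inherits(params, "spindle_params"))
  bp <- bandpass_filter(x, fs, params$band[1L], params$band[2L],
                        order = params$filter_order)
  env <- Mod(analytic_signal(bp))
  bi <- (floor(params$baseline[1L] * fs) + 1L):floor(params$baseline[2L] * fs)
  if (bi[1L] < 1L || bi[length(bi)] > length(x)) {
    stop("baseline interval lies outside the recording")
  }
  mu <- mean(env[bi]); sd_ <- stats::sd(env[bi])
  if (sd_ == 0) stop("degenerate baseline: zero envelope variance")
  z <- (env - mu) / sd_

  above <- z >= params$onset_z
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty_spindle_df())
  ## merge runs separated by short sub-threshold gaps
  gap_n <- params$merge_gap_ms / 1000 * fs
  if (nrow(runs) > 1L) {
    keep_start <- runs$start[1L]; merged <- NULL
    cur_end <- runs$end[1L]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - cur_end - 1L < gap_n) {
        cur_end <- runs$end[i]
      } else {
        merged <- rbind(merged, c(keep_start, cur_end))
        keep_start <- runs$start[i]; cur_end <- runs$end[i]
      }
    }
    merged <- rbind(merged, c(keep_start, cur_end))
    runs <- data.frame(start = merged[, 1L], end = merged[, 2L])
  }
  dur_ms <- (runs$end - runs$start + 1L) / fs * 1000
  pk_idx <- mapply(function(a, b) a - 1L + which.max(z[a:b]),
                   runs$start, runs$end)
  pk_z <- z[pk_idx]
  ok <- dur_ms >= params$duration_ms[1L] & dur_ms <= params$duration_ms[2L] &
    pk_z >= params$peak_z & pk_z <= params$artifact_z
  if (!any(ok)) return(empty_spindle_df())
  data.frame(start_s = (runs$start[ok] - 1L) / fs,
             end_s = runs$end[ok] / fs,
             peak_s = (pk_idx[ok] - 0.5) / fs,
             peak_z = pk_z[ok],
             duration_ms = dur_ms[ok])
}

empty_spindle_df <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), peak_s = numeric(0),
             peak_z = numeric(0), duration_ms = numeric(0))
}

## ---- empirical mode decomposition (sifting with spline envelopes) ----

local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  ## collapse flat stretches
  s[s == 0] <- NA
  s <- zoo_fill(s)
  chg <- diff(s)
  maxima <- which(chg < 0) + 1L
  minima <- which(chg > 0) + 1L
  list(max = maxima, min = minima)
}

## forward-fill NA (tiny substitute to avoid a dependency for one call)
zoo_fill <- function(v) {
  idx <- cumsum(!is.na(v))
  idx[idx == 0L] <- 1L
  v_no_na <- v[!is.na(v)]
  if (length(v_no_na) == 0L) return(rep(1, length(v)))
  v_no_na[idx]
}

## one IMF extraction by sifting; returns NULL when x is monotone-ish
sift_imf <- function(x, max_sift = 50, sd_stop = 0.3) {
  n <- length(x)
  h <- x
  for (it in seq_len(max_sift)) {
    ex <- local_extrema(h)
    if (length(ex$max) < 2L || length(ex$min) < 2L) {
      return(if (it == 1L) NULL else h)
    }
    ## mirror end extrema to tame edge splines
    mx_i <- c(1L, ex$max, n); mx_v <- c(h[ex$max[1L]], h[ex$max], h[ex$max[length(ex$max)]])
    mn_i <- c(1L, ex$min, n); mn_v <- c(h[ex$min[1L]], h[ex$min], h[ex$min[length(ex$min)]])
    upper <- stats::spline(mx_i, mx_v, xout = seq_len(n), method = "natural")$y
    lower <- stats::spline(mn_i, mn_v, xout = seq_len(n), method = "natural")$y
    m <- (upper + lower) / 2
    h_new <- h - m
    crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (crit < sd_stop^2) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Standard sifting with natural cubic-spline envelopes through local
#' extrema (Cauchy-type stopping criterion), used by the Hilbert-Huang
#' peak-frequency estimator.
#'
#' @param x numeric vector.
#' @param max_imfs maximum number of intrinsic mode functions.
#' @return matrix, one IMF per column; the residual is not included.
#' @export
emd_decompose <- function(x, max_imfs = 8) {
  imfs <- NULL
  resid <- x
  for (i in seq_len(max_imfs)) {
    imf <- sift_imf(resid)
    if (is.null(imf)) break
    imfs <- cbind(imfs, imf)
    resid <- resid - imf
    ex <- local_extrema(resid)
    if (length(ex$max) + length(ex$min) < 4L) break
  }
  imfs
}

#' Spindle peak frequency (Hilbert-Huang)
#'
#' Decomposes the event's raw signal segment into intrinsic mode functions,
#' forms the Hilbert spectrum (amplitude-squared-weighted instantaneous
#' frequency over time for every IMF), and reports the frequency bin of
#' maximum marginal power within the analysis band. A plain multitaper-PSD
#' argmax fallback (`method = "psd"`) is provided for cross-checking.
#'
#' @param segment numeric vector covering the event (raw signal).
#' @param fs sampling rate in Hz.
#' @param band frequency band searched for the peak, Hz.
#' @param method `"hht"` (default) or `"psd"`.
#' @param bin_hz marginal-spectrum bin width for the HHT method.
#' @return peak frequency in Hz.
#' @export
spindle_peak_frequency <- function(segment, fs = 1000, band = c(9, 17),
                                   method = c("hht", "psd"), bin_hz = 0.5) {
  method <- match.arg(method)
  if (length(segment) < 8L) stop("segment too short for the event")
  if (method == "psd") {
    n <- length(segment)
    nw <- 2; k <- 3
    tp <- dpss_tapers(n, nw, k)
    nfft <- 2^ceiling(log2(max(n, 4 * fs)))  # zero-pad for fine resolution
    freq <- (0:(nfft - 1L)) * fs / nfft
    keep <- freq >= band[1L] & freq <= band[2L]
    pw <- numeric(sum(keep))
    for (j in seq_len(k)) {
      sp <- Mod(stats::fft(c(segment * tp[, j], numeric(nfft - n))))^2
      pw <- pw + sp[keep]
    }
    return(freq[keep][which.max(pw)])
  }
  imfs <- emd_decompose(segment)
  if (is.null(imfs)) stop("no intrinsic mode could be extracted")
  edges <- seq(0, fs / 2, by = bin_hz)
  marg <- numeric(length(edges) - 1L)
  for (j in seq_len(ncol(imfs))) {
    a <- analytic_signal(imfs[, j])
    amp2 <- Mod(a)^2
    ph <- Arg(a)
    finst <- c(NA, diff(unwrap_phase(ph))) * fs / (2 * pi)
    ok <- !is.na(finst) & finst > 0 & finst < fs / 2
    if (!any(ok)) next
    bin <- findInterval(finst[ok], edges, rightmost.closed = TRUE)
    marg <- marg + as.numeric(tapply(amp2[ok], factor(bin, levels = seq_along(marg)),
                                     sum, default = 0))
  }
  ctr <- edges[-length(edges)] + bin_hz / 2
  sel <- ctr >= band[1L] & ctr <= band[2L]
  if (!any(sel) || all(marg[sel] == 0)) stop("no power inside the analysis band")
  ctr[sel][which.max(marg[sel])]
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

#' Summarize spindle events per behavioral period
#'
#' Computes density (events per minute, per channel), pooled durations and
#' peak frequencies per period, and two-sided unpaired t-tests between all
#' period pairs flagged at the given significance threshold.
#'
#' @param events data frame of events with at least `peak_s`,
#'   `duration_ms`, optionally `peak_freq_hz` and `channel`.
#' @param periods data frame with `label`, `start_s`, `end_s`
#'   (non-overlapping).
#' @param alpha significance threshold for the pairwise t-tests
#'   (default 0.01).
#' @return list with `stats` (per period: `label`, `minutes`, `n_events`,
#'   `density_per_min`, `mean_duration_ms`, `mean_peak_freq_hz`),
#'   `samples` (per-period duration / peak-frequency samples) and
#'   `comparisons` (pairwise t-tests on density per channel, duration and
#'   peak frequency).
#' @export
summarize_spindles <- function(events, periods, alpha = 0.01) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(periods)))
  if (any(periods$end_s <= periods$start_s)) stop("zero-length period")
  ord <- order(periods$start_s)
  po <- periods[ord, ]
  if (nrow(po) > 1L && any(po$start_s[-1L] < po$end_s[-nrow(po)])) {
    stop("periods must be non-overlapping")
  }
  has_chan <- "channel" %in% names(events)
  per_stats <- list(); samples <- list(); dens_samples <- list()
  for (i in seq_len(nrow(periods))) {
    p <- periods[i, ]
    minutes <- (p$end_s - p$start_s) / 60
    inp <- events$peak_s >= p$start_s & events$peak_s < p$end_s
    ev <- events[inp, , drop = FALSE]
    if (has_chan) {
      chans <- unique(events$channel)
      dens <- vapply(chans, function(ch) sum(ev$channel == ch) / minutes,
                     numeric(1))
    } else {
      dens <- nrow(ev) / minutes
    }
    per_stats[[i]] <- data.frame(
      label = p$label, minutes = minutes, n_events = nrow(ev),
      density_per_min = mean(dens),
      mean_duration_ms = if (nrow(ev) > 0) mean(ev$duration_ms) else NA_real_,
      mean_peak_freq_hz = if (nrow(ev) > 0 && "peak_freq_hz" %in% names(ev))
        mean(ev$peak_freq_hz) else NA_real_)
    samples[[p$label]] <- ev
    dens_samples[[p$label]] <- dens
  }
  comparisons <- NULL
  labs <- periods$label
  if (length(labs) >= 2L) {
    cmb <- utils::combn(labs, 2L)
    rows <- lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      one <- function(metric, xa, xb) {
        if (length(xa) < 2L || length(xb) < 2L ||
            (stats::sd(xa) == 0 && stats::sd(xb) == 0)) {
          tt <- list(statistic = c(t = 0), p.value = 1)
          if (length(xa) >= 2L && identical(xa, xb)) tt$p.value <- 1
          return(data.frame(period_a = a, period_b = b, metric = metric,
                            t = unname(tt$statistic), p = tt$p.value,
                            significant = FALSE))
        }
        tt <- stats::t.test(xa, xb, var.equal = FALSE)
        data.frame(period_a = a, period_b = b, metric = metric,
                   t = unname(tt$statistic), p = tt$p.value,
                   significant = tt$p.value < alpha)
      }
      rbind(
        one("density_per_min", dens_samples[[a]], dens_samples[[b]]),
        one("duration_ms", samples[[a]]$duration_ms, samples[[b]]$duration_ms),
        if ("peak_freq_hz" %in% names(events))
          one("peak_freq_hz", samples[[a]]$peak_freq_hz,
              samples[[b]]$peak_freq_hz))
    })
    comparisons <- do.call(rbind, rows)
  }
  list(stats = do.call(rbind, per_stats), samples = samples,
       comparisons = comparisons)
}
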