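#' Spectral analysis configuration
#'
#' Defaults follow the analysis conventions for these recordings: 30-s
#' non-overlapping spectrogram windows with 3 tapers, 2-s non-overlapping
#' coherence windows, 1-min condition epochs analyzed by Welch's method with
#' percentile 95% confidence intervals across channels.
#'
#' @param spectrogram_window_s spectrogram window length (non-overlapping).
#' @param n_tapers number of Slepian tapers.
#' @param time_bandwidth taper time-bandwidth product NW.
#' @param coherence_window_s coherence window length (non-overlapping).
#' @param epoch_s condition epoch length for summary spectra.
#' @param welch_seg_s,welch_overlap Welch segment length and overlap.
#' @param ci_level confidence level for epoch CIs.
#' @param max_freq_hz highest frequency retained in outputs.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(spectrogram_window_s = 30, n_tapers = 3,
                            time_bandwidth = 2, coherence_window_s = 2,
                            epoch_s = 60, welch_seg_s = 2,
                            welch_overlap = 0.5, ci_level = 0.95,
                            max_freq_hz = 120) {
  stopifnot(spectrogram_window_s > 0, n_tapers >= 1, coherence_window_s > 0,
            epoch_s > 0, ci_level > 0, ci_level < 1)
  structure(list(spectrogram_window_s = spectrogram_window_s,
                 n_tapers = n_tapers, time_bandwidth = time_bandwidth,
                 coherence_window_s = coherence_window_s, epoch_s = epoch_s,
                 welch_seg_s = welch_seg_s, welch_overlap = welch_overlap,
                 ci_level = ci_level, max_freq_hz = max_freq_hz),
            class = "spectral_config")
}

#' Frequency-band definitions
#'
#' The canonical analysis bands: slow-delta 0.5-4 Hz, alpha 8-12 Hz, awake
#' beta 18-25 Hz (S1, S2) or 26-34 Hz (PMv), and the spindle band 9-17 Hz.
#'
#' @return data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("slow_delta", "alpha", "beta_s1s2", "beta_pmv", "spindle_band"),
    lo_hz = c(0.5, 8, 18, 26, 9),
    hi_hz = c(4, 12, 25, 34, 17),
    stringsAsFactors = FALSE
  )
}

#' Remove power-line noise
#'
#' Zero-phase band-stop filtering: a 2nd-order Butterworth notch run forward
#' and backward (`signal::filtfilt`), so the output has no phase distortion
#' and the same length as the input.
#'
#' @param x numeric vector, or matrix with one channel per column.
#' @param fs sampling rate in Hz.
#' @param notch_hz line frequency (default 60).
#' @param width_hz total stop-band width (default 2, i.e. 59-61 Hz).
#' @return filtered signal, same shape as `x`.
#' @export
remove_line_noise <- function(x, fs = 1000, notch_hz = 60, width_hz = 2) {
  if (notch_hz + width_hz / 2 >= fs / 2) {
    stop("notch frequency must lie below the Nyquist frequency")
  }
  bf <- signal::butter(2, c(notch_hz - width_hz / 2, notch_hz + width_hz / 2) /
                            (fs / 2), type = "stop")
  if (is.matrix(x)) {
    apply(x, 2L, function(col) signal::filtfilt(bf, col))
  } else {
    signal::filtfilt(bf, x)
  }
}

## zero-phase Butterworth band-pass (order refers to the one-pass design)
bandpass_filter <- function(x, fs, lo_hz, hi_hz, order = 4) {
  lo <- max(lo_hz, 0.01)
  hi <- min(hi_hz, fs / 2 * 0.999)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Multitaper spectrogram
#'
#' Power spectral density over consecutive non-overlapping windows, averaged
#' across Slepian tapers. Units are uV^2/Hz for a signal in microvolts.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @return list of class `spectrogram` with `freq_hz`, `time_bins_s`
#'   (window centers) and `power` (frequency x time matrix).
#' @export
multitaper_spectrogram <- function(x, fs = 1000, cfg = spectral_config()) {
  if (length(x) < round(cfg$spectrogram_window_s * fs)) {
    stop("signal shorter than one spectrogram window")
  }
  p <- mt_psd_windows(x, fs, cfg$spectrogram_window_s,
                      nw = cfg$time_bandwidth, k = cfg$n_tapers)
  keep <- p$freq <= cfg$max_freq_hz
  structure(list(freq_hz = p$freq[keep],
                 time_bins_s = p$time_s,
                 power = p$power[keep, , drop = FALSE]),
            class = "spectrogram")
}

#' Epoch power spectra with confidence intervals across channels
#'
#' Welch power spectral density of each channel over one epoch, summarized
#' as the channel mean with a percentile confidence interval across
#' channels.
#'
#' @param signals matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param epoch numeric `c(start_s, end_s)`; must lie inside the recording.
#' @param cfg a [spectral_config()].
#' @return list with `freq_hz`, `mean`, `lo`, `hi` (percentile CI bounds)
#'   and `per_channel` (frequency x channel matrix).
#' @export
epoch_psd_with_ci <- function(signals, fs = 1000, epoch, cfg = spectral_config()) {
  stopifnot(is.matrix(signals), length(epoch) == 2L)
  n <- nrow(signals)
  i0 <- floor(epoch[1L] * fs) + 1L
  i1 <- floor(epoch[2L] * fs)
  if (i0 < 1L || i1 > n || i1 <= i0) stop("epoch lies outside the recording")
  per <- NULL
  for (ch in seq_len(ncol(signals))) {
    w <- welch_psd(signals[i0:i1, ch], fs, cfg$welch_seg_s, cfg$welch_overlap)
    if (is.null(per)) {
      keep <- w$freq <= cfg$max_freq_hz
      per <- matrix(NA_real_, sum(keep), ncol(signals))
      freq <- w$freq[keep]
    }
    per[, ch] <- w$power[keep]
  }
  a <- (1 - cfg$ci_level) / 2
  list(freq_hz = freq,
       mean = rowMeans(per),
       lo = apply(per, 1L, stats::quantile, probs = a),
       hi = apply(per, 1L, stats::quantile, probs = 1 - a),
       per_channel = per)
}

## taper-averaged auto/cross spectra for all windows; internal
mt_cross_windows <- function(x, y, fs, window_s, nw, k) {
  Jx <- mt_tapered_fft(x, fs, window_s, nw, k)
  Jy <- mt_tapered_fft(y, fs, window_s, nw, k)
  list(freq = attr(Jx, "freq"), time_s = attr(Jx, "time_s"),
       sxx = tap_mean_mod2(Jx),
       syy = tap_mean_mod2(Jy),
       sxy = tap_mean_cross(Jx, Jy))
}

#' Channel-to-channel coherence
#'
#' Magnitude coherence per 2-s non-overlapping window (the coherogram) and,
#' optionally, a consistent epoch-averaged coherence spectrum obtained by
#' averaging auto- and cross-spectra over all windows inside the epoch
#' before normalizing.
#'
#' @param x,y equal-length numeric vectors (two channels).
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @param epoch optional `c(start_s, end_s)` for an epoch-averaged spectrum.
#' @return list of class `coherogram` with `freq_hz`, `time_bins_s`,
#'   `coherence` (frequency x time, in `[0, 1]`), and when `epoch` is given
#'   `epoch_freq_hz`/`epoch_coherence`.
#' @export
pairwise_coherence <- function(x, y, fs = 1000, cfg = spectral_config(),
                               epoch = NULL) {
  if (length(x) != length(y)) stop("signals must have equal length")
  cw <- mt_cross_windows(x, y, fs, cfg$coherence_window_s,
                         cfg$time_bandwidth, cfg$n_tapers)
  keep <- cw$freq <= cfg$max_freq_hz
  coh <- Mod(cw$sxy[keep, , drop = FALSE]) /
    sqrt(cw$sxx[keep, , drop = FALSE] * cw$syy[keep, , drop = FALSE])
  out <- list(freq_hz = cw$freq[keep], time_bins_s = cw$time_s,
              coherence = pmin(coh, 1))
  if (!is.null(epoch)) {
    inw <- cw$time_s >= epoch[1L] & cw$time_s <= epoch[2L]
    if (!any(inw)) stop("epoch contains no coherence windows")
    sxy <- rowMeans(cw$sxy[keep, inw, drop = FALSE])
    sxx <- rowMeans(cw$sxx[keep, inw, drop = FALSE])
    syy <- rowMeans(cw$syy[keep, inw, drop = FALSE])
    out$epoch_freq_hz <- cw$freq[keep]
    out$epoch_coherence <- pmin(Mod(sxy) / sqrt(sxx * syy), 1)
  }
  class(out) <- "coherogram"
  out
}

#' Enumerate within- and between-region channel pairs
#'
#' @param region_channels named list (or named integer vector of channel
#'   counts) giving the channels of each region.
#' @return list with data frames `within` (`region`, `ch1`, `ch2`) and
#'   `between` (`region1`, `region2`, `ch1`, `ch2`), plus named count
#'   vectors `within_counts` and `between_counts`. Within-region counts are
#'   `n*(n-1)/2`; between-region counts are `n1*n2`.
#' @examples
#' enumerate_channel_pairs(c(S1 = 9, S2 = 11, PMv = 10))$within_counts
#' @export
enumerate_channel_pairs <- function(region_channels) {
  if (!is.list(region_channels)) {
    region_channels <- lapply(stats::setNames(as.integer(region_channels),
                                              names(region_channels)),
                              seq_len)
  }
  regions <- names(region_channels)
  within <- do.call(rbind, lapply(regions, function(r) {
    ch <- region_channels[[r]]
    if (length(ch) < 2L) return(NULL)
    idx <- utils::combn(length(ch), 2L)
    data.frame(region = r, ch1 = ch[idx[1L, ]], ch2 = ch[idx[2L, ]],
               stringsAsFactors = FALSE)
  }))
  between <- NULL
  if (length(regions) >= 2L) {
    combos <- utils::combn(regions, 2L)
    between <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      r1 <- combos[1L, j]; r2 <- combos[2L, j]
      g <- expand.grid(ch1 = region_channels[[r1]], ch2 = region_channels[[r2]],
                       stringsAsFactors = FALSE)
      if (nrow(g) == 0L) return(NULL)
      data.frame(region1 = r1, region2 = r2, g, stringsAsFactors = FALSE)
    }))
  }
  wc <- vapply(regions, function(r) {
    n <- length(region_channels[[r]]); n * (n - 1) / 2
  }, numeric(1))
  bc <- numeric(0)
  if (length(regions) >= 2L) {
    combos <- utils::combn(regions, 2L)
    bc <- stats::setNames(
      vapply(seq_len(ncol(combos)), function(j) {
        length(region_channels[[combos[1L, j]]]) *
          length(region_channels[[combos[2L, j]]])
      }, numeric(1)),
      paste(combos[1L, ], combos[2L, ], sep = "-"))
  }
  list(within = within, between = between,
       within_counts = wc, between_counts = bc)
}

#' Region-averaged epoch coherence with bootstrap CI
#'
#' Epoch-averaged coherence spectra for every channel pair within one
#' region (`signals_b = NULL`) or between two regions, averaged across
#' pairs with a bias-corrected bootstrap confidence interval.
#'
#' @param signals_a matrix, samples x channels (first region).
#' @param signals_b optional matrix for a second region; when `NULL`, all
#'   within-region pairs of `signals_a` are used.
#' @param fs sampling rate in Hz.
#' @param epoch `c(start_s, end_s)` epoch to average over.
#' @param cfg a [spectral_config()].
#' @param n_boot bootstrap resamples (default 1000).
#' @return list with `freq_hz`, `mean`, `lo`, `hi`, `n_pairs`,
#'   `per_pair` (pair x frequency matrix).
#' @export
region_coherence <- function(signals_a, signals_b = NULL, fs = 1000, epoch,
                             cfg = spectral_config(), n_boot = 1000) {
  i0 <- floor(epoch[1L] * fs) + 1L
  i1 <- floor(epoch[2L] * fs)
  stopifnot(i0 >= 1L, i1 <= nrow(signals_a), i1 > i0)
  ## taper FFTs once per channel over the epoch
  tap_fft <- function(sig) {
    mt_tapered_fft(sig[i0:i1], fs, cfg$coherence_window_s,
                   cfg$time_bandwidth, cfg$n_tapers)
  }
  Ja <- lapply(seq_len(ncol(signals_a)), function(ch) tap_fft(signals_a[, ch]))
  if (is.null(signals_b)) {
    Jb <- Ja
    pairs <- t(utils::combn(length(Ja), 2L))
  } else {
    stopifnot(nrow(signals_b) == nrow(signals_a))
    Jb <- lapply(seq_len(ncol(signals_b)), function(ch) tap_fft(signals_b[, ch]))
    pairs <- as.matrix(expand.grid(seq_along(Ja), seq_along(Jb)))
  }
  freq <- attr(Ja[[1L]], "freq")
  keep <- freq <= cfg$max_freq_hz
  auto <- function(J) rowMeans(tap_mean_mod2(J))
  Sa <- vapply(Ja, auto, numeric(length(freq)))
  Sb <- vapply(Jb, auto, numeric(length(freq)))
  per <- matrix(NA_real_, nrow(pairs), sum(keep))
  for (p in seq_len(nrow(pairs))) {
    j1 <- pairs[p, 1L]; j2 <- pairs[p, 2L]
    sxy <- rowMeans(tap_mean_cross(Ja[[j1]], Jb[[j2]]))
    per[p, ] <- pmin(Mod(sxy) / sqrt(Sa[, j1] * Sb[, j2]), 1)[keep]
  }
  m <- colMeans(per)
  np <- nrow(per)
  boot_idx <- matrix(sample.int(np, np * n_boot, replace = TRUE), n_boot, np)
  W <- matrix(0, n_boot, np)
  for (b in seq_len(n_boot)) W[b, ] <- tabulate(boot_idx[b, ], np) / np
  boots <- W %*% per  # n_boot x freq matrix of resampled means
  a <- (1 - cfg$ci_level) / 2
  ## bias-corrected percentile bounds, per frequency
  z0 <- stats::qnorm(pmin(pmax(colMeans(boots < rep(m, each = n_boot)),
                               1 / n_boot), 1 - 1 / n_boot))
  lo <- hi <- numeric(length(m))
  for (f in seq_along(m)) {
    p_lo <- stats::pnorm(2 * z0[f] + stats::qnorm(a))
    p_hi <- stats::pnorm(2 * z0[f] + stats::qnorm(1 - a))
    qs <- stats::quantile(boots[, f], probs = c(p_lo, p_hi), names = FALSE)
    lo[f] <- qs[1L]; hi[f] <- qs[2L]
  }
  list(freq_hz = freq[keep], mean = m, lo = lo, hi = hi,
       n_pairs = np, per_pair = per)
}

#' Z-score normalization to a pre-anesthetic baseline
#'
#' `z = (value - baseline mean) / baseline SD`, computed per channel
#' (column). Used for band power and firing-rate series.
#'
#' @param series numeric vector or matrix (bins x channels).
#' @param baseline_idx integer or logical index of baseline bins (rows).
#' @return z-scored series, same shape as `series`.
#' @export
normalize_to_baseline_z <- function(series, baseline_idx) {
  vec <- !is.matrix(series)
  if (vec) series <- matrix(series, ncol = 1L)
  base <- series[baseline_idx, , drop = FALSE]
  if (nrow(base) < 2L) stop("baseline must contain at least 2 bins")
  mu <- colMeans(base)
  sd_ <- apply(base, 2L, stats::sd)
  if (any(sd_ == 0)) stop("baseline has zero variance in at least one channel")
  out <- sweep(sweep(series, 2L, mu), 2L, sd_, "/")
  if (vec) out[, 1L] else out
}

#' Band power time series from a spectrogram
#'
#' Integrates spectrogram power over a frequency band, per time bin.
#'
#' @param spec a [multitaper_spectrogram()] result.
#' @param lo_hz,hi_hz band edges (inclusive).
#' @return numeric vector, one value per time bin (uV^2).
#' @export
band_power <- function(spec, lo_hz, hi_hz) {
  sel <- spec$freq_hz >= lo_hz & spec$freq_hz <= hi_hz
  if (!any(sel)) stop("band contains no frequency bins")
  df <- if (length(spec$freq_hz) > 1L) diff(spec$freq_hz[1:2]) else 1
  colSums(spec$power[sel, , drop = FALSE]) * df
}
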