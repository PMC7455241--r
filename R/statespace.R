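#' Per-second spectral power ratios
#'
#' For each channel and each 1-s bin, three band-power ratios computed from
#' a per-bin multitaper spectral estimate:
#' `r1 = power(17-35 Hz) / power(0.5-60 Hz)` (beta fraction),
#' `r2 = power(1-8 Hz) / power(1-16 Hz)` (slow fraction) and
#' `r3 = power(9-15 Hz) / power(1-16 Hz)` (alpha-spindle fraction).
#' The numerator bands of r2 and r3 are disjoint subsets of their common
#' denominator, so `r2 + r3 <= 1` up to floating error. Bins with zero
#' denominator power are flagged invalid rather than silently zeroed.
#'
#' @param signals matrix, samples x channels (one region,
#'   line-noise-filtered).
#' @param fs sampling rate in Hz.
#' @param bin_s bin length in seconds (default 1).
#' @return list of class `ratio_series`: `times_s` (bin centers), `r1`,
#'   `r2`, `r3` (bins x channels matrices in `[0, 1]`), `valid` (logical
#'   bins x channels).
#' @export
compute_spectral_ratios <- function(signals, fs = 1000, bin_s = 1) {
  stopifnot(is.matrix(signals), nrow(signals) >= bin_s * fs)
  nch <- ncol(signals)
  r1 <- r2 <- r3 <- valid <- NULL
  for (ch in seq_len(nch)) {
    p <- mt_psd_windows(signals[, ch], fs, bin_s, nw = 2, k = 3)
    f <- p$freq
    bsum <- function(lo, hi) colSums(p$power[f >= lo & f <= hi, , drop = FALSE])
    num1 <- bsum(17, 35); den1 <- bsum(0.5, 60)
    num2 <- bsum(1, 8);  den23 <- bsum(1, 16)
    num3 <- bsum(9, 15)
    ok <- den1 > 0 & den23 > 0
    v1 <- ifelse(ok, num1 / den1, NA_real_)
    v2 <- ifelse(ok, num2 / den23, NA_real_)
    v3 <- ifelse(ok, num3 / den23, NA_real_)
    r1 <- cbind(r1, v1); r2 <- cbind(r2, v2); r3 <- cbind(r3, v3)
    valid <- cbind(valid, ok)
    if (ch == 1L) times <- p$time_s
  }
  colnames(r1) <- colnames(r2) <- colnames(r3) <- colnames(valid) <-
    colnames(signals)
  structure(list(times_s = times, r1 = r1, r2 = r2, r3 = r3, valid = valid),
            class = "ratio_series")
}

## normalized Hann smoothing; edges renormalized over the partial window
hann_smooth <- function(x, n_win) {
  if (n_win < 2L) return(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_win - 1) / (n_win - 1))
  n <- length(x)
  xp <- c(rep(0, n_win), x, rep(0, n_win))
  mp <- c(rep(0, n_win), rep(1, n), rep(0, n_win))
  num <- stats::filter(xp, w, sides = 2)
  den <- stats::filter(mp, w, sides = 2)
  idx <- n_win + seq_len(n)
  as.numeric(num[idx] / den[idx])
}

#' 3-D state-space embedding from per-ratio first principal components
#'
#' For each of the three ratios, runs PCA on the time-by-channel matrix
#' (channel means removed, no variance scaling -- the ratios are already
#' commensurate in `[0, 1]`), keeps the first principal component score
#' series and its explained-variance fraction, and smooths each score with
#' a normalized 20-s Hanning window. The PC1 sign is fixed so the loading
#' vector has positive mean (channels load positively), making embeddings
#' comparable across sessions and seeds; when `baseline_idx` is given the
#' sign is instead fixed so the baseline mean score is positive.
#'
#' @param ratios a [compute_spectral_ratios()] result.
#' @param smooth_window_s Hanning window length in seconds (default 20).
#' @param span_idx optional integer/logical index restricting the analysis
#'   span (e.g. from LOC to session end); PCA runs on this span only.
#' @param baseline_idx optional index (into the span rows) used for the
#'   sign convention.
#' @return list of class `statespace_embedding`: `times_s`, `points`
#'   (span x 3 matrix of smoothed PC1 scores), `variance_explained`
#'   (length 3), `loadings` (channels x 3).
#' @export
embed_pc1 <- function(ratios, smooth_window_s = 20, span_idx = NULL,
                      baseline_idx = NULL) {
  stopifnot(inherits(ratios, "ratio_series"))
  mats <- list(ratios$r1, ratios$r2, ratios$r3)
  n_bins <- nrow(mats[[1L]])
  if (is.null(span_idx)) span_idx <- seq_len(n_bins)
  if (is.logical(span_idx)) span_idx <- which(span_idx)
  if (ncol(mats[[1L]]) < 2L) stop("embedding requires at least 2 channels")
  dt <- if (length(ratios$times_s) > 1L) diff(ratios$times_s[1:2]) else 1
  n_win <- max(2L, round(smooth_window_s / dt))
  if (length(span_idx) < n_win) stop("analysis span shorter than the smoothing window")
  pts <- matrix(NA_real_, length(span_idx), 3L)
  varexp <- numeric(3L)
  loadings <- matrix(NA_real_, ncol(mats[[1L]]), 3L)
  for (j in 1:3) {
    M <- mats[[j]][span_idx, , drop = FALSE]
    if (anyNA(M)) stop("invalid ratio bins inside the analysis span")
    if (all(apply(M, 2L, stats::sd) == 0)) stop("constant ratio matrix: zero variance")
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    score <- pc$x[, 1L]
    load1 <- pc$rotation[, 1L]
    flip <- if (!is.null(baseline_idx)) mean(score[baseline_idx]) < 0
            else mean(load1) < 0
    if (flip) { score <- -score; load1 <- -load1 }
    varexp[j] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    pts[, j] <- hann_smooth(score, n_win)
    loadings[, j] <- load1
  }
  colnames(pts) <- c("pc1_r1", "pc1_r2", "pc1_r3")
  structure(list(times_s = ratios$times_s[span_idx], points = pts,
                 variance_explained = varexp, loadings = loadings),
            class = "statespace_embedding")
}

#' Gaussian product-kernel density estimate
#'
#' Kernel density with a Gaussian kernel and Silverman's rule-of-thumb
#' bandwidth per dimension, evaluated at arbitrary points.
#'
#' @param x data matrix (n x d).
#' @param eval evaluation points (m x d); default the data themselves.
#' @param bw optional bandwidth vector (length d).
#' @return numeric vector of densities at `eval`.
#' @export
kde_density <- function(x, eval = x, bw = NULL) {
  x <- as.matrix(x); eval <- as.matrix(eval)
  n <- nrow(x); d <- ncol(x)
  if (is.null(bw)) {
    bw <- apply(x, 2L, stats::sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
    bw[bw == 0] <- 1e-9
  }
  out <- numeric(nrow(eval))
  chunk <- max(1L, floor(2e6 / n))
  for (i0 in seq(1L, nrow(eval), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(eval))
    k <- matrix(1, i1 - i0 + 1L, n)
    for (j in seq_len(d)) {
      u <- outer(eval[i0:i1, j], x[, j], "-") / bw[j]
      k <- k * stats::dnorm(u) / bw[j]
    }
    out[i0:i1] <- rowMeans(k)
  }
  out
}

#' Trajectory density, speed and behavioral overlay
#'
#' Kernel density estimate at every embedded point, Euclidean speed between
#' consecutive points (per second; `NA` at the last point), and the
#' engagement/performance probabilities sampled on the embedding grid.
#'
#' @param embedding a [embed_pc1()] result.
#' @param probs optional [estimate_probabilities()] result sharing the 1-s
#'   grid; times must cover the embedding span.
#' @return data frame of class `trajectory_metrics`: `t_s`, `pc1_r1`,
#'   `pc1_r2`, `pc1_r3`, `density`, `speed`, and when `probs` is given
#'   `engagement` and `performance`.
#' @export
trajectory_metrics <- function(embedding, probs = NULL) {
  stopifnot(inherits(embedding, "statespace_embedding"))
  pts <- embedding$points
  dens <- kde_density(pts)
  dx <- diff(pts)
  speed <- c(sqrt(rowSums(dx^2)), NA_real_)
  out <- data.frame(t_s = embedding$times_s, pts, density = dens,
                    speed = speed)
  if (!is.null(probs)) {
    if (max(embedding$times_s) > max(probs$times_s) + 1 ||
        min(embedding$times_s) < min(probs$times_s) - 1) {
      stop("probability grid does not cover the embedding span")
    }
    out$engagement <- stats::approx(probs$times_s, probs$p_engage,
                                    embedding$times_s, rule = 2)$y
    out$performance <- stats::approx(probs$times_s, probs$p_perform,
                                     embedding$times_s, rule = 2)$y
  }
  class(out) <- c("trajectory_metrics", class(out))
  out
}
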