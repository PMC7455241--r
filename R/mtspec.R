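## Multitaper machinery: discrete prolate spheroidal (Slepian) tapers and
## tapered-FFT helpers shared by the spectrogram, coherence and state-space
## code. Tapers come from the classical symmetric tridiagonal eigenproblem
## (Slepian 1978): its top-k eigenvectors are the length-n DPSS at
## half-bandwidth W = nw/n. Eigenvalues are located by Sturm bisection and
## eigenvectors by inverse iteration on the sparse tridiagonal system.

## number of eigenvalues of the tridiagonal (d, e) strictly below x
sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1L] - x
  if (q < 0) cnt <- 1L
  e2 <- c(0, e^2)
  for (i in 2:n) {
    if (q == 0) q <- .Machine$double.eps * (abs(d[i - 1L]) + 1)
    q <- d[i] - x - e2[i] / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS of length `n` for time-bandwidth product
#' `nw`, each normalized to unit energy. Results are memoized per
#' `(n, nw, k)` because spectrogram windows reuse the same taper set.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 2, giving up to `2*nw - 1 = 3`
#'   well-concentrated tapers).
#' @param k number of tapers.
#' @return `n x k` matrix; columns are orthonormal tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 8, k >= 1, nw > 0, k <= n)
  key <- paste0("dpss_", n, "_", nw, "_", k)
  cached <- .dex_cache[[key]]
  if (!is.null(cached)) return(cached)

  w <- nw / n
  i <- 0:(n - 1L)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2

  ## Gershgorin bounds
  r <- c(e, 0) + c(0, e)
  lo0 <- min(d - r); hi0 <- max(d + r)

  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(e, d, e))
  tapers <- matrix(0, n, k)
  tol <- (hi0 - lo0) * 1e-12
  for (j in seq_len(k)) {
    m <- n - j + 1L  # ascending index of the j-th largest eigenvalue
    lo <- lo0; hi <- hi0
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sturm_count(d, e, mid) < m) lo <- mid else hi <- mid
    }
    lam <- (lo + hi) / 2
    ## inverse iteration, slightly shifted off the eigenvalue
    shift <- lam + (hi0 - lo0) * 1e-12
    B <- A - Matrix::Diagonal(n, shift)
    set_v <- sin(seq_len(n) * j * pi / (n + 1))  # deterministic start
    v <- set_v / sqrt(sum(set_v^2))
    for (it in 1:3) {
      v <- as.numeric(Matrix::solve(B, v))
      ## orthogonalize against previously found tapers for stability
      if (j > 1L) {
        prev <- tapers[, seq_len(j - 1L), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
    }
    ## sign convention: symmetric tapers have positive mean, antisymmetric
    ## tapers a positive initial slope
    s <- sum(v)
    if (abs(s) > 1e-6) {
      if (s < 0) v <- -v
    } else if (v[2L] - v[1L] < 0) v <- -v
    tapers[, j] <- v
  }
  .dex_cache[[key]] <- tapers
  tapers
}

## Tapered FFTs of all non-overlapping windows of x.
## Returns complex array [freq (one-sided), window, taper].
mt_tapered_fft <- function(x, fs, window_s, nw = 2, k = 3) {
  n_w <- round(window_s * fs)
  m <- floor(length(x) / n_w)
  if (m < 1L) stop("signal shorter than one analysis window")
  nf <- floor(n_w / 2) + 1L
  X <- matrix(x[seq_len(n_w * m)], n_w, m)
  tp <- dpss_tapers(n_w, nw, k)
  out <- array(0i, dim = c(nf, m, k))
  for (j in seq_len(k)) {
    Fj <- stats::mvfft(X * tp[, j])
    out[, , j] <- Fj[seq_len(nf), , drop = FALSE]
  }
  attr(out, "freq") <- (seq_len(nf) - 1L) * fs / n_w
  attr(out, "time_s") <- (seq_len(m) - 0.5) * window_s
  attr(out, "n_w") <- n_w
  out
}

## mean over tapers of |J|^2 -> freq x window matrix
tap_mean_mod2 <- function(J) {
  d <- dim(J)
  acc <- matrix(0, d[1L], d[2L])
  for (j in seq_len(d[3L])) acc <- acc + Mod(J[, , j, drop = FALSE][, , 1L])^2
  acc / d[3L]
}

## mean over tapers of J1 * Conj(J2) -> complex freq x window matrix
tap_mean_cross <- function(J1, J2) {
  d <- dim(J1)
  acc <- matrix(0i, d[1L], d[2L])
  for (j in seq_len(d[3L])) {
    acc <- acc + J1[, , j, drop = FALSE][, , 1L] *
      Conj(J2[, , j, drop = FALSE][, , 1L])
  }
  acc / d[3L]
}

## One-sided multitaper PSD per window (uV^2/Hz): freq x window matrix.
mt_psd_windows <- function(x, fs, window_s, nw = 2, k = 3) {
  n_w <- round(window_s * fs)
  m <- floor(length(x) / n_w)
  if (m < 1L) stop("signal shorter than one analysis window")
  nf <- floor(n_w / 2) + 1L
  X <- matrix(x[seq_len(n_w * m)], n_w, m)
  tp <- dpss_tapers(n_w, nw, k)
  P <- matrix(0, nf, m)
  for (j in seq_len(k)) {
    Fj <- stats::mvfft(X * tp[, j])
    P <- P + Mod(Fj[seq_len(nf), , drop = FALSE])^2
  }
  P <- P / (k * fs)
  ## fold negative frequencies (not DC; not Nyquist when n_w is even)
  hi <- if (n_w %% 2 == 0) nf - 1L else nf
  if (hi >= 2L) P[2:hi, ] <- 2 * P[2:hi, , drop = FALSE]
  list(freq = (seq_len(nf) - 1L) * fs / n_w, power = P,
       time_s = (seq_len(m) - 0.5) * window_s)
}

## Welch PSD with Hann taper (one-sided, uV^2/Hz).
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  n_seg <- round(seg_s * fs)
  if (length(x) < n_seg) stop("signal shorter than one Welch segment")
  step <- max(1L, round(n_seg * (1 - overlap)))
  starts <- seq(1L, length(x) - n_seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_seg - 1) / n_seg)  # periodic Hann
  u <- sum(w^2)
  nf <- floor(n_seg / 2) + 1L
  S <- matrix(x[outer(seq_len(n_seg) - 1L, starts, "+")], n_seg, length(starts))
  S <- sweep(S, 2L, colMeans(S))  # remove per-segment mean
  Fm <- stats::mvfft(S * w)
  P <- rowMeans(Mod(Fm[seq_len(nf), , drop = FALSE])^2) / (fs * u)
  hi <- if (n_seg %% 2 == 0) nf - 1L else nf
  if (hi >= 2L) P[2:hi] <- 2 * P[2:hi]
  list(freq = (seq_len(nf) - 1L) * fs / n_seg, power = P)
}

## analytic signal via FFT (Marple); x numeric vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
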