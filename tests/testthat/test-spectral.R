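test_that("line-noise removal notches 60 Hz, preserves neighbors, zero phase", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  tone60 <- sin(2 * pi * 60 * t)
  out60 <- remove_line_noise(tone60, fs)
  atten_db <- 20 * log10(stats::sd(out60[1000:9000]) / stats::sd(tone60))
  expect_lt(atten_db, -20)

  tone10 <- sin(2 * pi * 10 * t)
  out10 <- remove_line_noise(tone10, fs)
  expect_equal(stats::sd(out10[1000:9000]), stats::sd(tone10[1000:9000]),
               tolerance = 0.01)

  ## forward-backward filtering leaves no lag: cross-correlation peaks at 0
  set.seed(1)
  x <- stats::rnorm(5000)
  y <- remove_line_noise(x, fs)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(remove_line_noise(x, fs = 100, notch_hz = 60), "Nyquist")
})

test_that("multitaper PSD integrates to the variance of white noise", {
  set.seed(5)
  x <- stats::rnorm(120000)  # 2 min, unit variance
  spec <- multitaper_spectrogram(x, 1000, spectral_config(max_freq_hz = 500))
  df <- diff(spec$freq_hz[1:2])
  integ <- colSums(spec$power) * df
  expect_true(all(abs(integ - 1) < 0.1))
  expect_true(all(spec$power >= 0))
})

test_that("spectrogram peaks at a pure tone and bins count as floor(T/W)", {
  fs <- 1000
  t <- seq_len(360 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  spec <- multitaper_spectrogram(x, fs)
  expect_equal(ncol(spec$power), 12)  # floor(360 / 30)
  peaks <- spec$freq_hz[apply(spec$power, 2, which.max)]
  expect_true(all(abs(peaks - 10) <= diff(spec$freq_hz[1:2])))
  expect_error(multitaper_spectrogram(x[1:100], fs), "shorter")
})

test_that("spectrogram of concatenated segments concatenates", {
  set.seed(6)
  a <- stats::rnorm(60000)
  b <- stats::rnorm(60000)
  cfg <- spectral_config()
  sa <- multitaper_spectrogram(a, 1000, cfg)
  sb <- multitaper_spectrogram(b, 1000, cfg)
  sab <- multitaper_spectrogram(c(a, b), 1000, cfg)
  expect_equal(sab$power, cbind(sa$power, sb$power))
})

test_that("PSD scales as the square of the signal; coherence is scale-free", {
  set.seed(7)
  x <- stats::rnorm(60000)
  y <- stats::rnorm(60000)
  s1 <- multitaper_spectrogram(x, 1000)
  s3 <- multitaper_spectrogram(3 * x, 1000)
  expect_equal(s3$power, 9 * s1$power, tolerance = 1e-10)
  c1 <- pairwise_coherence(x, y, 1000, epoch = c(0, 60))
  c2 <- pairwise_coherence(5 * x, y, 1000, epoch = c(0, 60))
  expect_equal(c1$epoch_coherence, c2$epoch_coherence, tolerance = 1e-10)
})

test_that("epoch PSD: channel mean, percentile CI, flat white-noise spectrum", {
  set.seed(8)
  one <- stats::rnorm(90000)
  same <- cbind(one, one, one)
  res <- epoch_psd_with_ci(same, 1000, epoch = c(10, 70))
  expect_equal(res$lo, res$hi)                 # identical channels: width 0
  expect_equal(res$mean, rowMeans(res$per_channel))

  wn <- matrix(stats::rnorm(90000 * 4), ncol = 4)
  rw <- epoch_psd_with_ci(wn, 1000, epoch = c(10, 70))
  mid <- rw$freq_hz > 5 & rw$freq_hz < 115
  expect_lt(stats::sd(rw$mean[mid]) / mean(rw$mean[mid]), 0.15)

  expect_error(epoch_psd_with_ci(wn, 1000, epoch = c(80, 120)), "outside")
})

test_that("coherence oracles: identity, linear filtering, independence", {
  set.seed(9)
  x <- stats::rnorm(60000)
  self <- pairwise_coherence(x, x, 1000, epoch = c(0, 60))
  expect_true(all(abs(self$epoch_coherence - 1) < 1e-6))
  expect_true(all(self$coherence >= 0 & self$coherence <= 1))

  ## y = 2x delayed by 10 ms keeps magnitude coherence ~1
  y <- c(rep(0, 10), 2 * x[1:59990])
  del <- pairwise_coherence(x, y, 1000, epoch = c(0, 60))
  expect_gt(mean(del$epoch_coherence[del$epoch_freq_hz <= 100]), 0.98)

  ## independent white noise over a 60-s epoch sits near the estimator floor
  ind <- pairwise_coherence(stats::rnorm(60000), stats::rnorm(60000), 1000,
                            epoch = c(0, 60))
  expect_lt(mean(ind$epoch_coherence), 0.3)

  expect_error(pairwise_coherence(x, x[1:100], 1000), "equal length")
})

test_that("channel-pair enumeration reproduces the printed pair counts", {
  pairs <- enumerate_channel_pairs(c(S1 = 9, S2 = 11, PMv = 10))
  expect_equal(unname(pairs$within_counts), c(36, 55, 45))
  expect_equal(unname(pairs$between_counts["S1-S2"]), 99)
  expect_equal(unname(pairs$between_counts["S1-PMv"]), 90)
  expect_equal(unname(pairs$between_counts["S2-PMv"]), 110)
  expect_equal(nrow(pairs$within), 36 + 55 + 45)
  expect_equal(nrow(pairs$between), 99 + 90 + 110)
  ## no self-pairs or duplicates
  expect_true(all(pairs$within$ch1 != pairs$within$ch2))
  expect_equal(anyDuplicated(pairs$within), 0)
  single <- enumerate_channel_pairs(c(A = 1))
  expect_null(single$within)
  expect_equal(unname(single$within_counts), 0)
})

test_that("baseline z-normalization has the closed-form shift behavior", {
  set.seed(10)
  base <- stats::rnorm(50, mean = 4, sd = 2)
  z <- normalize_to_baseline_z(base, seq_along(base))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)

  mu <- mean(base); sigma <- stats::sd(base)
  shifted <- c(base, base + 3)
  zs <- normalize_to_baseline_z(shifted, 1:50)
  expect_equal(mean(zs[51:100]) - mean(zs[1:50]), 3 / sigma, tolerance = 1e-12)
  ## a doubled rate maps to z = mu / sigma
  doubled <- c(base, base * 2)
  zd <- normalize_to_baseline_z(doubled, 1:50)
  expect_equal(mean(zd[51:100]), mu / sigma, tolerance = 1e-12)

  expect_error(normalize_to_baseline_z(rep(1, 10), 1:10), "zero variance")
  expect_error(normalize_to_baseline_z(base, 1), "2 bins")
})

test_that("region coherence averages pairs and brackets the mean with its CI", {
  set.seed(11)
  shared <- stats::rnorm(62000)
  sig <- vapply(1:4, function(i) shared + stats::rnorm(62000, sd = 0.5),
                numeric(62000))
  rc <- region_coherence(sig, fs = 1000, epoch = c(0, 60), n_boot = 200)
  expect_equal(rc$n_pairs, 6)
  expect_true(all(rc$mean >= 0 & rc$mean <= 1))
  expect_true(all(rc$lo <= rc$mean + 1e-9 & rc$mean <= rc$hi + 1e-9))
  ## strongly shared signal: high coherence away from DC
  expect_gt(mean(rc$mean[rc$freq_hz > 1 & rc$freq_hz < 100]), 0.7)
})
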