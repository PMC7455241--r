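test_that("band-confined signals pin the ratios to their bounds", {
  fs <- 1000
  set.seed(31)
  mk <- function(lo, hi) {
    vapply(1:2, function(i) {
      x <- stats::rnorm(30 * fs)
      dexstates:::bandpass_filter(x, fs, lo, hi, order = 4)
    }, numeric(30 * fs))
  }
  beta <- compute_spectral_ratios(mk(18, 34), fs)
  expect_true(all(beta$r1 > 0.8))
  ## the 1-16 Hz denominator carries only leakage here, so r2 is small on
  ## average but individual low-power bins fluctuate
  expect_lt(mean(beta$r2), 0.15)

  slow <- compute_spectral_ratios(mk(1.5, 7), fs)
  expect_true(all(slow$r2 > 0.8))
  expect_true(all(slow$r3 < 0.2))
})

test_that("ratio invariants hold on generated sessions", {
  tl <- state_timeline(c("awake", "unconscious"), c(0, 60), c(60, 150))
  s <- generate_session(timeline = tl, n_channels = c(S1 = 3),
                        behavior_probs = NULL, seed = 32)
  rt <- compute_spectral_ratios(s$recording$signals$S1, 1000)
  for (m in list(rt$r1, rt$r2, rt$r3)) {
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_true(all(rt$r2 + rt$r3 <= 1 + 1e-9))
  expect_equal(length(rt$times_s), 150)
})

test_that("identical channels give a rank-1 embedding (variance 1)", {
  set.seed(33)
  x <- stats::rnorm(200)
  rt <- structure(list(times_s = seq_len(200) - 0.5,
                       r1 = cbind(x, x, x), r2 = cbind(x, x, x),
                       r3 = cbind(x, x, x),
                       valid = matrix(TRUE, 200, 3)),
                  class = "ratio_series")
  emb <- embed_pc1(rt)
  expect_equal(emb$variance_explained, rep(1, 3), tolerance = 1e-12)
})

test_that("a 9:1 shared-to-noise ratio keeps PC1 above 70% (eigen oracle)", {
  ## covariance 9*J + I has top eigenvalue 9k + 1 of trace 10k: for k = 6
  ## channels the oracle fraction is (9*6 + 1) / 60 = 0.917
  for (seed in 1:20) {
    set.seed(seed)
    shared <- stats::rnorm(300, sd = 3)
    M <- vapply(1:6, function(i) shared + stats::rnorm(300, sd = 1),
                numeric(300))
    rt <- structure(list(times_s = seq_len(300) - 0.5, r1 = M, r2 = M, r3 = M,
                         valid = matrix(TRUE, 300, 6)),
                    class = "ratio_series")
    emb <- embed_pc1(rt)
    expect_gte(emb$variance_explained[1], 0.7)
  }
})

test_that("smoothing preserves constants and reduces variance", {
  const <- dexstates:::hann_smooth(rep(2.5, 200), 20)
  expect_equal(const, rep(2.5, 200), tolerance = 1e-12)
  set.seed(34)
  x <- stats::rnorm(500)
  sm <- dexstates:::hann_smooth(x, 20)
  expect_lt(stats::var(sm), stats::var(x))
})

test_that("degenerate ratio matrices are rejected", {
  rt <- structure(list(times_s = seq_len(100) - 0.5,
                       r1 = matrix(0.5, 100, 3), r2 = matrix(0.5, 100, 3),
                       r3 = matrix(0.5, 100, 3),
                       valid = matrix(TRUE, 100, 3)),
                  class = "ratio_series")
  expect_error(embed_pc1(rt), "zero variance")
  one_ch <- structure(list(times_s = 1:100, r1 = matrix(0.5, 100, 1),
                           r2 = matrix(0.5, 100, 1), r3 = matrix(0.5, 100, 1),
                           valid = matrix(TRUE, 100, 1)),
                      class = "ratio_series")
  expect_error(embed_pc1(one_ch), "2 channels")
})

test_that("trajectory speed is the Euclidean step length", {
  pts <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  emb <- structure(list(times_s = 1:3, points = pts,
                        variance_explained = rep(1, 3),
                        loadings = matrix(1, 2, 3)),
                   class = "statespace_embedding")
  tm <- trajectory_metrics(emb)
  expect_equal(tm$speed[1:2], c(5, 12))
  expect_true(is.na(tm$speed[3]))

  same <- emb
  same$points <- matrix(1, 5, 3)
  same$times_s <- 1:5
  tm0 <- trajectory_metrics(same)
  expect_true(all(tm0$speed[1:4] == 0))
})

test_that("the KDE integrates to one (numerical integration oracle)", {
  set.seed(35)
  pts <- matrix(stats::rnorm(200 * 3), ncol = 3)
  gr <- seq(-5, 5, length.out = 41)
  grid <- as.matrix(expand.grid(gr, gr, gr))
  dens <- kde_density(pts, eval = grid)
  integral <- sum(dens) * diff(gr[1:2])^3
  expect_equal(integral, 1, tolerance = 0.02)
})

test_that("probability overlays require a covering grid", {
  emb <- structure(list(times_s = 1:100 - 0.5,
                        points = matrix(stats::rnorm(300), 100, 3),
                        variance_explained = rep(1, 3),
                        loadings = matrix(1, 2, 3)),
                   class = "statespace_embedding")
  short <- data.frame(times_s = 1:10, p_engage = rep(1, 10),
                      p_perform = rep(1, 10))
  class(short) <- c("probability_series", class(short))
  expect_error(trajectory_metrics(emb, short), "does not cover")
})
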