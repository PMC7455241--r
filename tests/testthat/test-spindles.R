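test_that("parameter gates are validated", {
  expect_error(spindle_params(onset_z = 7, peak_z = 6, baseline = c(0, 60)),
               "onset_z < peak_z")
  expect_error(spindle_params(duration_ms = c(2500, 500), baseline = c(0, 60)),
               "increasing")
})

test_that("a single injected burst yields exactly one covering event", {
  burst <- single_burst_channel(seed = 21, dur_ms = 1800, amplitude_z = 8)
  ev <- detect_spindles(burst$signal, 1000,
                        spindle_params(baseline = c(0, 60)))
  expect_equal(nrow(ev), 1L)
  ## detected event sits inside the injected support and contains its peak
  mid <- (burst$start_s + burst$end_s) / 2
  expect_gte(ev$start_s, burst$start_s - 0.05)
  expect_lte(ev$end_s, burst$end_s + 0.05)
  expect_true(ev$start_s < mid && mid < ev$end_s)
})

test_that("short and over-amplitude bursts are rejected by the gates", {
  params <- spindle_params(baseline = c(0, 60))
  ## 400 ms burst: its super-threshold core falls below the 500 ms gate
  short <- single_burst_channel(seed = 22, dur_ms = 400, amplitude_z = 8)
  expect_equal(nrow(detect_spindles(short$signal, 1000, params)), 0L)
  ## 20 z burst: above the 15 z artifact gate
  loud <- single_burst_channel(seed = 22, dur_ms = 1800, amplitude_z = 20)
  expect_equal(nrow(detect_spindles(loud$signal, 1000, params)), 0L)
})

test_that("every emitted event satisfies the printed gates exactly", {
  inj <- spindle_channel(seed = 23, dur_s = 360)
  ev <- detect_spindles(inj$signal, 1000, spindle_params(baseline = c(0, 60)))
  expect_gt(nrow(ev), 5)
  expect_true(all(ev$duration_ms >= 500 & ev$duration_ms <= 2500))
  expect_true(all(ev$peak_z >= 6 & ev$peak_z <= 15))
  expect_true(all(ev$start_s < ev$peak_s & ev$peak_s < ev$end_s))
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))  # non-overlapping
})

test_that("raising onset_z never increases the number of events", {
  inj <- spindle_channel(seed = 24, dur_s = 360)
  counts <- vapply(c(3, 4, 5, 5.9), function(oz) {
    nrow(detect_spindles(inj$signal, 1000,
                         spindle_params(onset_z = oz, baseline = c(0, 60))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate baselines are rejected", {
  x <- rep(0, 120000)
  expect_error(detect_spindles(x, 1000, spindle_params(baseline = c(0, 50))),
               "zero envelope variance")
})

test_that("peak frequency recovers noiseless carriers with both estimators", {
  for (f0 in c(10, 13)) {
    x <- burst_trace(f0, dur_s = 1.5, total_s = 3, at_s = 0.5)
    seg <- x[400:2100]
    expect_equal(spindle_peak_frequency(seg, 1000, method = "hht"), f0,
                 tolerance = 0.6)
    expect_equal(spindle_peak_frequency(seg, 1000, method = "psd"), f0,
                 tolerance = 0.3)
  }
})

test_that("superposed tones resolve to the stronger component (PSD oracle)", {
  t <- seq_len(2000) / 1000
  two <- 2 * sin(2 * pi * 11 * t) + sin(2 * pi * 15 * t)
  expect_equal(spindle_peak_frequency(two, 1000, method = "psd"), 11,
               tolerance = 0.3)
})

test_that("both estimators track the injected carrier on noisy spindles", {
  inj <- spindle_channel(seed = 25, dur_s = 240)
  ev <- detect_spindles(inj$signal, 1000, spindle_params(baseline = c(0, 60)))
  err_hht <- err_psd <- c()
  for (i in seq_len(nrow(ev))) {
    j <- which(inj$events$start_s < ev$end_s[i] &
                 inj$events$end_s > ev$start_s[i])
    if (length(j) != 1L) next
    seg <- inj$signal[round(ev$start_s[i] * 1000):round(ev$end_s[i] * 1000)]
    truth <- inj$events$freq_hz[j]
    err_hht <- c(err_hht, spindle_peak_frequency(seg, 1000, method = "hht") -
                   truth)
    err_psd <- c(err_psd, spindle_peak_frequency(seg, 1000, method = "psd") -
                   truth)
  }
  expect_gt(length(err_hht), 5)
  ## in-noise accuracy: within 3 Hz everywhere, median much tighter
  expect_true(all(abs(err_hht) < 3))
  expect_true(all(abs(err_psd) < 3))
  expect_lt(stats::median(abs(err_psd)), 1.5)
})

test_that("period summaries compute density and flag only real differences", {
  ev <- data.frame(peak_s = seq(5, 595, length.out = 100),
                   duration_ms = stats::runif(100, 800, 1500),
                   peak_freq_hz = stats::runif(100, 10, 14))
  periods <- data.frame(label = "anesthesia", start_s = 0, end_s = 600)
  s <- summarize_spindles(ev, periods)
  expect_equal(s$stats$density_per_min, 10)   # 100 events in 10 min

  none <- summarize_spindles(ev[0, ], periods)
  expect_equal(none$stats$density_per_min, 0)

  ## identical samples across two periods: t = 0, not significant
  ev2 <- ev
  ev2$peak_s <- ev$peak_s + 600
  both <- rbind(ev, ev2)
  periods2 <- data.frame(label = c("anesthesia", "recovery"),
                         start_s = c(0, 600), end_s = c(600, 1200))
  s2 <- summarize_spindles(both, periods2)
  dur_row <- s2$comparisons[s2$comparisons$metric == "duration_ms", ]
  expect_equal(dur_row$t, 0, tolerance = 1e-9)
  expect_false(dur_row$significant)

  expect_error(summarize_spindles(ev, data.frame(label = "a", start_s = 1,
                                                 end_s = 1)),
               "zero-length")
})
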