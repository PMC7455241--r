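test_that("timeline and schedule validators enforce their invariants", {
  expect_error(state_timeline(character(0), numeric(0), numeric(0)),
               "at least one segment")
  expect_error(state_timeline(c("unconscious"), 0, 10), "first timeline state")
  expect_error(state_timeline(c("awake", "unconscious"), c(0, 5), c(10, 20)),
               "contiguous")
  expect_error(state_timeline("awake", 0, 0), "start_s < end_s")
  sched <- infusion_schedule(c(18, 4), c(0, 10), c(10, 60))
  expect_equal(infusion_span_min(sched), 60)
  expect_error(infusion_schedule(-1, 0, 10), ">= 0")
  expect_error(infusion_schedule(18, 0, 10, antagonist = list(time_min = -5)),
               "antagonist")
})

test_that("state_at maps times to the active segment, half-open intervals", {
  tl <- step_timeline(300, 900, 1800)
  expect_equal(state_at(tl, c(0, 299.9, 300, 899, 900, 1799)),
               c("awake", "awake", "unconscious", "unconscious",
                 "recovered", "recovered"))
  expect_true(is.na(state_at(tl, 1800)))
})

test_that("generated sessions are bit-identical for a fixed seed", {
  tl <- state_timeline(c("awake", "unconscious"), c(0, 60), c(60, 150))
  s1 <- generate_session(timeline = tl, n_channels = c(S1 = 2), seed = 42)
  s2 <- generate_session(timeline = tl, n_channels = c(S1 = 2), seed = 42)
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$ground_truth_spindles, s2$ground_truth_spindles)
  s3 <- generate_session(timeline = tl, n_channels = c(S1 = 2), seed = 43)
  expect_false(identical(s1$recording$signals, s3$recording$signals))
})

test_that("generator rejects invalid profiles and empty timelines", {
  expect_error(oscillatory_profile(band_row(10, 4, -1)), "amplitudes")
  expect_error(oscillatory_profile(band_row(10, 4, 1), shared_fraction = 1.5),
               "shared_fraction")
  tl <- state_timeline(c("awake", "intermediate"), c(0, 60), c(60, 120))
  expect_error(generate_session(timeline = tl, n_channels = c(S1 = 2),
                                profiles = list(awake = default_profiles()$awake),
                                seed = 1),
               "no profile")
})

test_that("awake segment with a single 20 Hz component peaks at 20 Hz", {
  ## independent periodogram oracle (stats::spec.pgram)
  prof <- list(awake = oscillatory_profile(band_row(20, 2, 10),
                                           shared_fraction = 1,
                                           noise_sd_uV = 0))
  tl <- state_timeline("awake", 0, 120)
  s <- generate_session(profiles = prof, timeline = tl,
                        n_channels = c(S1 = 1), behavior_probs = NULL,
                        seed = 3)
  x <- s$recording$signals$S1[, 1]
  pg <- stats::spec.pgram(stats::ts(x, frequency = 1000), spans = 31,
                          plot = FALSE, taper = 0)
  expect_equal(pg$freq[which.max(pg$spec)], 20, tolerance = 0.1)
})

test_that("state segments carry their configured bands (band-power contract)", {
  tl <- state_timeline(c("awake", "unconscious"), c(0, 120), c(120, 240))
  s <- generate_session(timeline = tl, n_channels = c(S1 = 2, PMv = 2),
                        behavior_probs = NULL, seed = 8)
  for (r in c("S1", "PMv")) {
    spec <- multitaper_spectrogram(s$recording$signals[[r]][, 1], 1000)
    beta_band <- if (r == "PMv") c(26, 34) else c(18, 25)
    awake_bins <- spec$time_bins_s < 120
    beta <- band_power(spec, beta_band[1], beta_band[2])
    slow <- band_power(spec, 0.5, 4)
    expect_gt(mean(beta[awake_bins]), mean(slow[awake_bins]))
    expect_gt(mean(slow[!awake_bins]), mean(beta[!awake_bins]))
  }
})

test_that("shared_fraction drives cross-channel similarity", {
  tl <- state_timeline("awake", 0, 60)
  prof_shared <- list(awake = oscillatory_profile(band_row(21.5, 7, 15),
                                                  shared_fraction = 1,
                                                  noise_sd_uV = 0))
  s <- generate_session(profiles = prof_shared, timeline = tl,
                        n_channels = c(S1 = 2), behavior_probs = NULL, seed = 4)
  expect_equal(s$recording$signals$S1[, 1], s$recording$signals$S1[, 2])

  prof_indep <- list(awake = oscillatory_profile(band_row(21.5, 7, 15),
                                                 shared_fraction = 0,
                                                 noise_sd_uV = 5))
  s0 <- generate_session(profiles = prof_indep, timeline = tl,
                         n_channels = c(S1 = 2), behavior_probs = NULL, seed = 4)
  co <- pairwise_coherence(s0$recording$signals$S1[, 1],
                           s0$recording$signals$S1[, 2], 1000,
                           epoch = c(0, 60))
  expect_lt(mean(co$epoch_coherence), 0.3)
})

test_that("spindle injection matches its rate, bounds and ground-truth log", {
  inj <- spindle_channel(seed = 1, dur_s = 660, baseline_s = 60,
                         rate_per_min = 10, duration_bounds_ms = c(500, 2500))
  n_events <- nrow(inj$events)
  ## renewal construction targets rate * minutes = 100 expected events
  expect_lt(abs(n_events - 100), 3 * sqrt(100))
  expect_true(all(inj$events$duration_ms >= 500 &
                    inj$events$duration_ms <= 2500))
  expect_true(all(diff(inj$events$start_s) > 0))
  ## non-overlapping by construction
  expect_true(all(inj$events$start_s[-1] >= inj$events$end_s[-n_events]))
})

test_that("zero-amplitude injection is the identity", {
  set.seed(2)
  x <- stats::rnorm(60000)
  inj <- inject_spindles(x, 1000, rate_per_min = 10, amplitude_z = 0)
  expect_identical(inj$signal, x)
  expect_equal(nrow(inj$events), 0L)
  expect_error(inject_spindles(x, 1000, 10, duration_bounds_ms = c(2500, 500)),
               "increasing")
})

test_that("behavioral outcomes follow the state-conditional probabilities", {
  tl <- state_timeline("awake", 0, 2000)
  all_correct <- generate_behavior(tl, c(awake = 1), c(awake = 1), seed = 1)
  expect_true(all(all_correct$outcome == "correct"))
  none <- generate_behavior(tl, c(awake = 0), c(awake = 1), seed = 1)
  expect_true(all(none$outcome == "no_response"))
  expect_error(generate_behavior(tl, c(awake = 1.2), c(awake = 1)), "\\[0, 1\\]")

  ## binomial bound at p = 0.5: ~1000 trials in 8000 s at ITI 6-10 s
  tl_long <- state_timeline("awake", 0, 8000)
  tr <- generate_behavior(tl_long, c(awake = 0.5), c(awake = 1), seed = 9)
  frac <- mean(tr$outcome != "no_response")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})
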