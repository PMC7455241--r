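# Shared fixture builders. All fixtures are generated in code at test time.

# three-state session timeline with known switch times
step_timeline <- function(t_loc = 300, t_roc = 900, t_end = 1800) {
  state_timeline(c("awake", "unconscious", "recovered"),
                 c(0, t_loc, t_roc), c(t_loc, t_roc, t_end))
}

# trial log with a hard latent step at the state switches
step_trials <- function(seed, timeline = step_timeline()) {
  bp <- default_behavior_probs()
  generate_behavior(timeline, bp$p_engage, bp$p_correct_given_engaged,
                    seed = seed)
}

# white-noise channel with injected spindle bursts outside the baseline
spindle_channel <- function(seed, dur_s = 360, baseline_s = 60,
                            rate_per_min = 6, amplitude_z = 8,
                            duration_bounds_ms = c(1200, 2400)) {
  set.seed(seed)
  x <- stats::rnorm(dur_s * 1000, sd = 10)
  inject_spindles(x, 1000, rate_per_min = rate_per_min,
                  duration_bounds_ms = duration_bounds_ms,
                  amplitude_z = amplitude_z,
                  interval = c(baseline_s, dur_s),
                  baseline = c(0, baseline_s))
}

# overlap-based matching of detected against injected events
event_matches <- function(detected, truth) {
  recall_hits <- vapply(seq_len(nrow(truth)), function(i) {
    any(detected$start_s < truth$end_s[i] & detected$end_s > truth$start_s[i])
  }, logical(1))
  precision_hits <- if (nrow(detected) == 0L) logical(0) else
    vapply(seq_len(nrow(detected)), function(i) {
      any(truth$start_s < detected$end_s[i] & truth$end_s > detected$start_s[i])
    }, logical(1))
  list(recall = mean(recall_hits),
       precision = if (nrow(detected) == 0L) NA_real_ else mean(precision_hits))
}

# one deterministic Hann burst at a known location, calibrated in baseline
# envelope z units exactly like the generator's injections
single_burst_channel <- function(seed, dur_ms, amplitude_z, freq_hz = 13,
                                 fs = 1000, total_s = 120, at_s = 80,
                                 noise_sd = 5) {
  set.seed(seed)
  x <- stats::rnorm(total_s * fs, sd = noise_sd)
  bp <- dexstates:::bandpass_filter(x, fs, 9, 17, order = 4)
  env <- Mod(dexstates:::analytic_signal(bp))
  mu <- mean(env[1:(60 * fs)]); s <- stats::sd(env[1:(60 * fs)])
  amp <- (mu + amplitude_z * s) / dexstates:::band_gain(fs, c(9, 17), freq_hz)
  n <- round(dur_ms / 1000 * fs)
  t <- seq_len(n) / fs
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  i0 <- round(at_s * fs)
  x[i0:(i0 + n - 1L)] <- x[i0:(i0 + n - 1L)] +
    amp * hann * sin(2 * pi * freq_hz * t)
  list(signal = x, start_s = at_s, end_s = at_s + dur_ms / 1000)
}

# single Hann-enveloped burst embedded in a quiet trace
burst_trace <- function(freq_hz, dur_s, fs = 1000, total_s = 60,
                        at_s = 30, amp = 1, noise_sd = 0) {
  n <- total_s * fs
  x <- stats::rnorm(n, sd = noise_sd)
  nb <- round(dur_s * fs)
  t <- seq_len(nb) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nb) - 1) / (nb - 1))
  i0 <- round(at_s * fs)
  x[i0:(i0 + nb - 1L)] <- x[i0:(i0 + nb - 1L)] +
    amp * env * sin(2 * pi * freq_hz * t)
  x
}
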