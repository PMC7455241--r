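## Synthetic LFP sessions with ground-truth state timelines. Band
## components are narrow-band filtered Gaussian noise; a configurable
## fraction of each component's power is shared across the channels of a
## region (driving coherence and the common state trajectory seen by PCA),
## the remainder is channel-specific, plus an independent white-noise floor.

## unit-SD narrow-band Gaussian noise, synthesized spectrally: white
## Gaussian noise shaped by an order-2 Butterworth band-pass magnitude
## response (no filter edge transients, O(n log n))
narrowband_noise <- function(n, fs, center_hz, bandwidth_hz, order = 2) {
  lo <- max(center_hz - bandwidth_hz / 2, 0.05)
  hi <- min(center_hz + bandwidth_hz / 2, fs / 2 * 0.999)
  f <- (seq_len(n) - 1L) * fs / n
  fm <- pmin(f, fs - f)  # two-sided magnitude response
  f0sq <- lo * hi        # geometric band center
  B <- hi - lo
  H <- 1 / sqrt(1 + ((fm^2 - f0sq) / (pmax(fm, 1e-6) * B))^(2 * order))
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * H, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

## double-pass (zero-phase) magnitude gain of the band Butterworth at freq_hz
band_gain <- function(fs, band, freq_hz, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  w <- 2 * pi * freq_hz / fs
  H <- vapply(w, function(wi) {
    e <- exp(-1i * wi * (seq_along(bf$b) - 1))
    abs(sum(bf$b * e) / sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1))))
  }, numeric(1))
  H^2
}

## Hann-enveloped sinusoidal burst
spindle_burst <- function(n, fs, freq_hz, amplitude, phase) {
  t <- seq_len(n) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  amplitude * env * sin(2 * pi * freq_hz * t + phase)
}

## non-overlapping renewal event times within [t0, t1]; gap rate corrected
## for event duration so the realized rate matches rate_per_min
draw_spindle_times <- function(t0, t1, rate_per_min, duration_bounds_ms) {
  mean_dur <- mean(duration_bounds_ms) / 1000
  gap_mean <- 60 / rate_per_min - mean_dur
  if (gap_mean <= 0.05) stop("spindle rate too high for the duration bounds")
  starts <- numeric(0); durs <- numeric(0)
  t <- t0 + stats::rexp(1L, 1 / gap_mean)
  repeat {
    d <- stats::runif(1L, duration_bounds_ms[1L], duration_bounds_ms[2L]) / 1000
    if (t + d > t1) break
    starts <- c(starts, t); durs <- c(durs, d)
    t <- t + d + stats::rexp(1L, 1 / gap_mean)
  }
  data.frame(start_s = starts, duration_s = durs)
}

#' Inject spindle-like bursts into a signal
#'
#' Adds Hann-enveloped sinusoidal bursts with carriers drawn uniformly in
#' the spindle band at times drawn from a duration-corrected renewal
#' process (so events never overlap and the realized rate matches
#' `rate_per_min`). Burst peak amplitude is set to
#' `baseline envelope mean + amplitude_z * baseline envelope SD` of the
#' band-limited analytic envelope of the input, so a detector z-scored
#' against the same baseline sees the burst peak near `amplitude_z`.
#' `amplitude_z = 0` injects nothing and returns the signal unchanged.
#'
#' @param x numeric vector (one channel, microvolts).
#' @param fs sampling rate in Hz.
#' @param rate_per_min expected event rate per minute.
#' @param duration_bounds_ms burst duration bounds (uniform draw), ms.
#' @param amplitude_z burst peak amplitude in baseline-envelope z units.
#' @param band spindle carrier band in Hz.
#' @param interval optional `c(start_s, end_s)` restricting injection;
#'   default is the whole signal.
#' @param baseline optional `c(start_s, end_s)` over which the envelope
#'   mean/SD are measured; default is the whole signal.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return list with `signal` (modified trace) and `events` (data frame
#'   `start_s`, `end_s`, `duration_ms`, `freq_hz`, `amplitude_uV`).
#' @export
inject_spindles <- function(x, fs = 1000, rate_per_min,
                            duration_bounds_ms = c(500, 2500),
                            amplitude_z = 8, band = c(9, 17),
                            interval = NULL, baseline = NULL, seed = NULL) {
  if (diff(duration_bounds_ms) <= 0 || any(duration_bounds_ms <= 0)) {
    stop("duration bounds must be positive and increasing")
  }
  if (amplitude_z < 0) stop("amplitude_z must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), freq_hz = numeric(0),
                      amplitude_uV = numeric(0))
  if (amplitude_z == 0 || rate_per_min <= 0) {
    return(list(signal = x, events = empty))
  }
  dur_s <- length(x) / fs
  if (is.null(interval)) interval <- c(0, dur_s)
  if (is.null(baseline)) baseline <- c(0, dur_s)
  env <- Mod(analytic_signal(bandpass_filter(x, fs, band[1L], band[2L])))
  bi <- max(1L, floor(baseline[1L] * fs) + 1L):min(length(x), floor(baseline[2L] * fs))
  mu <- mean(env[bi]); sd_ <- stats::sd(env[bi])
  amp <- mu + amplitude_z * sd_
  ev <- draw_spindle_times(interval[1L], interval[2L], rate_per_min,
                           duration_bounds_ms)
  if (nrow(ev) == 0L) return(list(signal = x, events = empty))
  freqs <- stats::runif(nrow(ev), band[1L], band[2L])
  phases <- stats::runif(nrow(ev), 0, 2 * pi)
  ## calibrate so the band-limited envelope attains amplitude_z at the peak:
  ## compensate the zero-phase band filter's gain at each carrier
  amps <- amp / band_gain(fs, band, freqs)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$start_s[i] * fs) + 1L
    n_ev <- round(ev$duration_s[i] * fs)
    idx <- i0:(i0 + n_ev - 1L)
    x[idx] <- x[idx] + spindle_burst(n_ev, fs, freqs[i], amps[i], phases[i])
  }
  list(signal = x,
       events = data.frame(start_s = ev$start_s,
                           end_s = ev$start_s + ev$duration_s,
                           duration_ms = ev$duration_s * 1000,
                           freq_hz = freqs, amplitude_uV = amps))
}

#' Generate a synthetic multi-region LFP session
#'
#' Builds per-region multi-channel LFP at 1 kHz whose spectral content
#' follows the state timeline: within each state segment, each configured
#' band component is narrow-band Gaussian noise split into a shared
#' (region-common) and a channel-specific part according to the profile's
#' `shared_fraction`, on top of independent white channel noise. Spindle
#' bursts are injected per channel at the state's rate and logged exactly.
#' A behavioral trial log is generated from the same timeline.
#'
#' @param profiles named list of [oscillatory_profile()]s, one per state
#'   appearing in the timeline.
#' @param timeline a [state_timeline()].
#' @param n_channels named integer vector of channels per region.
#' @param schedule an [infusion_schedule()].
#' @param behavior_probs list as returned by [default_behavior_probs()];
#'   set to `NULL` to skip trial generation.
#' @param inter_trial_s trial-period bounds (uniform draw), seconds.
#' @param cross_fade_s linear cross-fade across segment boundaries
#'   (default 0: instantaneous transitions, keeping ground truth sharp).
#' @param fs sampling rate; fixed at 1000 Hz.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   sessions.
#' @return list of class `lfp_session`: `recording` (list with `signals`,
#'   a named list of samples x channels matrices, `fs`, `schedule`),
#'   `trials`, `timeline`, `ground_truth_spindles`, `seed`.
#' @export
generate_session <- function(profiles = default_profiles(),
                             timeline = default_timeline(),
                             n_channels = c(S1 = 9, S2 = 11, PMv = 10),
                             schedule = default_infusion_schedule(),
                             behavior_probs = default_behavior_probs(),
                             inter_trial_s = c(6, 10),
                             cross_fade_s = 0, fs = 1000, seed = 1L) {
  stopifnot(inherits(timeline, "state_timeline"),
            all(n_channels >= 1), fs == 1000)
  missing_states <- setdiff(timeline$state, names(profiles))
  if (length(missing_states) > 0) {
    stop("no profile for state(s): ", paste(missing_states, collapse = ", "))
  }
  set.seed(seed)
  n_total <- round(timeline_duration(timeline) * fs)
  awake_base <- c(timeline$start_s[1L], timeline$end_s[1L])
  regions <- names(n_channels)
  signals <- list()
  gt <- list()
  for (r in regions) {
    nch <- n_channels[[r]]
    sig <- matrix(0, n_total, nch)
    for (s in seq_len(nrow(timeline))) {
      st <- timeline$state[s]
      pr <- profiles[[st]]
      i0 <- round(timeline$start_s[s] * fs) + 1L
      i1 <- round(timeline$end_s[s] * fs)
      ## extend by the cross-fade half-width, then apply trapezoid weights
      pad <- round(cross_fade_s / 2 * fs)
      j0 <- max(1L, i0 - pad); j1 <- min(n_total, i1 + pad)
      len <- j1 - j0 + 1L
      wgt <- rep(1, len)
      if (pad > 0L) {
        ramp <- seq(0, 1, length.out = 2L * pad + 1L)[-1L]
        if (j0 < i0) wgt[seq_len(2L * pad)] <- ramp
        if (j1 > i1) wgt[len - seq_len(2L * pad) + 1L] <- ramp
      }
      bands <- pr$bands
      if (nrow(bands) > 0) {
        bands <- bands[is.na(bands$region) | bands$region == r, , drop = FALSE]
      }
      for (b in seq_len(nrow(bands))) {
        amp <- bands$amplitude_uV[b]
        if (amp == 0) next
        shared <- narrowband_noise(len, fs, bands$center_hz[b],
                                   bands$bandwidth_hz[b]) *
          amp * sqrt(pr$shared_fraction)
        for (ch in seq_len(nch)) {
          own <- if (pr$shared_fraction < 1) {
            narrowband_noise(len, fs, bands$center_hz[b],
                             bands$bandwidth_hz[b]) *
              amp * sqrt(1 - pr$shared_fraction)
          } else 0
          sig[j0:j1, ch] <- sig[j0:j1, ch] + (shared + own) * wgt
        }
      }
      if (pr$noise_sd_uV > 0) {
        sig[i0:i1, ] <- sig[i0:i1, ] +
          matrix(stats::rnorm((i1 - i0 + 1L) * nch, sd = pr$noise_sd_uV),
                 ncol = nch)
      }
    }
    ## spindle bursts per channel; envelope baseline measured once per
    ## channel over the awake segment, then bursts added per state segment
    sp_rows <- which(vapply(timeline$state, function(st) {
      profiles[[st]]$spindle_rate_per_min > 0
    }, logical(1)))
    if (length(sp_rows) > 0) {
      for (ch in seq_len(nch)) {
        ## envelope baseline over the awake segment only (5-s guard margins
        ## absorb filter edge effects)
        b0 <- round(awake_base[1L] * fs) + 1L
        b1 <- min(round(awake_base[2L] * fs) + 5L * fs, n_total)
        env <- Mod(analytic_signal(bandpass_filter(sig[b0:b1, ch], fs, 9, 17)))
        guard <- min(5L * fs, length(env) %/% 4L)
        core <- env[(guard + 1L):(length(env) - guard)]
        mu <- mean(core); sd_ <- stats::sd(core)
        for (s in sp_rows) {
          pr <- profiles[[timeline$state[s]]]
          amp <- mu + pr$spindle_amplitude_z * sd_
          ev <- draw_spindle_times(timeline$start_s[s], timeline$end_s[s],
                                   pr$spindle_rate_per_min,
                                   pr$spindle_duration_bounds_ms)
          if (nrow(ev) == 0L) next
          freqs <- stats::runif(nrow(ev), 9, 17)
          phases <- stats::runif(nrow(ev), 0, 2 * pi)
          amps <- amp / band_gain(fs, c(9, 17), freqs)
          for (i in seq_len(nrow(ev))) {
            i0 <- floor(ev$start_s[i] * fs) + 1L
            n_ev <- round(ev$duration_s[i] * fs)
            idx <- i0:(i0 + n_ev - 1L)
            sig[idx, ch] <- sig[idx, ch] +
              spindle_burst(n_ev, fs, freqs[i], amps[i], phases[i])
          }
          gt[[length(gt) + 1L]] <- data.frame(
            region = r, channel = sprintf("%s_%02d", r, ch),
            state = timeline$state[s], start_s = ev$start_s,
            end_s = ev$start_s + ev$duration_s,
            duration_ms = ev$duration_s * 1000, freq_hz = freqs,
            amplitude_uV = amps)
        }
      }
    }
    colnames(sig) <- sprintf("%s_%02d", r, seq_len(nch))
    signals[[r]] <- sig
  }
  trials <- NULL
  if (!is.null(behavior_probs)) {
    trials <- generate_behavior(timeline, behavior_probs$p_engage,
                                behavior_probs$p_correct_given_engaged,
                                inter_trial_s = inter_trial_s)
  }
  gt <- if (length(gt) > 0) do.call(rbind, gt) else NULL
  structure(list(
    recording = list(signals = signals, fs = fs, schedule = schedule),
    trials = trials, timeline = timeline,
    ground_truth_spindles = gt, seed = seed
  ), class = "lfp_session")
}

#' Generate a state-coupled behavioral trial log
#'
#' One trial per inter-trial period; the outcome is drawn from the state
#' active at trial time: engagement (any response) is Bernoulli with the
#' state's `p_engage`, and an engaged trial is correct with probability
#' `p_correct_given_engaged`.
#'
#' @param timeline a [state_timeline()].
#' @param p_engage named numeric vector, probability per state label.
#' @param p_correct_given_engaged named numeric vector per state label.
#' @param inter_trial_s trial-period bounds (uniform draw), seconds.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return data frame with `start_s` (strictly increasing) and `outcome`
#'   in `correct`, `failed_attempt`, `no_response`.
#' @export
generate_behavior <- function(timeline, p_engage, p_correct_given_engaged,
                              inter_trial_s = c(6, 10), seed = NULL) {
  stopifnot(inherits(timeline, "state_timeline"))
  if (any(p_engage < 0 | p_engage > 1) ||
      any(p_correct_given_engaged < 0 | p_correct_given_engaged > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  missing_states <- setdiff(timeline$state, names(p_engage))
  if (length(missing_states) > 0) {
    stop("no p_engage for state(s): ", paste(missing_states, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  dur <- timeline_duration(timeline)
  times <- numeric(0)
  t <- stats::runif(1L, inter_trial_s[1L], inter_trial_s[2L])
  while (t < dur) {
    times <- c(times, t)
    t <- t + stats::runif(1L, inter_trial_s[1L], inter_trial_s[2L])
  }
  states <- state_at(timeline, times)
  engaged <- stats::runif(length(times)) < p_engage[states]
  correct <- engaged &
    (stats::runif(length(times)) < p_correct_given_engaged[states])
  outcome <- ifelse(!engaged, "no_response",
                    ifelse(correct, "correct", "failed_attempt"))
  data.frame(start_s = times,
             outcome = factor(outcome,
                              levels = c("correct", "failed_attempt",
                                         "no_response")))
}
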