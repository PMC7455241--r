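#' Per-state oscillatory profile
#'
#' Describes the spectral content the synthetic generator produces while a
#' given behavioral state is active: a set of narrow-band components, a
#' spindle-burst rate, the fraction of component power shared across the
#' channels of a region, and the independent white-noise floor.
#'
#' Band components are narrow-band filtered Gaussian noise, not pure
#' sinusoids, so synthetic spectra have realistic bandwidth and pairwise
#' coherence is non-degenerate.
#'
#' @param bands data frame with columns `center_hz`, `bandwidth_hz`,
#'   `amplitude_uV` (component SD in microvolts) and optionally `region`
#'   (`NA` = applies to every region).
#' @param spindle_rate_per_min spindle-burst rate while the state is active.
#' @param spindle_duration_bounds_ms burst duration bounds (uniform draw).
#' @param spindle_amplitude_z burst peak amplitude in z-units of the awake
#'   9-17 Hz envelope (see [inject_spindles()]).
#' @param shared_fraction fraction of each band component's power that is
#'   common to all channels of a region, in `[0, 1]`.
#' @param noise_sd_uV SD of the independent per-channel white noise.
#' @return A list of class `oscillatory_profile`.
#' @export
oscillatory_profile <- function(bands,
                                spindle_rate_per_min = 0,
                                spindle_duration_bounds_ms = c(500, 2500),
                                spindle_amplitude_z = 8,
                                shared_fraction = 0.8,
                                noise_sd_uV = 10) {
  if (nrow(bands) > 0) {
    stopifnot(all(c("center_hz", "bandwidth_hz", "amplitude_uV") %in% names(bands)))
    if (any(bands$amplitude_uV < 0)) stop("band amplitudes must be >= 0")
    if (any(bands$bandwidth_hz <= 0)) stop("band bandwidths must be > 0")
  }
  if (is.null(bands$region)) bands$region <- NA_character_
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  if (diff(spindle_duration_bounds_ms) <= 0 || any(spindle_duration_bounds_ms <= 0)) {
    stop("spindle duration bounds must be positive and increasing")
  }
  if (spindle_rate_per_min < 0) stop("spindle rate must be >= 0")
  structure(list(
    bands = bands,
    spindle_rate_per_min = spindle_rate_per_min,
    spindle_duration_bounds_ms = spindle_duration_bounds_ms,
    spindle_amplitude_z = spindle_amplitude_z,
    shared_fraction = shared_fraction,
    noise_sd_uV = noise_sd_uV
  ), class = "oscillatory_profile")
}

band_row <- function(center_hz, bandwidth_hz, amplitude_uV, region = NA_character_) {
  data.frame(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
             amplitude_uV = amplitude_uV, region = region,
             stringsAsFactors = FALSE)
}

#' Default per-state oscillatory profiles
#'
#' Emulates the characteristic band signatures of each behavioral state:
#' awake/recovered beta (18-25 Hz in S1 and S2, 26-34 Hz in PMv), strong
#' slow-delta (0.5-4 Hz) during unconsciousness, transition alpha (8-12 Hz)
#' around induction and the intermediate recovery state, and 9-17 Hz spindle
#' bursts that peak during unconsciousness and early recovery. Absolute
#' amplitudes are free parameters (the source recordings are not calibrated
#' here); defaults put state components well above the noise floor.
#'
#' @return Named list of [oscillatory_profile()]s, one per state label.
#' @export
default_profiles <- function() {
  beta_awake <- rbind(
    band_row(21.5, 7, 15, "S1"),
    band_row(21.5, 7, 15, "S2"),
    band_row(30.0, 8, 15, "PMv")
  )
  list(
    awake = oscillatory_profile(beta_awake, spindle_rate_per_min = 0),
    induction = oscillatory_profile(
      rbind(band_row(10, 4, 20), band_row(2.25, 3.5, 15)),
      spindle_rate_per_min = 4),
    unconscious = oscillatory_profile(
      rbind(band_row(2.25, 3.5, 35)),
      spindle_rate_per_min = 6),
    intermediate = oscillatory_profile(
      rbind(band_row(10, 4, 25), band_row(2.25, 3.5, 10)),
      spindle_rate_per_min = 10),
    recovered = oscillatory_profile(beta_awake, spindle_rate_per_min = 0.5),
    post_antagonist = oscillatory_profile(beta_awake, spindle_rate_per_min = 0)
  )
}

#' Default state-conditional behavioral response probabilities
#'
#' Engagement is the probability a trial draws any response (correct or
#' failed attempt); performance is engagement times the conditional
#' probability of a correct response. Awake and recovered animals perform
#' near ceiling (trained criterion above 90 percent correct), unconscious
#' animals essentially never respond, and the intermediate recovery state
#' responds intermittently.
#'
#' @return list with named numeric vectors `p_engage` and
#'   `p_correct_given_engaged` (one entry per state label).
#' @export
default_behavior_probs <- function() {
  list(
    p_engage = c(awake = 0.99, induction = 0.70, unconscious = 0.02,
                 intermediate = 0.50, recovered = 0.995, post_antagonist = 0.995),
    p_correct_given_engaged = c(awake = 0.99, induction = 0.80,
                                unconscious = 0.50, intermediate = 0.70,
                                recovered = 0.995, post_antagonist = 0.995)
  )
}
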