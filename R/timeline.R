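#' Behavioral state timeline
#'
#' A `state_timeline` is an ordered, contiguous, non-overlapping set of
#' labeled segments describing the latent behavioral state of a session:
#' `awake`, `induction`, `unconscious`, `intermediate`, `recovered` or
#' `post_antagonist`. It is the ground truth against which behavioral
#' endpoint detection and state-space structure are validated.
#'
#' @param state character vector of state labels.
#' @param start_s,end_s segment bounds in seconds from session start;
#'   intervals are half-open `[start_s, end_s)`.
#' @return A data frame of class `state_timeline` with columns
#'   `state`, `start_s`, `end_s`.
#' @examples
#' state_timeline(c("awake", "unconscious", "recovered"),
#'                c(0, 600, 2400), c(600, 2400, 4200))
#' @export
state_timeline <- function(state, start_s, end_s) {
  known <- c("awake", "induction", "unconscious", "intermediate",
             "recovered", "post_antagonist")
  if (length(state) == 0L) stop("timeline must contain at least one segment")
  if (!all(state %in% known)) {
    stop("unknown state label(s): ", paste(setdiff(state, known), collapse = ", "))
  }
  if (length(state) != length(start_s) || length(state) != length(end_s)) {
    stop("state, start_s and end_s must have equal length")
  }
  if (any(end_s <= start_s)) stop("each segment must satisfy start_s < end_s")
  if (state[1L] != "awake") stop("first timeline state must be 'awake'")
  if (start_s[1L] != 0) stop("timeline must start at 0 s")
  if (length(state) > 1L &&
      any(abs(start_s[-1L] - end_s[-length(end_s)]) > 1e-9)) {
    stop("timeline segments must be contiguous and non-overlapping")
  }
  out <- data.frame(state = state, start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s), stringsAsFactors = FALSE)
  class(out) <- c("state_timeline", class(out))
  out
}

#' Default session timeline
#'
#' 10 min awake baseline, 60 min infusion (5 min induction then
#' unconsciousness) and 60 min recovery through an intermediate state,
#' mirroring a typical gradual-emergence session.
#'
#' @return A [state_timeline()].
#' @export
default_timeline <- function() {
  state_timeline(
    state   = c("awake", "induction", "unconscious", "intermediate", "recovered"),
    start_s = c(0,       600,         900,           4200,           5400),
    end_s   = c(600,     900,         4200,          5400,           7800)
  )
}

#' Antagonist-mode session timeline
#'
#' Awake baseline, induction, unconsciousness, then an instantaneous switch
#' to awake-like dynamics at `antagonist_s` (alpha-2 antagonist bolus while
#' the agonist is still infusing); no intermediate state.
#'
#' @param antagonist_s bolus time in seconds.
#' @param end_s session end in seconds.
#' @return A [state_timeline()].
#' @export
antagonist_timeline <- function(antagonist_s = 2400, end_s = 4200) {
  state_timeline(
    state   = c("awake", "induction", "unconscious", "post_antagonist"),
    start_s = c(0, 600, 900, antagonist_s),
    end_s   = c(600, 900, antagonist_s, end_s)
  )
}

#' State active at given times
#'
#' @param timeline a [state_timeline()].
#' @param t_s numeric vector of times (seconds).
#' @return character vector of state labels (`NA` outside the timeline).
#' @export
state_at <- function(timeline, t_s) {
  stopifnot(inherits(timeline, "state_timeline"))
  idx <- findInterval(t_s, timeline$start_s)
  out <- rep(NA_character_, length(t_s))
  ok <- idx >= 1L & t_s < timeline$end_s[pmax(idx, 1L)]
  out[ok] <- timeline$state[idx[ok]]
  out
}

#' Timeline duration in seconds
#' @param timeline a [state_timeline()].
#' @return numeric scalar.
#' @export
timeline_duration <- function(timeline) {
  stopifnot(inherits(timeline, "state_timeline"))
  max(timeline$end_s)
}

#' Anesthetic infusion schedule
#'
#' @param rate_ug_per_kg_per_h infusion rates, one per segment; must be >= 0.
#' @param start_min,end_min segment bounds in minutes from infusion start.
#' @param antagonist optional list with `time_min` and `dose_ug_per_kg`
#'   describing an antagonist bolus; must not precede the infusion.
#' @return A list of class `infusion_schedule`.
#' @examples
#' infusion_schedule(c(18, 4), c(0, 10), c(10, 60))
#' @export
infusion_schedule <- function(rate_ug_per_kg_per_h, start_min, end_min,
                              antagonist = NULL) {
  if (any(rate_ug_per_kg_per_h < 0)) stop("infusion rates must be >= 0")
  if (any(end_min <= start_min)) stop("schedule segments need start < end")
  if (is.unsorted(start_min, strictly = TRUE)) stop("schedule segments must be ordered")
  if (!is.null(antagonist)) {
    stopifnot(is.list(antagonist), !is.null(antagonist$time_min))
    if (antagonist$time_min < min(start_min)) {
      stop("antagonist bolus must fall within or after the infusion")
    }
  }
  structure(list(
    segments = data.frame(rate_ug_per_kg_per_h = rate_ug_per_kg_per_h,
                          start_min = start_min, end_min = end_min),
    antagonist = antagonist
  ), class = "infusion_schedule")
}

#' Default infusion schedule
#'
#' 60-min dexmedetomidine infusion: 18 ug/kg/h for the first 10 min, then
#' 4 ug/kg/h for 50 min.
#'
#' @param antagonist optional antagonist bolus, as in [infusion_schedule()].
#' @return An [infusion_schedule()].
#' @export
default_infusion_schedule <- function(antagonist = NULL) {
  infusion_schedule(c(18, 4), c(0, 10), c(10, 60), antagonist = antagonist)
}

#' Total infusion span in minutes
#' @param schedule an [infusion_schedule()].
#' @return numeric scalar, minutes from first segment start to last end.
#' @export
infusion_span_min <- function(schedule) {
  stopifnot(inherits(schedule, "infusion_schedule"))
  max(schedule$segments$end_min) - min(schedule$segments$start_min)
}
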