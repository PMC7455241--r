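#' Write a session container to disk
#'
#' Plain-format container: per-region signal matrices as little-endian
#' IEEE doubles (`<region>.bin`, column-major samples x channels) with a
#' JSON metadata sidecar (`meta.json`: sampling rate, dimensions, channel
#' names, timeline, schedule, seed), the trial log as CSV and the
#' ground-truth spindle log as CSV.
#'
#' @param session an `lfp_session` (see [generate_session()]).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "lfp_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rec <- session$recording
  meta <- list(
    fs = rec$fs,
    regions = lapply(rec$signals, function(m) {
      list(n_samples = nrow(m), n_channels = ncol(m),
           channel_names = colnames(m))
    }),
    timeline = as.data.frame(session$timeline),
    schedule = list(segments = rec$schedule$segments,
                    antagonist = rec$schedule$antagonist),
    seed = session$seed
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (r in names(rec$signals)) {
    con <- file(file.path(path, paste0(r, ".bin")), "wb")
    writeBin(as.numeric(rec$signals[[r]]), con, size = 8L, endian = "little")
    close(con)
  }
  if (!is.null(session$trials)) {
    utils::write.csv(session$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
  }
  if (!is.null(session$ground_truth_spindles)) {
    utils::write.csv(session$ground_truth_spindles,
                     file.path(path, "spindles.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session container
#'
#' Fails closed: any size mismatch between the metadata sidecar and the
#' binary payload raises a parse error naming the offending file, rather
#' than returning partial data.
#'
#' @param path directory written by [write_session()].
#' @return an `lfp_session`.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("malformed container: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  signals <- list()
  for (r in names(meta$regions)) {
    info <- meta$regions[[r]]
    bin_path <- file.path(path, paste0(r, ".bin"))
    if (!file.exists(bin_path)) stop("malformed container: missing ", bin_path)
    n_expect <- info$n_samples * info$n_channels
    if (file.info(bin_path)$size != n_expect * 8L) {
      stop("malformed container: ", bin_path, " has ",
           file.info(bin_path)$size, " bytes, expected ", n_expect * 8L)
    }
    con <- file(bin_path, "rb")
    vals <- readBin(con, "numeric", n = n_expect, size = 8L, endian = "little")
    close(con)
    m <- matrix(vals, info$n_samples, info$n_channels)
    colnames(m) <- info$channel_names
    signals[[r]] <- m
  }
  tl <- meta$timeline
  timeline <- state_timeline(tl$state, tl$start_s, tl$end_s)
  antag <- meta$schedule$antagonist
  if (is.null(antag) || length(antag) == 0L) antag <- NULL
  sched <- infusion_schedule(meta$schedule$segments$rate_ug_per_kg_per_h,
                             meta$schedule$segments$start_min,
                             meta$schedule$segments$end_min,
                             antagonist = antag)
  trials <- NULL
  tp <- file.path(path, "trials.csv")
  if (file.exists(tp)) {
    trials <- utils::read.csv(tp)
    trials$outcome <- factor(trials$outcome,
                             levels = c("correct", "failed_attempt",
                                        "no_response"))
  }
  gt <- NULL
  sp <- file.path(path, "spindles.csv")
  if (file.exists(sp)) gt <- utils::read.csv(sp)
  structure(list(
    recording = list(signals = signals, fs = meta$fs, schedule = sched),
    trials = trials, timeline = timeline, ground_truth_spindles = gt,
    seed = meta$seed
  ), class = "lfp_session")
}

#' Run the full analysis pipeline on a session
#'
#' Chains every stage on one session: line-noise removal, behavioral
#' probabilities and LOC/ROC/ROPAP endpoints, per-region multitaper
#' spectrograms and condition-epoch Welch spectra, spindle detection and
#' period summaries, the 3-D spectral-ratio state-space embedding with
#' trajectory metrics from LOC to session end, and a JSON-serializable
#' manifest (parameters, seed, config hash) for provenance.
#'
#' @param session an `lfp_session`.
#' @param spectral_cfg a [spectral_config()].
#' @param endpoint_cfg an [endpoint_config()].
#' @param n_trials_window behavior estimator window (trials).
#' @param out_dir optional directory; when given, stage outputs are written
#'   (CSV/JSON) as they are produced.
#' @param verbose log stage progress via `message()`.
#' @return list of class `pipeline_result` with `endpoints`, `probs`,
#'   `spectrograms`, `epoch_psd`, `spindles`, `spindle_summary`,
#'   `embedding`, `trajectory`, `manifest`.
#' @export
run_pipeline <- function(session, spectral_cfg = spectral_config(),
                         endpoint_cfg = endpoint_config(),
                         n_trials_window = 20, out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(session, "lfp_session"))
  say <- function(...) if (verbose) message("[dexstates] ", ...)
  rec <- session$recording
  fs <- rec$fs
  dur <- nrow(rec$signals[[1L]]) / fs
  if (is.null(session$trials) || nrow(session$trials) == 0L) {
    stop("pipeline stage 'endpoints': session has no trial log")
  }

  say("line-noise removal")
  clean <- lapply(rec$signals, remove_line_noise, fs = fs)

  say("behavioral endpoints")
  probs <- estimate_probabilities(session$trials, n_trials = n_trials_window,
                                  t_end_s = dur)
  endpoints <- detect_endpoints(probs, endpoint_cfg)

  say("spectrograms and epoch spectra")
  spectrograms <- lapply(clean, function(m) {
    multitaper_spectrogram(rowMeans(m), fs, spectral_cfg)
  })
  awake_epoch <- c(max(0, session$timeline$end_s[1L] - spectral_cfg$epoch_s),
                   session$timeline$end_s[1L])
  epoch_psd <- lapply(clean, epoch_psd_with_ci, fs = fs, epoch = awake_epoch,
                      cfg = spectral_cfg)

  say("spindle detection")
  base_int <- c(session$timeline$start_s[1L], session$timeline$end_s[1L])
  sp_params <- spindle_params(baseline = base_int)
  spindles <- do.call(rbind, lapply(names(clean), function(r) {
    m <- clean[[r]]
    do.call(rbind, lapply(seq_len(ncol(m)), function(ch) {
      ev <- detect_spindles(m[, ch], fs, sp_params)
      if (nrow(ev) == 0L) return(NULL)
      data.frame(region = r, channel = colnames(m)[ch], ev)
    }))
  }))
  spindle_summary <- NULL
  if (!is.null(spindles) && nrow(spindles) > 0L) {
    periods <- data.frame(label = session$timeline$state,
                          start_s = session$timeline$start_s,
                          end_s = session$timeline$end_s)
    spindle_summary <- summarize_spindles(spindles, periods)
  }

  say("state-space embedding")
  first_region <- clean[[1L]]
  ratios <- compute_spectral_ratios(first_region, fs)
  span0 <- if (!is.na(endpoints$loc_s)) endpoints$loc_s else 0
  span_idx <- which(ratios$times_s >= span0)
  embedding <- embed_pc1(ratios, span_idx = span_idx)
  trajectory <- trajectory_metrics(embedding, probs)

  manifest <- list(
    seed = session$seed,
    fs = fs, duration_s = dur,
    regions = lapply(rec$signals, ncol),
    spectral_cfg = unclass(spectral_cfg),
    endpoint_cfg = unclass(endpoint_cfg),
    n_trials_window = n_trials_window,
    package_version = as.character(utils::packageVersion("dexstates"))
  )
  tf <- tempfile(); saveRDS(manifest, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  out <- structure(list(endpoints = endpoints, probs = probs,
                        spectrograms = spectrograms, epoch_psd = epoch_psd,
                        spindles = spindles, spindle_summary = spindle_summary,
                        embedding = embedding, trajectory = trajectory,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(loc_s = endpoints$loc_s, roc_s = endpoints$roc_s,
                              ropap_s = endpoints$ropap_s),
                         file.path(out_dir, "endpoints.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(trajectory),
                     file.path(out_dir, "trajectory.csv"), row.names = FALSE)
    if (!is.null(spindles)) {
      utils::write.csv(spindles, file.path(out_dir, "spindles.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
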