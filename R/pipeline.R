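#' Default analysis configuration
#'
#' Returns every tunable constant of the analysis chain with its standard
#' value: 12 +/- 1 s ISI, 3 s quiet period, 1.5 s reward window, ~50-trial
#' blocks; 100 s noise-model blocks, 5 SD / 0.05 Hz activity filter,
#' stimulus-triggered windows -300..0 / 0..200 ms and lick-triggered
#' -800..-500 / -100..100 ms, 15-trial and 5-neuron decoder minima with
#' -1000..0 and 0..200 ms decoding windows; 2 x SD jaw onset threshold with
#' -2000..0 ms pooled baseline, -500 ms stimulus cutoff and 1500 ms
#' isolation; 5-frame dF/F baseline, 0..100 / 100..200 ms response windows
#' and sigma = 3 px smoothing; 0.5 mm stimulation grid, 100/250 ms
#' pre-stimulation baselines with 2 deg / 0.75 deg inclusion thresholds,
#' 4 ms vs 200 ms evoked-movement windows and the 50%-of-maximum centroid
#' threshold.
#'
#' @return a nested named list, serializable to JSON.
#' @export
default_config <- function() {
  list(
    session = list(isi_mean_s = 12, isi_sd_s = 1, quiet_period_s = 3,
                   reward_window_s = 1.5, block_length_trials = 50L),
    calcium = list(block_s = 100, threshold_sd = 5, min_rate_hz = 0.05,
                   stim_baseline_ms = c(-300, 0), stim_response_ms = c(0, 200),
                   lick_baseline_ms = c(-800, -500),
                   lick_response_ms = c(-100, 100),
                   alpha_default = 0.38, min_events = 15L),
    decoder = list(min_trials = 15L, min_neurons = 5L,
                   pre_window_ms = c(-1000, 0), post_window_ms = c(0, 200)),
    jaw = list(k_sd = 2, gap_ms = 1500, baseline_ms = 2000,
               stim_cutoff_ms = 500),
    widefield = list(n_baseline_frames = 5L, early_ms = c(0, 100),
                     late_ms = c(100, 200), smooth_sigma_px = 3),
    motormap = list(grid_spacing_mm = 0.5,
                    baseline_s = list(whisker = 0.1, jaw = 0.25),
                    include_sd_deg = list(whisker = 2, jaw = 0.75),
                    evoked_pre_ms = 4, evoked_response_ms = 200,
                    centroid_threshold_frac = 0.5)
  )
}

#' Validate a trial table
#'
#' Schema and sanity checks used before any analysis stage: required
#' columns, monotone non-negative stimulus times, parseable lick lists with
#' no event before session start, and (for multimotor sessions) a usable
#' `block_side` column.
#'
#' @param trials a trial table data.frame.
#' @param task optional task name to check block information against.
#' @return character vector of issues (length 0 when clean).
#' @export
validate_inputs <- function(trials, task = NULL) {
  issues <- character(0)
  need <- c("trial_id", "type", "stim_time_s",
            "lick_times_right", "lick_times_left")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (any(!trials$type %in% c("whisker", "auditory", "catch"))) {
    issues <- c(issues, "unknown trial type")
  }
  st <- trials$stim_time_s
  if (any(!is.finite(st)) || any(st < 0) || any(diff(st) <= 0)) {
    issues <- c(issues, "nonmonotonic/negative stimulus time")
  }
  for (col in c("lick_times_right", "lick_times_left")) {
    lt <- unlist(lapply(trials[[col]], split_times))
    if (any(!is.finite(lt)) || any(lt < 0)) {
      issues <- c(issues, "nonmonotonic/negative event time")
      break
    }
  }
  if (identical(task, "multimotor") &&
      (!"block_side" %in% names(trials) ||
       !any(trials$block_side %in% c("right", "left")))) {
    issues <- c(issues, "trial table missing block_side for multimotor task")
  }
  issues
}

#' Run the analysis chain end to end on a synthetic session
#'
#' Orchestrates synthesis, behavior classification, calcium conditioning
#' (neuropil correction, noise model, z-scoring, activity filter), decoder
#' fitting on spontaneous licks and evaluation in both decoding windows, and
#' jaw-movement onset detection.  All stages draw their randomness from
#' streams derived from `seed`, so a run is reproducible end to end.
#'
#' @param session_cfg a [session_config()].
#' @param calcium_cfg a [calcium_config()].
#' @param jaw_params optional named list of [generate_jaw()] arguments.
#' @param seed master seed; overrides the seeds in the two configs.
#' @param stages character subset of `c("behavior", "calcium", "decode",
#'   "jaw")` to run after synthesis.
#' @return object of class `run_report`: per-stage results and headline
#'   metrics (`hit_rate`, `n_kept_neurons`, `performance_pre`,
#'   `performance_post`, `n_jaw_onsets`), plus the seed and configs.
#' @export
run_pipeline <- function(session_cfg = session_config(),
                         calcium_cfg = calcium_config(),
                         jaw_params = list(),
                         seed = session_cfg$seed,
                         stages = c("behavior", "calcium", "decode", "jaw")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("decode" %in% stages && !"calcium" %in% stages) {
    stop_config("stage 'decode' requires stage 'calcium'")
  }
  session_cfg$seed <- as.integer(seed)
  calcium_cfg$seed <- as.integer(seed)
  report <- list(seed = seed, config = list(session = session_cfg,
                                            calcium = calcium_cfg))

  ses <- generate_session(session_cfg)
  issues <- validate_inputs(ses$trials, task = session_cfg$task)
  if (length(issues)) stop_config("generated session invalid: %s",
                                  paste(issues, collapse = "; "))
  report$n_trials <- nrow(ses$trials)

  trials <- ses$trials
  if ("behavior" %in% stages) {
    trials <- classify_trials(trials, session_cfg$reward_window_s)
    report$behavior <- outcome_summary(trials)
    hr <- report$behavior$rates
    report$hit_rate <- hr$rate[hr$category == "whisker_hit"]
  }

  if ("calcium" %in% stages) {
    cal <- generate_calcium(calcium_cfg, trials, ses$truth)
    fr <- calcium_cfg$frame_rate_hz
    z_list <- vector("list", length(cal$neurons))
    keep <- logical(length(cal$neurons))
    for (j in seq_along(cal$neurons)) {
      f <- neuropil_correct(cal$neurons[[j]])
      nm <- fit_noise_model(f, frame_rate_hz = fr)
      z_list[[j]] <- zscore_trace(f, nm)
      keep[j] <- filter_infrequent(z_list[[j]], frame_rate_hz = fr)$keep
    }
    report$n_kept_neurons <- sum(keep)
    report$calcium <- list(z = z_list, keep = keep, truth = cal$truth)
  }

  if ("decode" %in% stages) {
    spont <- ses$truth$spont_licks
    z_keep <- report$calcium$z[keep]
    responses <- lapply(z_keep, function(z) {
      al <- function(side) {
        ev <- spont$time_s[spont$side == side]
        if (length(ev) == 0) return(NULL)
        suppressWarnings(align_trace(z, ev, frame_rate_hz = fr,
                                     pre_ms = 800, post_ms = 200))
      }
      list(left = al("left"), right = al("right"))
    })
    dec <- compute_tuning(responses)
    report$decoder <- dec
    if (dec$status == "ok") {
      sel <- match(dec$neuron_ids, as.character(seq_along(responses)))
      z_mat <- do.call(rbind, z_keep[sel])
      perf <- decoder_performance_by_window(z_mat, trials, dec,
                                            frame_rate_hz = fr, seed = seed)
      report$decode <- perf
      report$performance_pre <- perf$pre$performance
      report$performance_post <- perf$post$performance
    }
  }

  if ("jaw" %in% stages) {
    jaw <- do.call(generate_jaw,
                   c(list(trials = trials, truth = ses$truth, seed = seed),
                     jaw_params))
    ev <- detect_onsets(motion_energy(jaw$position), trials,
                        frame_rate_hz = jaw$frame_rate_hz)
    report$jaw <- list(events = ev, truth = jaw$truth)
    report$n_jaw_onsets <- ev$n_events
  }

  report$trials <- trials
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  trials:       ", x$n_trials, "\n", sep = "")
  if (!is.null(x$hit_rate)) {
    cat(sprintf("  hit rate:      %.3f\n", x$hit_rate))
  }
  if (!is.null(x$n_kept_neurons)) {
    cat("  kept neurons: ", x$n_kept_neurons, "\n", sep = "")
  }
  if (!is.null(x$performance_pre)) {
    cat(sprintf("  decoder:       pre %.3f / post %.3f\n",
                x$performance_pre, x$performance_post))
  }
  if (!is.null(x$n_jaw_onsets)) {
    cat("  jaw onsets:   ", x$n_jaw_onsets, "\n", sep = "")
  }
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serializes the headline metrics, seed and resolved parameters of a
#' pipeline run to JSON next to the outputs, for provenance.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    seed = report$seed,
    n_trials = report$n_trials,
    hit_rate = report$hit_rate,
    n_kept_neurons = report$n_kept_neurons,
    performance_pre = report$performance_pre,
    performance_post = report$performance_post,
    n_jaw_onsets = report$n_jaw_onsets,
    session_config = unclass(report$config$session),
    calcium_config = unclass(report$config$calcium)
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
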