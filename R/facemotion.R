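#' Frame-to-frame motion signal of a jaw trace
#'
#' Jaw movement is quantified from the mean pixel value of a jaw ROI by
#' taking the difference between consecutive frames; the motion signal is
#' one sample shorter than the position trace.
#'
#' @param position per-frame ROI-mean jaw position (a.u.).
#' @return numeric motion signal, `diff(position)`.
#' @export
motion_energy <- function(position) {
  if (length(position) < 2) stop("need at least two frames", call. = FALSE)
  diff(position)
}

#' Detect isolated small jaw-movement onsets
#'
#' Thresholds the motion signal at `k_sd` times the standard deviation of
#' motion pooled over all trials' pre-stimulus epochs (-2000..0 ms relative
#' to each stimulus, over the entire session).  An onset is the first
#' supra-threshold sample of each excursion (maximal run above threshold).
#' During stimulus trials only times up to -500 ms before the stimulus are
#' eligible (and, by default, nothing until `post_guard_s` after it, so
#' stimulus- and lick-evoked movement does not masquerade as spontaneous).
#' Onsets are then thinned greedily left to right so that consecutive onsets
#' are at least `gap_ms` apart.
#'
#' @param motion motion signal from [motion_energy()].
#' @param trials trial table supplying stimulus times.
#' @param frame_rate_hz camera frame rate (Hz).
#' @param k_sd threshold multiplier (default 2).
#' @param gap_ms isolation gap between onsets (default 1500 ms).
#' @param baseline_ms pooled-SD epoch before each stimulus (default 2000 ms).
#' @param stim_cutoff_ms eligibility ends this long before each stimulus
#'   (default 500 ms).
#' @param post_guard_s eligibility resumes this long after each stimulus
#'   (default 3 s).
#' @return list of class `movement_events`: `onsets_s`, `threshold`,
#'   `gap_ms`, `n_events`.
#' @export
detect_onsets <- function(motion, trials, frame_rate_hz = 200, k_sd = 2,
                          gap_ms = 1500, baseline_ms = 2000,
                          stim_cutoff_ms = 500, post_guard_s = 3) {
  n <- length(motion)
  stim <- trials$stim_time_s
  if (length(stim) == 0) stop("no pre-stimulus epochs available", call. = FALSE)
  # pooled pre-stimulus SD
  pooled <- c()
  for (t0 in stim) {
    i0 <- max(1L, round((t0 - baseline_ms / 1000) * frame_rate_hz) + 1L)
    i1 <- min(n, round(t0 * frame_rate_hz))
    if (i1 >= i0) pooled <- c(pooled, motion[i0:i1])
  }
  if (length(pooled) == 0) stop("no pre-stimulus epochs available", call. = FALSE)
  threshold <- k_sd * stats::sd(pooled)

  # eligibility mask: everything except [stim - cutoff, stim + guard]
  allowed <- rep(TRUE, n)
  stim_trials <- stim[trials$type != "catch"]
  for (t0 in stim_trials) {
    i0 <- max(1L, round((t0 - stim_cutoff_ms / 1000) * frame_rate_hz) + 1L)
    i1 <- min(n, round((t0 + post_guard_s) * frame_rate_hz))
    if (i1 >= i0) allowed[i0:i1] <- FALSE
  }

  above <- motion > threshold
  starts <- which(above & !c(FALSE, above[-n]))  # first sample of each run
  starts <- starts[allowed[starts]]
  onset_t <- (starts - 1L) / frame_rate_hz

  # greedy left-to-right isolation-gap enforcement
  gap_s <- gap_ms / 1000
  kept <- numeric(0)
  last <- -Inf
  for (t0 in onset_t) {
    if (t0 - last >= gap_s) {
      kept <- c(kept, t0)
      last <- t0
    }
  }
  out <- list(onsets_s = kept, threshold = threshold, gap_ms = gap_ms,
              n_events = length(kept))
  class(out) <- "movement_events"
  out
}

#' @export
print.movement_events <- function(x, ...) {
  cat(sprintf("%d isolated movement onsets (threshold %.3g, gap %g ms)\n",
              x$n_events, x$threshold, x$gap_ms))
  invisible(x)
}

#' Jaw-movement ratio in catch trials under optogenetic inactivation
#'
#' For every correct-rejection catch trial, computes the SD of the jaw
#' position over the catch window (starting at the virtual stimulus time)
#' and over the immediately preceding baseline window of equal length, and
#' forms the ratio `SD_catch / SD_baseline`.  Ratios are averaged separately
#' for light-off and light-on trials.  Under the null (identical statistics
#' in both windows) the expected ratio is 1; suppression of small movements
#' during the light pushes the light-on ratio below the light-off ratio.
#'
#' @param position jaw position trace (a.u.).
#' @param trials classified trial table; only rows with
#'   `outcome == "correct_rejection"` are used.
#' @param frame_rate_hz camera frame rate (Hz).
#' @param window_s catch/baseline window length (s); defaults to the light
#'   stimulus duration used in inactivation experiments (1.5 s).
#' @return list of class `inactivation_metric`: `per_trial` (data.frame with
#'   `trial_id`, `light_on`, `sd_catch`, `sd_baseline`, `ratio`),
#'   `mean_ratio` (named: `light_off`, `light_on`; NA when absent).
#' @export
inactivation_ratio <- function(position, trials, frame_rate_hz = 200,
                               window_s = 1.5) {
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  cr <- trials[trials$outcome == "correct_rejection", , drop = FALSE]
  if (nrow(cr) == 0) {
    stop("no correct-rejection catch trials", call. = FALSE)
  }
  n <- length(position)
  w <- round(window_s * frame_rate_hz)
  rows <- list()
  for (i in seq_len(nrow(cr))) {
    c0 <- round(cr$stim_time_s[i] * frame_rate_hz) + 1L
    c1 <- c0 + w - 1L
    b0 <- c0 - w
    b1 <- c0 - 1L
    if (b0 < 1L || c1 > n) next
    sdc <- stats::sd(position[c0:c1])
    sdb <- stats::sd(position[b0:b1])
    rows[[length(rows) + 1L]] <-
      data.frame(trial_id = cr$trial_id[i], light_on = cr$light_on[i],
                 sd_catch = sdc, sd_baseline = sdb, ratio = sdc / sdb)
  }
  per_trial <- do.call(rbind, rows)
  if (is.null(per_trial)) stop("no catch trial fits inside the trace",
                               call. = FALSE)
  mr <- c(light_off = mean(per_trial$ratio[!per_trial$light_on]),
          light_on = mean(per_trial$ratio[per_trial$light_on]))
  mr[c(sum(!per_trial$light_on), sum(per_trial$light_on)) == 0] <- NA_real_
  out <- list(per_trial = per_trial, mean_ratio = mr)
  class(out) <- "inactivation_metric"
  out
}

#' @export
print.inactivation_metric <- function(x, ...) {
  cat(sprintf("SD_catch/SD_baseline over %d correct-rejection trials\n",
              nrow(x$per_trial)))
  print(round(x$mean_ratio, 3))
  invisible(x)
}

#' Correlate spout-contact tuning with block tuning during jaw movements
#'
#' Across neurons with significant spontaneous-lick responses, correlates
#' the right-minus-left spout-contact response difference with the
#' right-minus-left block difference of responses aligned to small jaw
#' movements.  A positive correlation indicates that the same neurons that
#' prefer one lick direction are also more active during preparatory jaw
#' movements in the corresponding block.
#'
#' @param contact_diff per-neuron right-minus-left spout-contact response (z).
#' @param block_diff per-neuron right-minus-left block response during small
#'   jaw movements (z).
#' @return list with `r` (Pearson), `p`, `n`.
#' @export
block_tuning_correlation <- function(contact_diff, block_diff) {
  stopifnot(length(contact_diff) == length(block_diff))
  ok <- is.finite(contact_diff) & is.finite(block_diff)
  if (sum(ok) < 3) stop("need at least 3 neurons", call. = FALSE)
  ct <- stats::cor.test(contact_diff[ok], block_diff[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
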