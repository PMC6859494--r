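# Shared fixture builders (everything is generated in code at test time).

# A session with no licking at all: clean background for detector tests.
quiet_session <- function(n_trials = 40, seed = 1) {
  generate_session(session_config(
    n_trials = n_trials, task = "multisensory", p_catch = 0,
    hit_prob = 0, fa_prob = 0, spont_rate_hz = 0, seed = seed))
}

# Build a minimal trial table by hand.
trial_row <- function(trial_id = 1L, type = "whisker", block_side = "none",
                      stim_time_s = 10, light_on = FALSE,
                      licks_right = numeric(0), licks_left = numeric(0),
                      is_associative = FALSE) {
  data.frame(trial_id = trial_id, type = type, block_side = block_side,
             stim_time_s = stim_time_s, light_on = light_on,
             lick_times_right = cortilick:::join_times(licks_right),
             lick_times_left = cortilick:::join_times(licks_left),
             is_associative = is_associative, stringsAsFactors = FALSE)
}

# An aligned_responses object built directly from a trials x time matrix on a
# regular grid (for responsiveness/tuning tests with controlled content).
aligned_from_matrix <- function(mat, frame_rate_hz = 30, t0_ms = -1000) {
  structure(list(mat = mat,
                 time_ms = t0_ms + (seq_len(ncol(mat)) - 1L) /
                   frame_rate_hz * 1000,
                 event_times_s = seq_len(nrow(mat)),
                 frame_rate_hz = frame_rate_hz),
            class = "aligned_responses")
}

# Brute-force two-class decoder oracle: explicit per-neuron sum of
# r * log(f + eps); returns decisions with ties marked NA and the raw
# left/right log-likelihood difference as attribute "diff".
oracle_decode <- function(tuning, activity, eps) {
  n_tr <- nrow(activity)
  out <- character(n_tr)
  diffs <- numeric(n_tr)
  for (t in seq_len(n_tr)) {
    ll <- c(left = 0, right = 0)
    for (d in c("left", "right")) {
      s <- 0
      for (j in seq_len(nrow(tuning))) {
        s <- s + activity[t, j] * log(max(tuning[j, d], 0) + eps)
      }
      ll[d] <- s
    }
    diffs[t] <- ll[["right"]] - ll[["left"]]
    out[t] <- if (ll["right"] == ll["left"]) NA_character_ else
      if (ll["right"] > ll["left"]) "right" else "left"
  }
  attr(out, "diff") <- diffs
  out
}

# Brute-force onset-detection oracle: scan every sample with explicit
# eligibility and gap bookkeeping.
oracle_onsets <- function(motion, threshold, allowed, frame_rate_hz, gap_s) {
  onsets <- numeric(0)
  last <- -Inf
  prev_above <- FALSE
  for (i in seq_along(motion)) {
    above <- motion[i] > threshold
    if (above && !prev_above && allowed[i]) {
      t0 <- (i - 1) / frame_rate_hz
      if (t0 - last >= gap_s) {
        onsets <- c(onsets, t0)
        last <- t0
      }
    }
    prev_above <- above
  }
  onsets
}

# Hand-coded outcome oracle for the exhaustive truth-table tests: outcome as
# a function of task, trial type, rewarded side and the in-window lick
# pattern (first in-window lick time per spout, Inf when none).
oracle_outcome <- function(task, type, block_side, first_r, first_l,
                           is_associative = FALSE) {
  if (is_associative) return("excluded")
  any_lick <- is.finite(first_r) || is.finite(first_l)
  if (type == "catch") {
    return(if (any_lick) "false_alarm" else "correct_rejection")
  }
  if (task == "multisensory") return(if (any_lick) "hit" else "miss")
  if (!any_lick) return("miss")
  first <- if (first_r < first_l) "right" else if (first_l < first_r) "left"
  else setdiff(c("right", "left"), block_side)   # tie -> error
  if (first == block_side) "hit" else paste0("error_", first)
}
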