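#' Configure a synthetic behavioral session
#'
#' Builds a validated configuration for [generate_session()].  Defaults follow
#' the head-fixed detection paradigms the package targets: interstimulus
#' intervals of 12 +/- 1 s, a 3 s pre-stimulus quiet period during which the
#' animal must withhold licking, a 1.5 s reward window, and (for the
#' multimotor task) a rewarded-spout side that alternates every ~50 trials.
#'
#' @param n_trials number of trials.
#' @param task `"multisensory"` (whisker/auditory/catch, single spout) or
#'   `"multimotor"` (whisker/catch, two spouts, block-switched reward side).
#' @param isi_mean_s,isi_sd_s mean and SD of the interstimulus interval draw
#'   (seconds).  Draws are floored so the quiet period is always respected.
#' @param quiet_period_s no-lick period required before each stimulus (s).
#' @param reward_window_s response window after stimulus onset (s).
#' @param block_length_trials trials per reward-side block (multimotor).
#' @param p_catch probability that a trial is a no-stimulus catch trial.
#'   Catch trials carry a virtual stimulus time drawn from the same ISI
#'   process.
#' @param p_auditory probability that a non-catch multisensory trial is
#'   auditory rather than whisker (ignored for multimotor).
#' @param hit_prob probability of licking in the reward window on a stimulus
#'   trial.
#' @param fa_prob probability of licking in the (virtual) reward window on a
#'   catch trial.
#' @param lick_latency_median_ms,lick_latency_sdlog first-lick latency model:
#'   log-normal with this median (ms) and log-scale SD, chosen for
#'   positivity and right skew.
#' @param switch_adapt_trials multimotor only: number of trials over which
#'   the animal re-learns the rewarded side after a block switch
#'   (exponential decay of perseverative errors).
#' @param error_prob multimotor only: asymptotic probability of licking the
#'   unrewarded spout first, well after a switch.
#' @param spont_rate_hz rate of spontaneous licks outside trial windows (Hz).
#'   Spontaneous licks never violate the quiet period (offending draws are
#'   discarded).
#' @param p_light fraction of trials with the optogenetic light flag set.
#' @param p_associative fraction of associative (auto-rewarded) trials; these
#'   are flagged and excluded from analysis downstream.
#' @param seed integer master seed; the behavioral schedule, calcium, jaw and
#'   imaging generators each draw from their own stream derived from it.
#' @return an object of class `session_config` (a validated list).
#' @seealso [generate_session()]
#' @export
session_config <- function(n_trials = 400L,
                           task = c("multimotor", "multisensory"),
                           isi_mean_s = 12, isi_sd_s = 1,
                           quiet_period_s = 3,
                           reward_window_s = 1.5,
                           block_length_trials = 50L,
                           p_catch = 0.15,
                           p_auditory = 0.5,
                           hit_prob = 0.69,
                           fa_prob = 0.2,
                           lick_latency_median_ms = 300,
                           lick_latency_sdlog = 0.35,
                           switch_adapt_trials = 10,
                           error_prob = 0.1,
                           spont_rate_hz = 0.06,
                           p_light = 0,
                           p_associative = 0,
                           seed = 1L) {
  task <- match.arg(task)
  if (!is.numeric(n_trials) || n_trials < 1) stop_config("n_trials must be >= 1")
  for (nm in c("p_catch", "p_auditory", "hit_prob", "fa_prob", "error_prob",
               "p_light", "p_associative")) {
    check_prob(get(nm), nm)
  }
  check_pos(isi_mean_s, "isi_mean_s", strict = TRUE)
  check_pos(isi_sd_s, "isi_sd_s")
  check_pos(quiet_period_s, "quiet_period_s")
  if (reward_window_s < 0) stop_config("reward_window_s must be non-negative")
  check_pos(lick_latency_median_ms, "lick_latency_median_ms", strict = TRUE)
  if (block_length_trials < 1) stop_config("block_length_trials must be >= 1")
  cfg <- list(n_trials = as.integer(n_trials), task = task,
              isi_mean_s = isi_mean_s, isi_sd_s = isi_sd_s,
              quiet_period_s = quiet_period_s,
              reward_window_s = reward_window_s,
              block_length_trials = as.integer(block_length_trials),
              p_catch = p_catch, p_auditory = p_auditory,
              hit_prob = hit_prob, fa_prob = fa_prob,
              lick_latency_median_ms = lick_latency_median_ms,
              lick_latency_sdlog = lick_latency_sdlog,
              switch_adapt_trials = switch_adapt_trials,
              error_prob = error_prob,
              spont_rate_hz = spont_rate_hz,
              p_light = p_light, p_associative = p_associative,
              seed = as.integer(seed))
  class(cfg) <- "session_config"
  cfg
}

#' Generate a synthetic behavioral session
#'
#' Draws a full trial table (stimulus identity and time, block side, per-spout
#' lick-time lists, light and associative flags) together with a ground-truth
#' record of the intended outcome of every trial, spontaneous lick times and
#' block-switch indices.  The quiet-period rule is enforced on the generated
#' lick stream: no lick falls within `quiet_period_s` before any stimulus
#' time.  Identical configurations (including the seed) yield identical
#' sessions.
#'
#' @param config a [session_config()].
#' @return a list with elements `trials` (data.frame, one row per trial with
#'   columns `trial_id`, `type`, `block_side`, `stim_time_s`, `light_on`,
#'   `lick_times_right`, `lick_times_left` (semicolon-joined seconds),
#'   `is_associative`) and `truth` (list: `outcome`, `first_lick_side`,
#'   `switch_trials`, `spont_licks`, `duration_s`, `config`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, "behavior"), {
    n <- cfg$n_trials
    # stimulus schedule: truncated-normal ISI, floored so consecutive trials
    # always leave room for the quiet period and reward window
    isi_floor <- cfg$quiet_period_s + cfg$reward_window_s + 1
    isi <- pmax(stats::rnorm(n, cfg$isi_mean_s, cfg$isi_sd_s), isi_floor)
    stim_time <- cumsum(isi) + cfg$quiet_period_s
    duration <- stim_time[n] + cfg$isi_mean_s

    # trial types
    is_catch <- stats::runif(n) < cfg$p_catch
    type <- rep("whisker", n)
    if (cfg$task == "multisensory") {
      aud <- !is_catch & stats::runif(n) < cfg$p_auditory
      type[aud] <- "auditory"
    }
    type[is_catch] <- "catch"

    # block schedule (multimotor): side alternates every block, starting right
    if (cfg$task == "multimotor") {
      blk <- ((seq_len(n) - 1L) %/% cfg$block_length_trials)
      block_side <- ifelse(blk %% 2L == 0L, "right", "left")
      switch_trials <- which(diff(blk) != 0L) + 1L
    } else {
      block_side <- rep("none", n)
      switch_trials <- integer(0)
    }

    light_on <- stats::runif(n) < cfg$p_light
    is_assoc <- stats::runif(n) < cfg$p_associative

    latency_s <- function(k) {
      stats::rlnorm(k, meanlog = log(cfg$lick_latency_median_ms / 1000),
                    sdlog = cfg$lick_latency_sdlog)
    }
    bout <- function(t0, n_extra = stats::rpois(1, 3)) {
      c(t0, t0 + cumsum(stats::runif(n_extra, 0.12, 0.16)))
    }

    lick_r <- vector("list", n)
    lick_l <- vector("list", n)
    outcome <- rep(NA_character_, n)
    first_side <- rep(NA_character_, n)
    trials_since_switch <- 0L

    for (i in seq_len(n)) {
      if (cfg$task == "multimotor") {
        trials_since_switch <-
          if (i %in% switch_trials) 1L else trials_since_switch + 1L
        if (i == 1L) trials_since_switch <- cfg$block_length_trials  # settled
      }
      t0 <- stim_time[i]
      licked <- if (type[i] == "catch") {
        stats::runif(1) < cfg$fa_prob
      } else {
        stats::runif(1) < cfg$hit_prob
      }
      if (licked) {
        lat <- latency_s(1)
        # latencies beyond the reward window become misses/CRs naturally
        t_first <- t0 + lat
        if (cfg$task == "multimotor") {
          # perseveration after a switch decays exponentially
          tau <- max(cfg$switch_adapt_trials / 2, 1e-6)
          p_correct <- (1 - cfg$error_prob) *
            (1 - exp(-trials_since_switch / tau))
          side <- if (stats::runif(1) < p_correct) block_side[i] else
            setdiff(c("right", "left"), block_side[i])
        } else {
          side <- "right"
        }
        times <- bout(t_first)
        if (side == "right") lick_r[[i]] <- times else lick_l[[i]] <- times
        first_side[i] <- side
      }
      outcome[i] <- NA  # assigned by behavior::classify_trials downstream
    }

    # spontaneous licks across the whole session, outside trial windows
    spont <- numeric(0)
    if (cfg$spont_rate_hz > 0) {
      n_sp <- stats::rpois(1, cfg$spont_rate_hz * duration)
      spont <- sort(stats::runif(n_sp, 0, duration))
    }
    # enforce the quiet period and keep spontaneous licks clear of the
    # stimulus/reward epochs
    keep <- rep(TRUE, length(spont))
    for (t0 in stim_time) {
      keep <- keep & !(spont >= t0 - cfg$quiet_period_s &
                         spont < t0 + cfg$reward_window_s + 1.5)
    }
    spont <- spont[keep]
    spont_side <- if (cfg$task == "multimotor") {
      idx <- findInterval(spont, stim_time) + 1L
      idx[idx > n] <- n
      cur <- block_side[pmax(idx, 1L)]
      ifelse(stats::runif(length(spont)) < 0.8, cur,
             ifelse(cur == "right", "left", "right"))
    } else {
      rep("right", length(spont))
    }

    # quiet-period enforcement on response licks (belt and braces: the ISI
    # floor already guarantees it)
    strip_quiet <- function(x) {
      if (length(x) == 0L) return(x)
      bad <- rep(FALSE, length(x))
      for (t0 in stim_time) bad <- bad | (x >= t0 - cfg$quiet_period_s & x < t0)
      x[!bad]
    }

    # fold spontaneous licks into the owning trial's lick list (trial i owns
    # licks from the midpoint with its neighbors)
    bounds <- c(0, stim_time[-n] + diff(stim_time) / 2, duration + 1)
    for (i in seq_len(n)) {
      in_i <- spont >= bounds[i] & spont < bounds[i + 1]
      add_r <- spont[in_i & spont_side == "right"]
      add_l <- spont[in_i & spont_side == "left"]
      lick_r[[i]] <- strip_quiet(sort(c(lick_r[[i]], add_r)))
      lick_l[[i]] <- strip_quiet(sort(c(lick_l[[i]], add_l)))
    }

    trials <- data.frame(
      trial_id = seq_len(n),
      type = type,
      block_side = block_side,
      stim_time_s = stim_time,
      light_on = light_on,
      lick_times_right = vapply(lick_r, join_times, character(1)),
      lick_times_left = vapply(lick_l, join_times, character(1)),
      is_associative = is_assoc,
      stringsAsFactors = FALSE
    )
    truth <- list(first_lick_side = first_side,
                  switch_trials = switch_trials,
                  spont_licks = data.frame(time_s = spont, side = spont_side,
                                           stringsAsFactors = FALSE),
                  duration_s = duration,
                  config = cfg)
    list(trials = trials, truth = truth)
  })
}

#' Configure the synthetic calcium generator
#'
#' Forward model for two-photon somatic traces: each neuron's clean signal is
#' a double-exponential calcium kernel convolved with an event train; tuned
#' neurons emit events time-locked to licks of their preferred side (with a
#' small motor lead, since motor cortical activity precedes tongue contact),
#' untuned neurons emit background Poisson events.  Neuropil contamination is
#' a shared low-pass-filtered Gaussian process added through each neuron's
#' true alpha coefficient (population mean 0.38, SD 0.30, as typical for
#' ring-based surround estimates), so that subtracting `alpha * surround`
#' restores the clean trace exactly.
#'
#' @param n_neurons number of neurons.
#' @param frac_left_tuned,frac_right_tuned,frac_untuned tuning-class
#'   fractions; must sum to 1.
#' @param transient_amplitude peak transient amplitude (fluorescence a.u.).
#' @param kernel_tau_rise_ms,kernel_tau_decay_ms kernel time constants (ms).
#' @param noise_sd white-noise SD on the somatic trace (a.u.).
#' @param baseline_f0 somatic baseline fluorescence (a.u.).
#' @param alpha_mean,alpha_sd population distribution of the neuropil
#'   coefficient (truncated at 0).
#' @param contaminant_sd SD of the shared surround contaminant (a.u.).
#' @param event_reliability probability that a preferred-side lick triggers a
#'   transient.
#' @param motor_lead_ms lead of the neural event before tongue contact (ms).
#' @param background_rate_hz Poisson event rate of untuned neurons (Hz); also
#'   added to tuned neurons at a quarter rate.
#' @param preparatory_rate_hz extra Poisson event rate for tuned neurons while
#'   the session is in their preferred block (models preparatory activity in
#'   tongue-jaw motor cortex; 0 disables, as appropriate for a sensory area).
#' @param untuned_lick_responsive if TRUE, untuned neurons respond to licks of
#'   both sides equally (lick-responsive but direction-unselective, as in a
#'   sensory area); if FALSE (default) they emit only background events.
#' @param stim_amplitude amplitude of an untuned stimulus-locked response
#'   shared by all neurons (models a sensory area; 0 disables).
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param seed integer seed for the calcium stream.
#' @return an object of class `calcium_config`.
#' @export
calcium_config <- function(n_neurons = 20L,
                           frac_left_tuned = 0.4,
                           frac_right_tuned = 0.4,
                           frac_untuned = 0.2,
                           transient_amplitude = 30,
                           kernel_tau_rise_ms = 50,
                           kernel_tau_decay_ms = 500,
                           noise_sd = 5,
                           baseline_f0 = 100,
                           alpha_mean = 0.38,
                           alpha_sd = 0.30,
                           contaminant_sd = 10,
                           event_reliability = 0.9,
                           motor_lead_ms = 100,
                           background_rate_hz = 0.1,
                           preparatory_rate_hz = 0,
                           untuned_lick_responsive = FALSE,
                           stim_amplitude = 0,
                           frame_rate_hz = 30,
                           seed = 1L) {
  fr <- c(frac_left_tuned, frac_right_tuned, frac_untuned)
  if (abs(sum(fr) - 1) > 1e-8) stop_config("tuning fractions must sum to 1")
  if (n_neurons < 1) stop_config("n_neurons must be >= 1")
  check_pos(kernel_tau_rise_ms, "kernel_tau_rise_ms", strict = TRUE)
  check_pos(kernel_tau_decay_ms, "kernel_tau_decay_ms", strict = TRUE)
  check_pos(frame_rate_hz, "frame_rate_hz", strict = TRUE)
  check_pos(noise_sd, "noise_sd")
  cfg <- as.list(environment())
  cfg$fr <- NULL
  class(cfg) <- "calcium_config"
  cfg
}

# double-exponential calcium kernel sampled on the frame grid, peak 1
calcium_kernel <- function(tau_rise_s, tau_decay_s, frame_rate_hz,
                           length_s = 6 * tau_decay_s) {
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  k <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  if (max(k) > 0) k <- k / max(k)
  k
}

# superpose one kernel per event on the frame grid (sparse event trains make
# direct placement much cheaper than convolution)
events_to_trace <- function(event_times, n_frames, frame_rate_hz, kernel) {
  tr <- numeric(n_frames)
  idx <- round(event_times * frame_rate_hz) + 1L
  idx <- idx[idx >= 1L & idx <= n_frames]
  k <- length(kernel)
  for (i in idx) {
    j <- i:min(n_frames, i + k - 1L)
    tr[j] <- tr[j] + kernel[seq_along(j)]
  }
  tr
}

#' Generate synthetic calcium traces for a session
#'
#' @param config a [calcium_config()].
#' @param trials trial table from [generate_session()].
#' @param truth ground-truth record from [generate_session()].
#' @return a list with `neurons` (list; each has `f_soma`, `f_surround`,
#'   `alpha`, `frame_rate_hz`, `class`) and `truth` (per-neuron event times,
#'   tuning class, clean signal, the shared contaminant).
#' @export
generate_calcium <- function(config, trials, truth) {
  stopifnot(inherits(config, "calcium_config"))
  cfg <- config
  if (cfg$n_neurons < 1) stop_config("zero neurons requested")
  duration <- truth$duration_s
  fr <- cfg$frame_rate_hz
  n_frames <- ceiling(duration * fr)
  with_seed(derive_seed(cfg$seed, "calcium"), {
    n <- cfg$n_neurons
    n_l <- round(cfg$frac_left_tuned * n)
    n_r <- round(cfg$frac_right_tuned * n)
    classes <- c(rep("left", n_l), rep("right", n_r),
                 rep("untuned", n - n_l - n_r))

    kernel <- calcium_kernel(cfg$kernel_tau_rise_ms / 1000,
                             cfg$kernel_tau_decay_ms / 1000, fr)

    licks <- session_licks(trials)
    stim_t <- trials$stim_time_s[trials$type != "catch"]

    # shared neuropil contaminant: low-pass-filtered white noise (AR(1))
    raw <- stats::rnorm(n_frames)
    shared <- as.numeric(stats::filter(raw, 0.98, method = "recursive"))
    shared <- shared / stats::sd(shared) * cfg$contaminant_sd

    # block epochs for preparatory activity
    block_epochs <- NULL
    if (cfg$preparatory_rate_hz > 0 && "block_side" %in% names(trials)) {
      bnd <- c(0, trials$stim_time_s[-nrow(trials)] +
                 diff(trials$stim_time_s) / 2, duration)
      block_epochs <- data.frame(start = bnd[-length(bnd)], end = bnd[-1],
                                 side = trials$block_side)
    }

    neurons <- vector("list", n)
    ev_list <- vector("list", n)
    clean_list <- vector("list", n)
    alphas <- pmax(stats::rnorm(n, cfg$alpha_mean, cfg$alpha_sd), 0)
    for (j in seq_len(n)) {
      cls <- classes[j]
      ev <- numeric(0)
      if (cls %in% c("left", "right")) {
        pref <- licks$time_s[licks$side == cls]
        keep <- stats::runif(length(pref)) < cfg$event_reliability
        ev <- pref[keep] - cfg$motor_lead_ms / 1000 +
          stats::rnorm(sum(keep), 0, 0.02)
        bg_rate <- cfg$background_rate_hz / 4
        if (cfg$preparatory_rate_hz > 0 && !is.null(block_epochs)) {
          ep <- block_epochs[block_epochs$side == cls, , drop = FALSE]
          for (k in seq_len(nrow(ep))) {
            len <- ep$end[k] - ep$start[k]
            m <- stats::rpois(1, cfg$preparatory_rate_hz * len)
            ev <- c(ev, stats::runif(m, ep$start[k], ep$end[k]))
          }
        }
      } else if (isTRUE(cfg$untuned_lick_responsive)) {
        pref <- licks$time_s
        keep <- stats::runif(length(pref)) < cfg$event_reliability
        ev <- pref[keep] - cfg$motor_lead_ms / 1000 +
          stats::rnorm(sum(keep), 0, 0.02)
        bg_rate <- cfg$background_rate_hz / 4
      } else {
        bg_rate <- cfg$background_rate_hz
      }
      m_bg <- stats::rpois(1, bg_rate * duration)
      ev <- sort(c(ev, stats::runif(m_bg, 0, duration)))
      ev <- ev[ev > 0 & ev < duration]
      if (cfg$stim_amplitude > 0 && length(stim_t)) {
        sig_stim <- events_to_trace(stim_t + 0.03, n_frames, fr, kernel) *
          cfg$stim_amplitude
      } else sig_stim <- 0
      signal <- events_to_trace(ev, n_frames, fr, kernel) *
        cfg$transient_amplitude + sig_stim
      noise <- stats::rnorm(n_frames, 0, cfg$noise_sd)
      f_surround <- 50 + shared + stats::rnorm(n_frames, 0, 1)
      clean <- cfg$baseline_f0 + signal + noise
      neurons[[j]] <- list(f_soma = clean + alphas[j] * f_surround,
                           f_surround = f_surround,
                           alpha = alphas[j],
                           frame_rate_hz = fr,
                           class = cls)
      ev_list[[j]] <- ev
      clean_list[[j]] <- signal
    }
    list(neurons = neurons,
         truth = list(events = ev_list, class = classes,
                      signal = clean_list, alpha = alphas,
                      contaminant = shared, n_frames = n_frames))
  })
}

#' Collect all spout contacts of a session into one stream
#'
#' @param trials trial table from [generate_session()].
#' @return data.frame with `time_s` and `side`, sorted by time.
#' @export
session_licks <- function(trials) {
  r <- unlist(lapply(trials$lick_times_right, split_times))
  l <- unlist(lapply(trials$lick_times_left, split_times))
  out <- data.frame(time_s = c(r, l),
                    side = c(rep("right", length(r)), rep("left", length(l))),
                    stringsAsFactors = FALSE)
  out[order(out$time_s), , drop = FALSE]
}

#' Generate a synthetic jaw-position trace
#'
#' Video-derived jaw position as a mean-ROI pixel value: baseline noise,
#' large smooth deflections at every spout contact, and small isolated jaw
#' deflections at Poisson times whose rate may differ between left and right
#' blocks (preparatory movements).  Small-movement amplitude is specified as
#' a signal-to-noise ratio on the frame-difference (motion) signal, the
#' scale on which onsets are detected.
#'
#' Two baseline-noise regimes are available.  `"wander"` (default) models
#' the resting face as a slow bounded wander: frame-to-frame jitter is
#' uniform (bounded, as for a quantization-limited ROI mean at high frame
#' rate) and integrates into a slowly mean-reverting position.  Bounded
#' jitter is what makes a fixed-multiple-of-SD motion threshold a specific
#' movement detector; with Gaussian-tailed jitter any such threshold fires
#' constantly on noise alone.  `"iid"` models a stationary
#' quantization-jitter-dominated position (uniform, independent per frame),
#' the regime in which per-window position-SD statistics are stable; use it
#' for window-SD ratio analyses.
#'
#' @param trials,truth session pieces from [generate_session()].
#' @param frame_rate_hz camera frame rate (Hz, >= 100).
#' @param noise_sd baseline jitter SD (a.u.): the frame-to-frame motion SD
#'   under `"wander"`, the per-frame position SD under `"iid"`.
#' @param small_rate_hz rate of small jaw movements (Hz).
#' @param n_small if non-NULL, plant exactly this many small movements
#'   (uniformly over the eligible span) instead of a Poisson draw.
#' @param small_snr peak amplitude of a small movement on the motion signal,
#'   in units of the baseline motion SD.
#' @param block_mod relative rate modulation by block: right-block rate is
#'   `small_rate_hz * (1 + block_mod)`, left-block `* (1 - block_mod)`.
#' @param lick_amp amplitude of lick deflections, in baseline-jitter SDs.
#' @param light_suppression multiplicative amplitude reduction of small
#'   movements during light-on catch trials (1 = fully suppressed).
#' @param noise_model `"wander"` or `"iid"` (see Details).
#' @param seed integer seed for the jaw stream.
#' @return a list with `position` (numeric trace), `frame_rate_hz`, and
#'   `truth` (small-movement onset times, their amplitude, the noise SD).
#' @export
generate_jaw <- function(trials, truth, frame_rate_hz = 200,
                         noise_sd = 1, small_rate_hz = 0.15,
                         n_small = NULL, small_snr = 6, block_mod = 0,
                         lick_amp = 40, light_suppression = 0,
                         noise_model = c("wander", "iid"),
                         seed = 1L) {
  if (frame_rate_hz < 100) stop_config("frame_rate_hz must be >= 100")
  noise_model <- match.arg(noise_model)
  check_pos(noise_sd, "noise_sd", strict = TRUE)
  check_pos(small_rate_hz, "small_rate_hz")
  duration <- truth$duration_s
  n_frames <- ceiling(duration * frame_rate_hz)
  with_seed(derive_seed(seed, "jaw"), {
    half <- noise_sd * sqrt(3)          # uniform half-width for this SD
    if (noise_model == "wander") {
      # bounded uniform jitter integrated with slow mean reversion
      u <- stats::runif(n_frames, -half, half)
      pos <- as.numeric(stats::filter(u, 0.999, method = "recursive"))
      motion_sd <- noise_sd
    } else {
      pos <- stats::runif(n_frames, -half, half)
      motion_sd <- noise_sd * sqrt(2)
    }

    # unit bump: half-cosine rise (40 ms) and fall (80 ms)
    rise_f <- max(2L, round(0.04 * frame_rate_hz))
    fall_f <- max(2L, round(0.08 * frame_rate_hz))
    bump <- c((1 - cos(pi * seq_len(rise_f) / rise_f)) / 2,
              (1 + cos(pi * seq_len(fall_f) / fall_f)) / 2)
    peak_diff <- max(abs(diff(c(0, bump))))
    small_amp <- small_snr * motion_sd / peak_diff

    add_bump <- function(pos, t0, amp) {
      i0 <- round(t0 * frame_rate_hz) + 1L
      idx <- i0 + seq_along(bump) - 1L
      ok <- idx >= 1L & idx <= n_frames
      pos[idx[ok]] <- pos[idx[ok]] + amp * bump[ok]
      pos
    }

    licks <- session_licks(trials)
    for (t0 in licks$time_s) pos <- add_bump(pos, t0, lick_amp * noise_sd)

    # candidate small-movement times, kept clear of stimulus trials' evoked
    # epochs and of licks; catch (virtual-stimulus) windows stay eligible
    stim_all <- trials$stim_time_s
    stim_real <- stim_all[trials$type != "catch"]
    n_tr <- nrow(trials)
    bnd <- c(0, stim_all[-n_tr] + diff(stim_all) / 2, duration)
    eligible <- function(x) {
      ok <- rep(TRUE, length(x))
      for (t0 in stim_real) ok <- ok & !(x > t0 - 0.7 & x < t0 + 3.2)
      for (t0 in licks$time_s) ok <- ok & !(abs(x - t0) < 0.8)
      ok & x > 0.5 & x < duration - 0.5
    }
    if (!is.null(n_small)) {
      cand <- sort(stats::runif(20 * n_small, 0, duration))
      cand <- cand[eligible(cand)]
    } else {
      cand <- numeric(0)
      for (i in seq_len(n_tr)) {
        rate <- small_rate_hz
        if (block_mod != 0 && trials$block_side[i] != "none") {
          rate <- small_rate_hz *
            (1 + if (trials$block_side[i] == "right") block_mod else -block_mod)
        }
        len <- bnd[i + 1] - bnd[i]
        m <- stats::rpois(1, rate * len)
        cand <- c(cand, stats::runif(m, bnd[i], bnd[i + 1]))
      }
      cand <- sort(cand)
      cand <- cand[eligible(cand)]
    }
    if (length(cand) > 1) {             # enforce isolation in the truth
      keep <- c(TRUE, diff(cand) >= 1.6)
      while (!all(keep)) {
        cand <- cand[keep]
        keep <- c(TRUE, diff(cand) >= 1.6)
      }
    }
    if (!is.null(n_small)) {
      if (length(cand) < n_small) {
        stop_config("session too short to plant %d isolated movements", n_small)
      }
      cand <- sort(sample(cand, n_small))
    }

    # light-on catch windows where small movements are suppressed
    supp <- function(t0) {
      if (light_suppression <= 0) return(1)
      on <- trials$light_on & trials$type == "catch"
      in_win <- any(t0 >= trials$stim_time_s[on] &
                      t0 < trials$stim_time_s[on] + 1.5)
      if (in_win) 1 - light_suppression else 1
    }
    for (t0 in cand) pos <- add_bump(pos, t0, small_amp * supp(t0))

    list(position = pos, frame_rate_hz = frame_rate_hz,
         truth = list(small_onsets = cand, small_amp = small_amp,
                      noise_sd = noise_sd))
  })
}

#' Generate a synthetic wide-field imaging stack
#'
#' Forward model for a trial-averaged wide-field movie: a smooth baseline
#' image modulated multiplicatively by one or more Gaussian spatial bumps
#' whose time courses switch on at configured lags after the stimulus (an
#' early sensory spot within 100 ms, a late frontal spot at 100--200 ms),
#' plus multiplicative white noise averaged over trials.
#'
#' @param shape image dimensions `c(rows, cols)` (default 100 x 100 px).
#' @param spots list of spots; each a list with `center = c(row, col)`,
#'   `amplitude` (peak fractional dF/F), `sigma_px`, `lag_s` (onset lag after
#'   stimulus), and optionally `tau_decay_s` (default 0.5).
#' @param n_trials trials averaged (noise shrinks as `1/sqrt(n)`).
#' @param frame_rate_hz frame rate (Hz, default 100).
#' @param pre_s,post_s pre- and post-stimulus movie span (s); the trial
#'   covers a 2 s baseline and 3.12 s response by default.
#' @param noise_sd fractional single-trial pixel noise SD.
#' @param seed integer seed.
#' @return list with `movie` (rows x cols x frames array, trial-averaged raw
#'   fluorescence), `stim_frame` (index of the first post-stimulus frame),
#'   `frame_rate_hz`, and `truth` (spot centers, lags, amplitudes).
#' @export
generate_widefield <- function(shape = c(100L, 100L),
                               spots = list(
                                 list(center = c(65, 70), amplitude = 0.03,
                                      sigma_px = 6, lag_s = 0.03),
                                 list(center = c(25, 35), amplitude = 0.02,
                                      sigma_px = 6, lag_s = 0.13)),
                               n_trials = 50L, frame_rate_hz = 100,
                               pre_s = 2, post_s = 3.12,
                               noise_sd = 0.01, seed = 1L) {
  if (pre_s < 2 || post_s < 3) {
    stop_config("movie must cover >= 2 s pre-stimulus and >= 3 s post-stimulus")
  }
  nr <- shape[1]; nc <- shape[2]
  for (sp in spots) {
    if (sp$center[1] < 1 || sp$center[1] > nr ||
        sp$center[2] < 1 || sp$center[2] > nc) {
      stop_config("spot center (%g, %g) lies outside the %d x %d image",
                  sp$center[1], sp$center[2], nr, nc)
    }
  }
  n_pre <- round(pre_s * frame_rate_hz)
  n_post <- round(post_s * frame_rate_hz)
  n_frames <- n_pre + n_post
  stim_frame <- n_pre + 1L
  t_rel <- (seq_len(n_frames) - stim_frame) / frame_rate_hz

  # smooth baseline image (illumination gradient), strictly positive
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  base <- 1000 * (1 + 0.2 * rr / nr + 0.1 * cc / nc)

  modulation <- array(0, dim = c(nr, nc, n_frames))
  for (sp in spots) {
    tau <- sp$tau_decay_s %||% 0.5
    g <- ifelse(t_rel < sp$lag_s, 0,
                (1 - exp(-(t_rel - sp$lag_s) / 0.02)) *
                  exp(-(t_rel - sp$lag_s) / tau))
    bump <- sp$amplitude *
      exp(-((rr - sp$center[1])^2 + (cc - sp$center[2])^2) /
            (2 * sp$sigma_px^2))
    for (f in which(g > 0)) {
      modulation[, , f] <- modulation[, , f] + bump * g[f]
    }
  }

  with_seed(derive_seed(seed, "widefield"), {
    # trial-averaged multiplicative noise has SD noise_sd / sqrt(n_trials)
    eff_sd <- noise_sd / sqrt(max(n_trials, 1L))
    movie <- array(0, dim = c(nr, nc, n_frames))
    for (f in seq_len(n_frames)) {
      movie[, , f] <- base * (1 + modulation[, , f]) *
        (1 + stats::rnorm(nr * nc, 0, eff_sd))
    }
    list(movie = movie, stim_frame = stim_frame,
         frame_rate_hz = frame_rate_hz,
         truth = list(centers = lapply(spots, `[[`, "center"),
                      lags_s = vapply(spots, `[[`, numeric(1), "lag_s"),
                      amplitudes = vapply(spots, `[[`, numeric(1),
                                          "amplitude")))
  })
}

#' Generate synthetic optogenetic motor-mapping trials
#'
#' Per grid site, angle traces (whisker or jaw, 500 Hz) with baseline noise
#' and an evoked deflection during the 500 ms light stimulus whose amplitude
#' falls off as a spatial Gaussian around a hotspot.  A configurable fraction
#' of trials is given an inflated baseline so that the part-specific
#' inclusion rule (baseline SD below 2 deg for whisker, 0.75 deg for jaw)
#' rejects them.
#'
#' @param grid_x_mm,grid_y_mm site coordinates (mm), default a 0.5 mm grid.
#' @param hotspot list with `x`, `y` (mm), `sigma_mm`, `amplitude_deg`.
#' @param part `"whisker"` or `"jaw"` (sets baseline window and thresholds).
#' @param n_trials trials per site.
#' @param noisy_frac fraction of trials with a baseline noisy enough to be
#'   excluded.
#' @param noise_sd_deg baseline angle noise SD (degrees).
#' @param frame_rate_hz sampling rate (Hz, default 500).
#' @param stim_dur_s light stimulus duration (s, default 0.5).
#' @param seed integer seed.
#' @return list with `trials` (list of per-trial records: `site_x_mm`,
#'   `site_y_mm`, `part`, `angle`, `frame_rate_hz`, `stim_onset_index`) and
#'   `truth` (hotspot and per-site true amplitude).
#' @export
generate_motormap_trials <- function(grid_x_mm = seq(0, 3, by = 0.5),
                                     grid_y_mm = seq(0, 3, by = 0.5),
                                     hotspot = list(x = 1.5, y = 2,
                                                    sigma_mm = 0.7,
                                                    amplitude_deg = 8),
                                     part = c("jaw", "whisker"),
                                     n_trials = 20L,
                                     noisy_frac = 0,
                                     noise_sd_deg = 0.1,
                                     frame_rate_hz = 500,
                                     stim_dur_s = 0.5,
                                     seed = 1L) {
  part <- match.arg(part)
  check_prob(noisy_frac, "noisy_frac")
  if (hotspot$x < min(grid_x_mm) || hotspot$x > max(grid_x_mm) ||
      hotspot$y < min(grid_y_mm) || hotspot$y > max(grid_y_mm)) {
    stop_config("grid does not cover the hotspot")
  }
  thr <- motormap_thresholds()
  base_s <- thr$baseline_s[[part]]
  pre_s <- base_s + 0.05
  n_pre <- round(pre_s * frame_rate_hz)
  n_stim <- round(stim_dur_s * frame_rate_hz)
  n_post <- round(0.1 * frame_rate_hz)
  n_frames <- n_pre + n_stim + n_post
  onset <- n_pre + 1L

  sites <- expand.grid(x = grid_x_mm, y = grid_y_mm)
  d2 <- (sites$x - hotspot$x)^2 + (sites$y - hotspot$y)^2
  amp <- hotspot$amplitude_deg * exp(-d2 / (2 * hotspot$sigma_mm^2))

  # smooth evoked time course: 20 ms rise, plateau for the stimulus
  rise <- round(0.02 * frame_rate_hz)
  shape_t <- c(seq(0, 1, length.out = rise),
               rep(1, n_stim - rise), rep(0, n_post))

  with_seed(derive_seed(seed, "motormap"), {
    trials <- list()
    k <- 0L
    for (s in seq_len(nrow(sites))) {
      for (tr in seq_len(n_trials)) {
        noisy <- stats::runif(1) < noisy_frac
        sd_use <- if (noisy) thr$sd_deg[[part]] * 3 else noise_sd_deg
        angle <- stats::rnorm(n_frames, 0, sd_use)
        angle[onset:n_frames] <- angle[onset:n_frames] + amp[s] * shape_t
        k <- k + 1L
        trials[[k]] <- list(site_x_mm = sites$x[s], site_y_mm = sites$y[s],
                            part = part, angle = angle,
                            frame_rate_hz = frame_rate_hz,
                            stim_onset_index = onset)
      }
    }
    list(trials = trials,
         truth = list(hotspot = hotspot, sites = sites, amplitude_deg = amp))
  })
}
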