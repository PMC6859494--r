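#' Classify trials into behavioral outcomes
#'
#' Applies the outcome taxonomy of head-fixed detection tasks.  In the
#' multisensory task a stimulus trial with an in-window lick is a hit,
#' without one a miss; a catch trial with an in-window lick is a false alarm,
#' otherwise a correct rejection.  In the multimotor task the spout of the
#' first in-window contact decides: rewarded side first is a hit, the other
#' side an error (`error_left` / `error_right`, named after the spout that
#' was licked); no contact is a miss.  Associative trials are excluded from
#' analysis.  The in-window rule is half-open: a lick at exactly
#' `stim + reward_window_s` does not count.
#'
#' Simultaneous first contacts on both spouts (same sample) are resolved as
#' an error, the conservative choice.  The light flag does not modify
#' outcomes; it is an analysis grouping.
#'
#' @param trials trial table (see [generate_session()] for the schema).
#' @param reward_window_s response window length (s).
#' @param task `"multisensory"` or `"multimotor"`; by default inferred from
#'   the `block_side` column.
#' @return the trial table with added columns `outcome` and
#'   `first_lick_latency_s` (NA when no in-window lick).
#' @export
classify_trials <- function(trials, reward_window_s = 1.5, task = NULL) {
  if (reward_window_s < 0) stop_config("reward_window_s must be non-negative")
  if (is.null(task)) {
    task <- if (any(trials$block_side %in% c("right", "left")))
      "multimotor" else "multisensory"
  }
  n <- nrow(trials)
  outcome <- character(n)
  latency <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (isTRUE(trials$is_associative[i])) {
      outcome[i] <- "excluded"
      next
    }
    t0 <- trials$stim_time_s[i]
    in_win <- function(x) x[x >= t0 & x < t0 + reward_window_s]
    lr <- in_win(split_times(trials$lick_times_right[i]))
    ll <- in_win(split_times(trials$lick_times_left[i]))
    t_r <- if (length(lr)) min(lr) else Inf
    t_l <- if (length(ll)) min(ll) else Inf
    any_lick <- is.finite(t_r) || is.finite(t_l)
    t_first <- min(t_r, t_l)
    if (any_lick) latency[i] <- t_first - t0

    if (trials$type[i] == "catch") {
      outcome[i] <- if (any_lick) "false_alarm" else "correct_rejection"
    } else if (task == "multisensory") {
      outcome[i] <- if (any_lick) "hit" else "miss"
    } else {
      if (!any_lick) {
        outcome[i] <- "miss"
      } else {
        rewarded <- trials$block_side[i]
        first_side <- if (t_r < t_l) "right" else if (t_l < t_r) "left" else
          setdiff(c("right", "left"), rewarded)  # tie -> error side
        outcome[i] <- if (first_side == rewarded) "hit" else
          paste0("error_", first_side)
      }
    }
  }
  trials$outcome <- outcome
  trials$first_lick_latency_s <- latency
  trials
}

#' Summarize session performance
#'
#' Computes per-modality hit rates, the false-alarm rate on catch trials, and
#' median first-lick latencies per outcome category.  Rates are plain
#' count ratios; an empty denominator yields `NA`, never 0.  Latencies are
#' computed only over trials with at least one in-window lick.
#'
#' @param trials classified trial table from [classify_trials()].
#' @return a list of class `outcome_summary`: `rates` (data.frame with
#'   `category`, `n`, `k`, `rate`), `median_latency_ms` (named vector per
#'   outcome), `n_trials`.
#' @export
outcome_summary <- function(trials) {
  if (nrow(trials) < 1) stop_config("need at least one classified trial")
  if (is.null(trials$outcome)) stop_config("trials are not classified")
  tr <- trials[trials$outcome != "excluded", , drop = FALSE]
  rate_row <- function(category, n, k) {
    data.frame(category = category, n = n, k = k,
               rate = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  is_err <- startsWith(tr$outcome, "error")
  for (ty in c("whisker", "auditory")) {
    sel <- tr$type == ty
    if (!any(sel) && ty == "auditory") next
    rows[[paste0(ty, "_hit")]] <-
      rate_row(paste0(ty, "_hit"), sum(sel), sum(sel & tr$outcome == "hit"))
    if (any(is_err)) {
      rows[[paste0(ty, "_error")]] <-
        rate_row(paste0(ty, "_error"), sum(sel), sum(sel & is_err))
    }
  }
  sel <- tr$type == "catch"
  rows[["false_alarm"]] <-
    rate_row("false_alarm", sum(sel), sum(sel & tr$outcome == "false_alarm"))
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL

  lat <- tapply(tr$first_lick_latency_s, tr$outcome,
                function(x) stats::median(x, na.rm = TRUE) * 1000)
  lat <- lat[!is.na(lat)]

  out <- list(rates = rates, median_latency_ms = lat, n_trials = nrow(tr))
  class(out) <- "outcome_summary"
  out
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("Session outcome summary (", x$n_trials, " trials)\n", sep = "")
  df <- x$rates
  df$rate <- round(df$rate, 3)
  print(df, row.names = FALSE)
  if (length(x$median_latency_ms)) {
    cat("Median first-lick latency (ms):\n")
    print(round(x$median_latency_ms))
  }
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Lick probability aligned to block switches
#'
#' For every block switch of a multimotor session, pools trials at offsets
#' `-window_trials .. +window_trials` relative to the switch and reports the
#' fraction of trials with at least one in-window lick on each spout,
#' with Wilson 95% confidence intervals.  Offsets with no pooled trials
#' yield `NA` bounds rather than a clamped interval.
#'
#' @param trials classified trial table ([classify_trials()]).
#' @param window_trials half-width of the offset window (trials).
#' @param reward_window_s response window used to define an in-window lick.
#' @return data.frame with columns `offset`, `n`, `p_right`, `p_left`,
#'   `right_lo`, `right_hi`, `left_lo`, `left_hi`.
#' @export
switch_aligned_lick_prob <- function(trials, window_trials = 25,
                                     reward_window_s = 1.5) {
  blk <- trials$block_side
  switches <- which(blk[-1] != blk[-length(blk)]) + 1L
  if (length(switches) == 0) stop_config("no block switches in session")
  offs <- -window_trials:window_trials
  n <- k_r <- k_l <- stats::setNames(rep(0L, length(offs)), offs)
  for (s in switches) {
    for (j in seq_along(offs)) {
      i <- s + offs[j]
      if (i < 1 || i > nrow(trials)) next
      t0 <- trials$stim_time_s[i]
      in_win <- function(x) any(x >= t0 & x < t0 + reward_window_s)
      n[j] <- n[j] + 1L
      if (in_win(split_times(trials$lick_times_right[i]))) k_r[j] <- k_r[j] + 1L
      if (in_win(split_times(trials$lick_times_left[i]))) k_l[j] <- k_l[j] + 1L
    }
  }
  ci_r <- t(mapply(wilson_ci, k_r, n))
  ci_l <- t(mapply(wilson_ci, k_l, n))
  data.frame(offset = offs, n = as.integer(n),
             p_right = ifelse(n > 0, k_r / n, NA_real_),
             p_left = ifelse(n > 0, k_l / n, NA_real_),
             right_lo = ci_r[, 1], right_hi = ci_r[, 2],
             left_lo = ci_l[, 1], left_hi = ci_l[, 2],
             row.names = NULL)
}
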