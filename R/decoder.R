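#' Fit a probabilistic-population-code lick-direction decoder
#'
#' Estimates per-neuron tuning curves from spontaneous-lick-aligned
#' responses and assembles the decoder used to read out lick direction from
#' windowed population activity.  For each neuron, the tuning value for a
#' direction is the mean z-scored response in a -100..100 ms window around
#' spontaneous licks of that direction.  A neuron is included only if it
#' responds significantly (Wilcoxon rank-sum on baseline -700..-500 ms vs
#' response window) to at least one direction and has at least
#' `min_trials` licks per direction; a field of view with fewer than
#' `min_neurons` qualifying neurons is excluded as a whole (explicit status,
#' not an empty set).
#'
#' Because tuning values are mean z-scores they can be zero or negative;
#' before taking logs they are clamped at zero and floored by
#' `epsilon` (default: the larger of 1e-3 and 1% of the largest absolute
#' tuning value in the field).  The per-neuron bias term is subtracted from
#' the log tuning so that log-likelihood magnitudes are comparable across
#' fields; it cancels in all left-right comparisons, which is verified by
#' the invariance tests.
#'
#' @param responses a list, one element per neuron, each a named list with
#'   elements `left` and `right`: [align_trace()] objects of
#'   spontaneous-lick-aligned z traces for that direction.
#' @param epsilon positivity floor added to tuning before the log, or
#'   `"auto"`.
#' @param bias_mode `"log_mean"` (subtract the across-direction mean of the
#'   log tuning, the default) or `"raw_mean"` (subtract the log of the
#'   across-direction mean tuning).
#' @param response_ms,baseline_ms tuning/response and significance baseline
#'   windows (ms).
#' @param min_trials minimum licks per direction per neuron (default 15).
#' @param min_neurons minimum qualifying population size (default 5).
#' @param alpha significance level for inclusion (default 0.05).
#' @return an object of class `lick_decoder`: `tuning` (neurons x 2 matrix,
#'   columns `left`, `right`), `log_tuning`, `bias`, `epsilon`,
#'   `neuron_ids`, `status` (`"ok"` or `"excluded"`), `n_candidates`.
#' @seealso [predict.lick_decoder()], [decode_licks()]
#' @export
compute_tuning <- function(responses, epsilon = "auto",
                           bias_mode = c("log_mean", "raw_mean"),
                           response_ms = c(-100, 100),
                           baseline_ms = c(-700, -500),
                           min_trials = 15, min_neurons = 5,
                           alpha = 0.05) {
  bias_mode <- match.arg(bias_mode)
  n_cand <- length(responses)
  ids <- names(responses) %||% as.character(seq_len(n_cand))
  tuning <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("left", "right")))
  kept <- character(0)
  for (j in seq_len(n_cand)) {
    resp <- responses[[j]]
    if (is.null(resp$left) || is.null(resp$right)) next
    n_l <- nrow(resp$left$mat)
    n_r <- nrow(resp$right$mat)
    if (n_l < min_trials || n_r < min_trials) next
    sig <- FALSE
    for (d in c("left", "right")) {
      tst <- test_responsiveness(resp[[d]], trigger_kind = "lick",
                                 baseline_ms = baseline_ms,
                                 response_ms = response_ms,
                                 alpha = alpha, min_events = min_trials)
      if (isTRUE(tst$significant)) sig <- TRUE
    }
    if (!sig) next
    f <- c(left = mean(window_means(resp$left, response_ms[1], response_ms[2])),
           right = mean(window_means(resp$right, response_ms[1], response_ms[2])))
    tuning <- rbind(tuning, f)
    kept <- c(kept, ids[j])
  }
  rownames(tuning) <- kept
  if (nrow(tuning) < min_neurons) {
    out <- list(tuning = tuning, status = "excluded",
                n_candidates = n_cand, neuron_ids = kept,
                reason = sprintf("only %d qualifying neurons (minimum %d)",
                                 nrow(tuning), min_neurons))
    class(out) <- "lick_decoder"
    return(out)
  }
  lick_decoder(tuning, epsilon = epsilon, bias_mode = bias_mode,
               n_candidates = n_cand)
}

#' Construct a lick-direction decoder from a tuning matrix
#'
#' Lower-level constructor used by [compute_tuning()] and by tests that
#' supply tuning curves directly.
#'
#' @param tuning neurons x 2 matrix of mean responses, columns `left`,
#'   `right` (any two-column matrix is accepted; columns are taken in that
#'   order if unnamed).
#' @param epsilon positivity floor, or `"auto"` (max of 1e-3 and 1% of the
#'   largest absolute tuning value).
#' @param clamp clamp negative tuning values to 0 before adding `epsilon`
#'   (default TRUE; mean z responses can be negative, logs cannot).
#' @inheritParams compute_tuning
#' @param n_candidates bookkeeping: neurons considered before inclusion.
#' @return an object of class `lick_decoder`.
#' @export
lick_decoder <- function(tuning, epsilon = "auto",
                         bias_mode = c("log_mean", "raw_mean"),
                         clamp = TRUE, n_candidates = nrow(tuning)) {
  bias_mode <- match.arg(bias_mode)
  tuning <- as.matrix(tuning)
  if (ncol(tuning) != 2) stop("tuning must have two columns", call. = FALSE)
  if (is.null(colnames(tuning))) colnames(tuning) <- c("left", "right")
  if (identical(epsilon, "auto")) {
    epsilon <- max(1e-3, 0.01 * max(abs(tuning)))
  }
  check_pos(epsilon, "epsilon", strict = TRUE)
  f <- if (clamp) pmax(tuning, 0) else tuning
  log_tuning <- log(f + epsilon)
  bias <- switch(bias_mode,
                 log_mean = rowMeans(log_tuning),
                 raw_mean = log(rowMeans(f) + epsilon))
  out <- list(tuning = tuning, log_tuning = log_tuning, bias = bias,
              epsilon = epsilon, bias_mode = bias_mode,
              neuron_ids = rownames(tuning) %||%
                as.character(seq_len(nrow(tuning))),
              status = "ok", n_candidates = n_candidates)
  class(out) <- "lick_decoder"
  out
}

#' @export
print.lick_decoder <- function(x, ...) {
  if (x$status != "ok") {
    cat("Lick-direction decoder: field of view EXCLUDED (", x$reason, ")\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Lick-direction decoder: %d neurons (of %d candidates), epsilon = %.4g\n",
    nrow(x$tuning), x$n_candidates, x$epsilon))
  cat(sprintf("Bias correction: %s of the tuning curves\n",
              if (x$bias_mode == "log_mean") "mean log" else "log mean"))
  invisible(x)
}

#' @export
summary.lick_decoder <- function(object, ...) {
  print(object)
  if (object$status == "ok") {
    pref <- ifelse(object$tuning[, "right"] > object$tuning[, "left"],
                   "right", "left")
    cat("Preferred side: ", sum(pref == "right"), " right, ",
        sum(pref == "left"), " left\n", sep = "")
    cat("Tuning range (z): ",
        paste(round(range(object$tuning), 3), collapse = " .. "), "\n",
        sep = "")
  }
  invisible(object)
}

#' @export
coef.lick_decoder <- function(object, ...) object$tuning

#' Decode lick direction from windowed population activity
#'
#' Computes, per trial, the log-likelihood of a left and a right lick as the
#' matrix product of the population activity vector with the bias-corrected
#' log tuning curves, `LL(trial, d) = sum_n r_n (log(f_n(d) + eps) - b_n)`,
#' and decodes the direction maximizing it.  Exact ties are flagged and
#' broken by a seeded coin flip.  When actual directions are supplied,
#' performance is the fraction of correctly decoded trials.
#'
#' @param decoder a `lick_decoder` with status `"ok"`.
#' @param activity trials x neurons matrix of window-averaged z; columns
#'   must match the decoder's neuron order.
#' @param actual optional per-trial actual direction (`"left"`/`"right"`).
#' @param seed seed for tie-breaking coin flips.
#' @return list of class `decode_result`: `loglik` (trials x 2), `decoded`,
#'   `tie`, `performance` (NA without `actual`), `n_trials`, `seed`.
#' @export
decode_licks <- function(decoder, activity, actual = NULL, seed = 1L) {
  stopifnot(inherits(decoder, "lick_decoder"))
  if (decoder$status != "ok") {
    stop("decoder field of view was excluded: ", decoder$reason, call. = FALSE)
  }
  activity <- as.matrix(activity)
  if (ncol(activity) != nrow(decoder$tuning)) {
    stop("activity has ", ncol(activity), " neurons but the decoder has ",
         nrow(decoder$tuning), call. = FALSE)
  }
  bad <- which(!apply(activity, 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("non-finite activity in trial(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ll <- activity %*% (decoder$log_tuning - decoder$bias)
  colnames(ll) <- colnames(decoder$log_tuning)
  d <- unname(ll[, "right"] - ll[, "left"])
  # a tie is a zero log-likelihood difference up to floating-point rounding
  tie <- abs(d) <= 1e-9 * pmax(1, abs(ll[, "left"]) + abs(ll[, "right"]))
  decoded <- ifelse(d > 0, "right", "left")
  if (any(tie)) {
    flips <- with_seed(derive_seed(seed, "tiebreak"),
                       stats::runif(sum(tie)) < 0.5)
    decoded[tie] <- ifelse(flips, "right", "left")
  }
  perf <- NA_real_
  if (!is.null(actual)) {
    stopifnot(length(actual) == nrow(activity))
    perf <- mean(decoded == actual)
  }
  out <- list(loglik = ll, decoded = decoded, tie = tie,
              performance = perf, n_trials = nrow(activity), seed = seed)
  class(out) <- "decode_result"
  out
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Decoded %d trials (%d tie%s)", x$n_trials, sum(x$tie),
              if (sum(x$tie) == 1) "" else "s"))
  if (is.finite(x$performance)) {
    cat(sprintf("; performance %.3f", x$performance))
  }
  cat("\n")
  invisible(x)
}

#' @rdname decode_licks
#' @param object a `lick_decoder`.
#' @param newdata trials x neurons activity matrix.
#' @param ... passed on (`actual`, `seed`).
#' @export
predict.lick_decoder <- function(object, newdata, ...) {
  decode_licks(object, newdata, ...)
}

# window-averaged z per trial for one neuron: mean of z over
# [stim + lo, stim + hi) ms, sampled on the native frame grid
trial_window_activity <- function(z, stim_times_s, frame_rate_hz,
                                  lo_ms, hi_ms) {
  vapply(stim_times_s, function(t0) {
    i0 <- round((t0 + lo_ms / 1000) * frame_rate_hz) + 1L
    i1 <- round((t0 + hi_ms / 1000) * frame_rate_hz)
    if (i0 < 1L || i1 > length(z) || i1 < i0) return(NA_real_)
    mean(z[i0:i1])
  }, numeric(1))
}

#' Decoder performance in the pre- and post-stimulus windows
#'
#' Runs the decoder on identical trial sets for the pre-stimulus
#' (-1000..0 ms) and post-stimulus (0..200 ms) activity windows of all hit
#' and error trials (trials with evoked licking).  Trials with a tongue
#' contact on either spout inside the pre-stimulus window are excluded from
#' both analyses, so the pre window is genuinely movement-free.  The
#' tuning-estimation licks (spontaneous) and the evaluation trials (stimulus
#' hit/error) are disjoint by construction; overlap of the windows with a
#' reward window would break that and raises an error upstream.
#'
#' @param z_mat neurons x frames matrix of z-scored traces (decoder neuron
#'   order).
#' @param trials classified trial table ([classify_trials()]).
#' @param decoder a `lick_decoder`.
#' @param frame_rate_hz imaging frame rate.
#' @param pre_ms,post_ms the two windows, `c(lo, hi)` ms.
#' @param seed tie-break seed.
#' @return list with elements `pre` and `post` (each a `decode_result` or a
#'   missing-result record with a `reason`), plus `n_trials`, `excluded_pre_lick`.
#' @export
decoder_performance_by_window <- function(z_mat, trials, decoder,
                                          frame_rate_hz = 30,
                                          pre_ms = c(-1000, 0),
                                          post_ms = c(0, 200),
                                          seed = 1L) {
  stopifnot(is.matrix(z_mat))
  is_evoked <- trials$outcome %in% c("hit", "error_left", "error_right")
  tr <- trials[is_evoked, , drop = FALSE]
  # actual direction = side of the first in-window contact
  actual <- character(nrow(tr))
  pre_lick <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    t0 <- tr$stim_time_s[i]
    lr <- split_times(tr$lick_times_right[i])
    ll <- split_times(tr$lick_times_left[i])
    t_r <- suppressWarnings(min(lr[lr >= t0]))
    t_l <- suppressWarnings(min(ll[ll >= t0]))
    actual[i] <- if (t_r < t_l) "right" else "left"
    pre0 <- t0 + pre_ms[1] / 1000
    pre_lick[i] <- any(c(lr, ll) >= pre0 & c(lr, ll) < t0)
  }
  tr <- tr[!pre_lick, , drop = FALSE]
  actual <- actual[!pre_lick]
  run_window <- function(win) {
    if (nrow(tr) == 0) {
      return(list(performance = NA_real_, reason = "no included trials"))
    }
    act <- sapply(seq_len(nrow(z_mat)), function(j) {
      trial_window_activity(z_mat[j, ], tr$stim_time_s, frame_rate_hz,
                            win[1], win[2])
    })
    act <- matrix(act, nrow = nrow(tr))
    ok <- apply(act, 1, function(r) all(is.finite(r)))
    if (!any(ok)) {
      return(list(performance = NA_real_, reason = "no included trials"))
    }
    decode_licks(decoder, act[ok, , drop = FALSE], actual = actual[ok],
                 seed = seed)
  }
  list(pre = run_window(pre_ms), post = run_window(post_ms),
       n_trials = nrow(tr), excluded_pre_lick = sum(pre_lick))
}
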