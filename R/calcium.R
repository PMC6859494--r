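#' Neuropil-correct a somatic fluorescence trace
#'
#' Removes out-of-focus contamination by subtracting the alpha-scaled
#' surround-ring signal from the somatic signal, elementwise:
#' `F(t) = F_soma(t) - alpha * F_surround(t)`.  The coefficient alpha is an
#' upstream (ROI-extraction) output; if absent, the population mean 0.38 is
#' used with a message.  Values outside `[0, 1]` are accepted with a warning
#' (the empirical distribution of alpha is wide, 0.38 +/- 0.30).
#'
#' @param f_soma,f_surround numeric traces of equal length, or a single
#'   neuron record (a list with `f_soma`, `f_surround`, `alpha`) in `f_soma`.
#' @param alpha neuropil coefficient.
#' @return the corrected trace.
#' @export
neuropil_correct <- function(f_soma, f_surround = NULL, alpha = NULL) {
  if (is.list(f_soma)) {
    neuron <- f_soma
    f_surround <- neuron$f_surround
    alpha <- alpha %||% neuron$alpha
    f_soma <- neuron$f_soma
  }
  if (is.null(alpha)) {
    message("alpha not supplied; using population mean 0.38")
    alpha <- 0.38
  }
  if (length(f_soma) != length(f_surround)) {
    stop("soma and surround traces differ in length", call. = FALSE)
  }
  if (!is.finite(alpha)) stop("alpha must be finite", call. = FALSE)
  if (alpha < 0 || alpha > 1) {
    warning(sprintf("alpha = %.3g lies outside [0, 1]", alpha))
  }
  f_soma - alpha * f_surround
}

# Mode of a fluorescence distribution.  Default: argmax of a Gaussian kernel
# density estimate with twice the rule-of-thumb bandwidth -- at a locally
# symmetric peak the widened kernel adds (to leading order) no bias but cuts
# the argmax variance, which is what limits accuracy at typical block sizes.
# "histogram" (Freedman-Diaconis bins, midpoint of the max-count bin) is the
# simpler, coarser alternative.
estimate_mode <- function(x, method = c("kde", "histogram")) {
  method <- match.arg(method)
  iqr <- stats::IQR(x)
  if (iqr == 0) return(stats::median(x))
  if (method == "kde") {
    d <- stats::density(x, bw = 2 * stats::bw.nrd0(x), n = 4096)
    return(d$x[which.max(d$y)])
  }
  bw <- 2 * iqr / length(x)^(1 / 3)
  breaks <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Fit a mode-based noise model to a fluorescence trace
#'
#' Estimates, in blocks of `block_s` seconds, the baseline level `f_mode`
#' (histogram mode of the block's fluorescence distribution) and the noise SD
#' `sigma_noise`, obtained by taking the values below the mode and
#' symmetrizing them around it: the SD is computed over the values at or
#' below the mode together with their reflection above it.  Because calcium
#' transients are positive-going, this estimator is robust to their skew.
#' A final partial block is merged into the preceding one; traces shorter
#' than one block form a single block.
#'
#' @param f corrected fluorescence trace.
#' @param frame_rate_hz sampling rate (Hz).
#' @param block_s block length in seconds (default 100).
#' @param mode_method `"kde"` (kernel-density argmax, default) or
#'   `"histogram"` (Freedman-Diaconis max bin midpoint).
#' @return an object of class `noise_model`: data.frame `blocks` with
#'   `start`, `end` (sample indices), `f_mode`, `sigma_noise`.
#' @export
fit_noise_model <- function(f, frame_rate_hz = 30, block_s = 100,
                            mode_method = c("kde", "histogram")) {
  mode_method <- match.arg(mode_method)
  check_pos(block_s, "block_s", strict = TRUE)
  n <- length(f)
  if (n < 2) stop("trace too short", call. = FALSE)
  per <- as.integer(round(block_s * frame_rate_hz))
  n_blocks <- max(1L, n %/% per)
  starts <- (seq_len(n_blocks) - 1L) * per + 1L
  ends <- c(starts[-1L] - 1L, length(f))  # last block absorbs the remainder
  ends <- as.integer(ends)
  fit_block <- function(a, b) {
    x <- f[a:b]
    if (stats::sd(x) == 0) {
      stop("constant trace in block; noise SD undefined", call. = FALSE)
    }
    m <- estimate_mode(x, method = mode_method)
    below <- x[x <= m]
    sym <- c(below, 2 * m - x[x < m])
    c(f_mode = m, sigma_noise = stats::sd(sym))
  }
  est <- t(mapply(fit_block, starts, ends))
  out <- list(blocks = data.frame(start = starts, end = ends,
                                  f_mode = est[, "f_mode"],
                                  sigma_noise = est[, "sigma_noise"]),
              frame_rate_hz = frame_rate_hz, block_s = block_s)
  class(out) <- "noise_model"
  out
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Mode-based noise model: %d block(s) of ~%g s\n",
              nrow(x$blocks), x$block_s))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' z-score a trace under a fitted noise model
#'
#' Standardizes each sample with its own block's parameters:
#' `z(t) = (F(t) - f_mode) / sigma_noise`.  Blocks are concatenated without
#' smoothing across boundaries.
#'
#' @param f corrected fluorescence trace the model was fitted on.
#' @param model a [fit_noise_model()] result.
#' @return numeric z-scored trace of the same length.
#' @export
zscore_trace <- function(f, model) {
  stopifnot(inherits(model, "noise_model"))
  b <- model$blocks
  if (b$end[nrow(b)] != length(f)) {
    stop("noise model does not tile this trace", call. = FALSE)
  }
  z <- numeric(length(f))
  for (i in seq_len(nrow(b))) {
    idx <- b$start[i]:b$end[i]
    z[idx] <- (f[idx] - b$f_mode[i]) / b$sigma_noise[i]
  }
  z
}

#' Flag infrequently active neurons
#'
#' Counts upward crossings of `z = threshold_sd` (a plateau above threshold
#' counts once) and keeps the neuron iff the crossing rate is at least
#' `min_rate_hz`.
#'
#' @param z z-scored trace.
#' @param frame_rate_hz sampling rate (Hz).
#' @param threshold_sd event threshold in noise SDs (default 5).
#' @param min_rate_hz minimum event rate to keep (default 0.05 Hz).
#' @return list with `keep` (logical), `rate_hz`, `n_events`.
#' @export
filter_infrequent <- function(z, frame_rate_hz = 30, threshold_sd = 5,
                              min_rate_hz = 0.05) {
  above <- z >= threshold_sd
  crossings <- sum(above[-1] & !above[-length(above)]) +
    as.integer(above[1])
  duration <- length(z) / frame_rate_hz
  rate <- crossings / duration
  list(keep = rate >= min_rate_hz, rate_hz = rate,
       n_events = as.integer(crossings))
}

#' Align a trace to events
#'
#' Cuts out one row per event, sampled on the native frame grid: the window
#' runs from `-pre_ms` to `+post_ms` in frame steps around the frame nearest
#' each event time; no interpolation.  Events whose window extends beyond
#' the trace are dropped with a warning.
#'
#' @param z trace (any per-frame signal).
#' @param event_times_s event times (s).
#' @param frame_rate_hz sampling rate (Hz).
#' @param pre_ms,post_ms window extent before/after the trigger (ms).
#' @return an object of class `aligned_responses`: `mat` (events x time),
#'   `time_ms` (relative grid), `event_times_s`, `frame_rate_hz`.
#' @export
align_trace <- function(z, event_times_s, frame_rate_hz = 30,
                        pre_ms = 1000, post_ms = 3500) {
  k0 <- round(-pre_ms / 1000 * frame_rate_hz)
  k1 <- round(post_ms / 1000 * frame_rate_hz)
  offs <- k0:k1
  rows <- list()
  kept <- numeric(0)
  for (t0 in event_times_s) {
    centre <- round(t0 * frame_rate_hz) + 1L
    idx <- centre + offs
    if (idx[1] < 1L || idx[length(idx)] > length(z)) next
    rows[[length(rows) + 1L]] <- z[idx]
    kept <- c(kept, t0)
  }
  n_dropped <- length(event_times_s) - length(kept)
  if (n_dropped > 0) {
    warning(sprintf("%d event(s) dropped: window outside trace", n_dropped))
  }
  if (length(rows) == 0) stop("no valid events to align", call. = FALSE)
  out <- list(mat = do.call(rbind, rows),
              time_ms = offs / frame_rate_hz * 1000,
              event_times_s = kept, frame_rate_hz = frame_rate_hz)
  class(out) <- "aligned_responses"
  out
}

# mean over a [lo, hi) ms window of each aligned row
window_means <- function(aligned, lo_ms, hi_ms) {
  sel <- aligned$time_ms >= lo_ms & aligned$time_ms < hi_ms
  if (!any(sel)) stop("window outside the aligned grid", call. = FALSE)
  rowMeans(aligned$mat[, sel, drop = FALSE])
}

#' Test event-locked responsiveness of a neuron
#'
#' Compares per-event baseline-window means against response-window means
#' with a two-sided Wilcoxon rank-sum test.  Window defaults follow the
#' trigger kind: stimulus-triggered analysis uses baseline -300..0 ms and
#' response 0..200 ms; lick-triggered analysis uses baseline -800..-500 ms
#' and response -100..100 ms.  Fewer than `min_events` events excludes the
#' neuron from the category (flagged, not failed).
#'
#' @param aligned an [align_trace()] result.
#' @param trigger_kind `"stimulus"` or `"lick"`.
#' @param baseline_ms,response_ms optional `c(lo, hi)` overrides (ms).
#' @param alpha significance level (default 0.05, uncorrected).
#' @param min_events minimum events per condition (default 15).
#' @return list with `mean_response`, `p_value`, `significant`, `excluded`,
#'   `n_events`.
#' @export
test_responsiveness <- function(aligned,
                                trigger_kind = c("stimulus", "lick"),
                                baseline_ms = NULL, response_ms = NULL,
                                alpha = 0.05, min_events = 15) {
  trigger_kind <- match.arg(trigger_kind)
  if (is.null(baseline_ms)) {
    baseline_ms <- if (trigger_kind == "stimulus") c(-300, 0) else c(-800, -500)
  }
  if (is.null(response_ms)) {
    response_ms <- if (trigger_kind == "stimulus") c(0, 200) else c(-100, 100)
  }
  n_ev <- nrow(aligned$mat)
  if (n_ev < min_events) {
    return(list(mean_response = NA_real_, p_value = NA_real_,
                significant = FALSE, excluded = TRUE, n_events = n_ev))
  }
  base <- window_means(aligned, baseline_ms[1], baseline_ms[2])
  resp <- window_means(aligned, response_ms[1], response_ms[2])
  p <- stats::wilcox.test(resp, base, exact = FALSE)$p.value
  list(mean_response = mean(resp) - mean(base), p_value = p,
       significant = is.finite(p) && p < alpha, excluded = FALSE,
       n_events = n_ev)
}

#' Population PCA trajectories from category-mean responses
#'
#' Takes per-neuron mean response curves for each behavioral category (time
#' grid -1000..3500 ms by convention), concatenates categories along time,
#' and applies PCA over neuron identities: observations are time-by-category
#' points, variables are neurons.  Each category's time course in PC1-PC2 is
#' its population trajectory.
#'
#' @param curves a named list (one element per category) of matrices, each
#'   neurons x time, with identical neuron order and time grids.
#' @param n_components components to return (default 2).
#' @return list of class `population_trajectory`: `trajectories` (named list
#'   of time x component matrices), `explained_variance` (fraction per
#'   component, non-increasing), `n_components`.
#' @export
population_trajectory <- function(curves, n_components = 2) {
  if (length(curves) < 2) stop("need >= 2 categories", call. = FALSE)
  n_neurons <- nrow(curves[[1]])
  if (n_neurons < 2) stop("need >= 2 neurons", call. = FALSE)
  n_time <- ncol(curves[[1]])
  stopifnot(all(vapply(curves, nrow, 1L) == n_neurons),
            all(vapply(curves, ncol, 1L) == n_time))
  # observations = time points of all categories, variables = neurons
  x <- do.call(rbind, lapply(curves, t))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  traj <- list()
  for (i in seq_along(curves)) {
    rows <- (i - 1) * n_time + seq_len(n_time)
    traj[[names(curves)[i]]] <- pc$x[rows, seq_len(k), drop = FALSE]
  }
  out <- list(trajectories = traj, explained_variance = ev[seq_len(k)],
              n_components = k)
  class(out) <- "population_trajectory"
  out
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("Population trajectory: %d categories, %d PCs (%.0f%% variance)\n",
              length(x$trajectories), x$n_components,
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' @export
plot.population_trajectory <- function(x, ...) {
  xs <- unlist(lapply(x$trajectories, function(m) m[, 1]))
  ys <- unlist(lapply(x$trajectories, function(m) m[, min(2, ncol(m))]))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = "PC1", ylab = "PC2", ...)
  for (i in seq_along(x$trajectories)) {
    m <- x$trajectories[[i]]
    graphics::lines(m[, 1], m[, min(2, ncol(m))], col = i)
  }
  graphics::legend("topright", legend = names(x$trajectories),
                   col = seq_along(x$trajectories), lty = 1, bty = "n")
  invisible(x)
}
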