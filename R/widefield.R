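#' Compute a dF/F0 movie
#'
#' `dF/F0(i,j,t) = (F(i,j,t) - F0(i,j)) / F0(i,j)` with the baseline image
#' `F0` the average of the last 5 frames before the stimulus.  Pixels with
#' non-positive baseline are masked (`NA`) and counted.
#'
#' @param movie rows x cols x frames array of raw fluorescence
#'   (trial-averaged; averaging repetitions is upstream).
#' @param stim_frame index of the first post-stimulus frame.
#' @param n_baseline_frames frames averaged for F0 (default 5).
#' @return list of class `dff_movie`: `dff` (array, same dim), `f0`,
#'   `stim_frame`, `n_masked`.
#' @export
compute_dff <- function(movie, stim_frame, n_baseline_frames = 5) {
  d <- dim(movie)
  if (length(d) != 3) stop("movie must be a 3-D array", call. = FALSE)
  if (stim_frame - n_baseline_frames < 1) {
    stop(sprintf("need %d pre-stimulus frames, have %d",
                 n_baseline_frames, stim_frame - 1L), call. = FALSE)
  }
  f0 <- apply(movie[, , (stim_frame - n_baseline_frames):(stim_frame - 1L),
                    drop = FALSE], c(1, 2), mean)
  mask <- f0 <= 0
  n_masked <- sum(mask)
  f0m <- f0
  f0m[mask] <- NA_real_
  dff <- sweep(sweep(movie, c(1, 2), f0m, "-"), c(1, 2), f0m, "/")
  out <- list(dff = dff, f0 = f0, stim_frame = stim_frame,
              n_masked = n_masked)
  class(out) <- "dff_movie"
  out
}

#' Early and late response images
#'
#' Averages the dF/F movie over the early (0..100 ms) and late (100..200 ms)
#' post-stimulus windows.  On the 100 Hz grid these are exactly the first
#' and second set of 10 post-stimulus frames; the windows are disjoint and
#' adjacent.  Images are returned unsmoothed (smoothing belongs to
#' [localize_peak()]).
#'
#' @param dff a [compute_dff()] result (or a raw dF/F array with
#'   `stim_frame` supplied).
#' @param stim_frame first post-stimulus frame (taken from `dff` if absent).
#' @param frame_rate_hz frame rate (default 100 Hz).
#' @param early_ms,late_ms window bounds `c(lo, hi)` in ms.
#' @return list with `early` and `late` matrices and the window definitions.
#' @export
response_images <- function(dff, stim_frame = NULL, frame_rate_hz = 100,
                            early_ms = c(0, 100), late_ms = c(100, 200)) {
  if (inherits(dff, "dff_movie")) {
    stim_frame <- dff$stim_frame
    dff <- dff$dff
  }
  if (is.null(stim_frame)) stop("stim_frame required", call. = FALSE)
  frames_for <- function(win) {
    f0 <- stim_frame + round(win[1] / 1000 * frame_rate_hz)
    f1 <- stim_frame + round(win[2] / 1000 * frame_rate_hz) - 1L
    if (f1 > dim(dff)[3]) {
      stop("movie does not cover the response window", call. = FALSE)
    }
    f0:f1
  }
  avg <- function(idx) apply(dff[, , idx, drop = FALSE], c(1, 2), mean)
  list(early = avg(frames_for(early_ms)), late = avg(frames_for(late_ms)),
       early_ms = early_ms, late_ms = late_ms)
}

# separable Gaussian smoothing with reflective padding
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    pad <- c(v[r:1], v, v[n:(n - r + 1)])
    stats::filter(pad, k, sides = 2)[(r + 1):(r + n)]
  }
  tmp <- apply(img, 2, smooth_vec)
  t(apply(tmp, 1, smooth_vec))
}

#' Localize the peak of a response image
#'
#' Gaussian-smooths the image (sigma in pixels, reflective borders) and
#' returns the integer-pixel coordinates of the maximum inside an optional
#' search mask (e.g. restricting the search for a secondary spot to the
#' frontal region).  A `low_confidence` flag is set when the peak does not
#' exceed the in-mask median by at least `z_min` robust SDs, indicating the
#' "peak" is noise-level: on a signal-free smoothed field of this size the
#' maximum reaches about 3 robust SDs by chance alone, while a genuine
#' activation spot exceeds the smoothed noise floor by an order of
#' magnitude, so the default threshold of 5 separates the two regimes.
#'
#' @param image numeric matrix (a response image).
#' @param sigma smoothing SD in pixels (default 3).
#' @param mask logical matrix of eligible pixels (default: all).
#' @param z_min confidence threshold in robust (MAD) SD units (default 5).
#' @return list with `row`, `col`, `value` (smoothed peak amplitude),
#'   `low_confidence`.
#' @export
localize_peak <- function(image, sigma = 3, mask = NULL, z_min = 5) {
  if (is.null(mask)) mask <- !is.na(image)
  if (!any(mask)) stop("search mask is empty", call. = FALSE)
  img <- image
  img[is.na(img)] <- stats::median(image, na.rm = TRUE)
  sm <- gaussian_smooth(img, sigma)
  vals <- sm
  vals[!mask] <- -Inf
  idx <- arrayInd(which.max(vals), dim(vals))
  centre <- stats::median(sm[mask])
  spread <- stats::mad(sm[mask])
  low <- if (spread > 0) (vals[idx] - centre) / spread < z_min else FALSE
  list(row = idx[1], col = idx[2], value = sm[idx],
       low_confidence = isTRUE(low))
}

#' Anterior-region mask helper
#'
#' Default frontal search mask: the anterior third of the image (rows
#' `1..nrow/3`); replace with an anatomy-derived mask when available.
#'
#' @param dim_img image dimensions `c(rows, cols)`.
#' @param fraction anterior fraction of rows included (default 1/3).
#' @return logical matrix.
#' @export
frontal_mask <- function(dim_img, fraction = 1 / 3) {
  m <- matrix(FALSE, dim_img[1], dim_img[2])
  m[seq_len(max(1L, floor(dim_img[1] * fraction))), ] <- TRUE
  m
}
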