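#' Read and write trial tables
#'
#' Trial tables are plain CSV with per-spout lick times encoded as
#' semicolon-joined seconds, so a session round-trips losslessly through
#' text.
#'
#' @param trials trial table data.frame.
#' @param path CSV file path.
#' @return `read_trials()` returns the trial table; `write_trials()` its
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lick_times_right = "character",
                                       lick_times_left = "character"))
  tr$lick_times_right[is.na(tr$lick_times_right)] <- ""
  tr$lick_times_left[is.na(tr$lick_times_left)] <- ""
  tr
}

#' Read and write per-frame traces
#'
#' Single-trace CSV (`frame_index`, `value`), used for jaw position traces
#' and per-neuron fluorescence.
#'
#' @param x numeric trace.
#' @param path CSV file path.
#' @return `read_trace()` returns the numeric trace.
#' @export
write_trace <- function(x, path) {
  utils::write.csv(data.frame(frame_index = seq_along(x) - 1L, value = x),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.csv(path)$value
}

#' Read and write wide-field movies as multi-page TIFF
#'
#' Frame 0 is t0; the frame interval comes from the acquisition config.
#' Requires the optional `tiff` package.  Intensities are stored as 32-bit
#' floats scaled to `[0, 1]` by `scale_max`.
#'
#' @param movie rows x cols x frames array.
#' @param path TIFF path.
#' @param scale_max intensity corresponding to 1.0 in the file.
#' @return `read_movie_tiff()` returns the array (rescaled back).
#' @export
write_movie_tiff <- function(movie, path, scale_max = 5000) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(f) pmin(pmax(movie[, , f] / scale_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale_max = 5000) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * scale_max
}
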