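# part-specific inclusion thresholds and baseline windows
motormap_thresholds <- function() {
  list(sd_deg = list(whisker = 2, jaw = 0.75),
       baseline_s = list(whisker = 0.1, jaw = 0.25))
}

#' Trial inclusion for optogenetic motor mapping
#'
#' A stimulation trial is included only when the animal was still before the
#' light: the SD of the movement angle over the part-specific pre-stimulation
#' window (100 ms for whisker, 250 ms for jaw) must not exceed the
#' part-specific threshold (2 deg for whisker, 0.75 deg for jaw).
#'
#' @param trial a trial record: list with `angle` (degrees),
#'   `frame_rate_hz`, `stim_onset_index`, `part`.
#' @return TRUE/FALSE; attribute `"reason"` explains an exclusion.
#' @export
include_trial <- function(trial) {
  thr <- motormap_thresholds()
  part <- trial$part
  n_base <- round(thr$baseline_s[[part]] * trial$frame_rate_hz)
  i1 <- trial$stim_onset_index - 1L
  i0 <- i1 - n_base + 1L
  if (i0 < 1L) {
    out <- FALSE
    attr(out, "reason") <- "baseline window not available"
    return(out)
  }
  stats::sd(trial$angle[i0:i1]) <= thr$sd_deg[[part]]
}

#' Optogenetically evoked movement of one trial
#'
#' The evoked movement is the difference in mean angles between the first
#' 200 ms of the stimulation and the 4 ms period immediately before it.
#' Positive values are protraction (whisker) or opening (jaw).
#'
#' @param trial a trial record (see [include_trial()]).
#' @param pre_ms pre-stimulation reference period (default 4 ms).
#' @param response_ms stimulation period analyzed (default 200 ms).
#' @return signed evoked movement in degrees.
#' @export
evoked_movement <- function(trial, pre_ms = 4, response_ms = 200) {
  fr <- trial$frame_rate_hz
  on <- trial$stim_onset_index
  n_pre <- max(1L, round(pre_ms / 1000 * fr))
  n_resp <- round(response_ms / 1000 * fr)
  if (on - n_pre < 1L || on + n_resp - 1L > length(trial$angle)) {
    stop("evoked-movement windows out of range", call. = FALSE)
  }
  mean(trial$angle[on:(on + n_resp - 1L)]) -
    mean(trial$angle[(on - n_pre):(on - 1L)])
}

#' Build a motor map from per-site stimulation trials
#'
#' Applies [include_trial()] to every trial and averages
#' [evoked_movement()] over the included trials of each grid site.  Sites
#' with no included trial are kept in the grid as `NA` (missing) and are
#' excluded from the centroid.
#'
#' @param trials list of trial records (as from
#'   [generate_motormap_trials()] or read from per-site CSVs).
#' @return object of class `motor_map`: data.frame `sites` (`x_mm`, `y_mm`,
#'   `value_deg`, `n_included`), `part`.
#' @export
build_map <- function(trials) {
  if (length(trials) == 0) stop("no trials", call. = FALSE)
  key <- vapply(trials, function(tr) paste(tr$site_x_mm, tr$site_y_mm),
                character(1))
  sites <- unique(data.frame(
    x_mm = vapply(trials, `[[`, numeric(1), "site_x_mm"),
    y_mm = vapply(trials, `[[`, numeric(1), "site_y_mm")))
  if (nrow(sites) < 4) stop("need trials on >= 4 sites", call. = FALSE)
  val <- rep(NA_real_, nrow(sites))
  n_inc <- integer(nrow(sites))
  skey <- paste(sites$x_mm, sites$y_mm)
  for (s in seq_len(nrow(sites))) {
    here <- trials[key == skey[s]]
    mv <- vapply(here[vapply(here, include_trial, logical(1))],
                 evoked_movement, numeric(1))
    n_inc[s] <- length(mv)
    if (length(mv)) val[s] <- mean(mv)
  }
  if (all(is.na(val))) stop("all sites missing after inclusion", call. = FALSE)
  out <- list(sites = data.frame(sites, value_deg = val, n_included = n_inc),
              part = trials[[1]]$part)
  class(out) <- "motor_map"
  out
}

#' @export
print.motor_map <- function(x, ...) {
  cat(sprintf("Motor map (%s): %d sites, max evoked %.2f deg\n", x$part,
              nrow(x$sites), max(x$sites$value_deg, na.rm = TRUE)))
  invisible(x)
}

#' Weighted-centroid hotspot of a motor map
#'
#' The map center is the value-weighted mean position of the sites whose
#' evoked movement strictly exceeds 50% of the map maximum.  The centroid is
#' computed on the positive (protraction/opening) map; missing sites are
#' ignored.
#'
#' @param map a `motor_map` (or a data.frame with `x_mm`, `y_mm`,
#'   `value_deg`).
#' @param threshold_frac fraction of the maximum that must be exceeded
#'   (default 0.5).
#' @return named numeric `c(x_mm, y_mm)`.
#' @export
map_centroid <- function(map, threshold_frac = 0.5) {
  sites <- if (inherits(map, "motor_map")) map$sites else map
  ok <- is.finite(sites$value_deg)
  v <- sites$value_deg[ok]
  x <- sites$x_mm[ok]
  y <- sites$y_mm[ok]
  m <- max(v)
  if (!is.finite(m) || m <= 0) {
    stop("no positive evoked movement; centroid undefined", call. = FALSE)
  }
  sel <- v > threshold_frac * m   # strictly "exceed"
  w <- v[sel]
  c(x_mm = sum(w * x[sel]) / sum(w), y_mm = sum(w * y[sel]) / sum(w))
}
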