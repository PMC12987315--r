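# Core signal containers shared by every pipeline stage. All angular
# quantities are canonically stored in degrees and deg/s, times in seconds,
# marker coordinates in meters.

skn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "stepkin_error")))
}

#' Uniformly sampled single-channel signal
#'
#' The common currency of the processing pipelines: an ordered vector of
#' samples at a fixed rate. Sample `k` (1-based) sits at
#' `start_time + (k - 1) / rate` seconds.
#'
#' @param values Numeric vector of samples (length >= 2).
#' @param rate Sampling rate in Hz (> 0), default 60.
#' @param start_time Time of the first sample in seconds.
#' @param units Unit label carried along for printing (e.g. "deg/s").
#' @return An object of class `uniform_signal`.
#' @export
uniform_signal <- function(values, rate = 60, start_time = 0, units = "deg/s") {
  stopifnot(is.numeric(values), length(values) >= 2, rate > 0)
  structure(
    list(values = as.numeric(values), rate = rate,
         start_time = start_time, units = units),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz, start %.4f s [%s]\n",
              length(x$values), x$rate, x$start_time, x$units))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#' @param x A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1) / x$rate
}

#' Tri-axial uniformly sampled signal
#'
#' Bundles three [uniform_signal] channels (anatomical x, y, z) that share
#' rate, start time and length. The x axis carries thigh flexion-extension.
#'
#' @param x,y,z `uniform_signal` channels.
#' @return An object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(x, y, z) {
  chans <- list(x = x, y = y, z = z)
  for (ch in chans) stopifnot(inherits(ch, "uniform_signal"))
  if (length(unique(vapply(chans, function(s) s$rate, 0))) != 1 ||
      length(unique(vapply(chans, function(s) s$start_time, 0))) != 1 ||
      length(unique(vapply(chans, function(s) length(s$values), 0L))) != 1)
    skn_stop("triaxial channels must share rate, start_time and length",
             "stepkin_contract_error")
  structure(chans, class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("<triaxial_signal> %d samples @ %g Hz, start %.4f s\n",
              length(x$x$values), x$x$rate, x$x$start_time))
  invisible(x)
}

#' Raw (non-uniform) tri-axial gyroscope stream
#'
#' As read from a sensor log: timestamps may be jittered and duplicated.
#' Values are angular velocity in deg/s after boundary unit conversion.
#'
#' @param time Non-decreasing timestamps in seconds (rebased to start at 0).
#' @param x,y,z Angular velocity samples, deg/s.
#' @param axis_map Named numeric vector of per-axis signs mapping device axes
#'   to the anatomical convention (positive = thigh elevation).
#' @return An object of class `raw_gyro_stream`.
#' @export
raw_gyro_stream <- function(time, x, y, z, axis_map = c(x = 1, y = 1, z = 1)) {
  n <- length(time)
  if (n < 2) skn_stop("gyro stream needs at least 2 samples", "stepkin_data_error")
  if (length(x) != n || length(y) != n || length(z) != n)
    skn_stop("axis arrays must match timestamp length", "stepkin_contract_error")
  if (any(diff(time) < -1e-9)) {
    bad <- which(diff(time) < -1e-9)[1] + 1L
    skn_stop(sprintf("timestamps are non-monotone at row %d", bad),
             "stepkin_data_error")
  }
  structure(list(time = as.numeric(time), x = as.numeric(x),
                 y = as.numeric(y), z = as.numeric(z), axis_map = axis_map),
            class = "raw_gyro_stream")
}

#' @export
print.raw_gyro_stream <- function(x, ...) {
  cat(sprintf("<raw_gyro_stream> %d rows spanning %.2f s (%d distinct stamps)\n",
              length(x$time), diff(range(x$time)), length(unique(x$time))))
  invisible(x)
}

#' Two-marker sagittal-plane trajectory
#'
#' Hip (greater trochanter) and knee (lateral condyle) marker positions
#' projected onto the sagittal plane; column `a` is the horizontal
#' (anterior) coordinate and `b` the vertical coordinate, in meters.
#'
#' @param hip,knee n x 2 numeric matrices of planar coordinates.
#' @param frame_rate Frames per second (> 0).
#' @param gap_mask Logical vector, `TRUE` where the frame is valid.
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(hip, knee, frame_rate = 60, gap_mask = NULL) {
  hip <- as.matrix(hip); knee <- as.matrix(knee)
  if (nrow(hip) != nrow(knee))
    skn_stop("hip and knee must have the same number of frames",
             "stepkin_contract_error")
  stopifnot(frame_rate > 0, ncol(hip) == 2, ncol(knee) == 2)
  if (is.null(gap_mask))
    gap_mask <- stats::complete.cases(hip) & stats::complete.cases(knee)
  coincident <- gap_mask & rowSums((hip - knee)^2) < 1e-18
  if (any(coincident, na.rm = TRUE))
    skn_stop(sprintf("hip and knee coincide at frame %d",
                     which(coincident)[1]), "stepkin_data_error")
  structure(list(hip = hip, knee = knee, frame_rate = frame_rate,
                 gap_mask = as.logical(gap_mask)),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d frames @ %g Hz (%d gap frames)\n",
              nrow(x$hip), x$frame_rate, sum(!x$gap_mask)))
  invisible(x)
}

#' Convert angular units
#'
#' @param x Numeric values.
#' @param from,to One of `"deg"` or `"rad"` (per second is implied
#'   throughout; the factor is the same for angles and angular velocities).
#' @return Converted numeric values.
#' @export
convert_angular <- function(x, from = c("deg", "rad"), to = c("deg", "rad")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(x)
  if (from == "rad") x * 180 / pi else x * pi / 180
}

# Tag an angular-velocity series with its provenance
# (reference | phone-AA | phone-ML-prefilter | truth).
set_provenance <- function(sig, provenance) {
  attr(sig, "provenance") <- provenance
  sig
}

#' Provenance tag of a series
#' @param sig A `uniform_signal`.
#' @return Character provenance label or `NA`.
#' @export
provenance <- function(sig) {
  p <- attr(sig, "provenance")
  if (is.null(p)) NA_character_ else p
}
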