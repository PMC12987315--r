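# Motion-capture reference pipeline: marker coordinates -> thigh angle ->
# angular velocity. The two-marker thigh model measures the segment angle
# from the downward vertical: 0 deg = thigh vertical (knee below hip),
# 90 deg = thigh horizontal with the knee anterior, so a raised knee gives a
# positive angle and elevation gives positive angular velocity.

# Fill NA runs by cubic spline through valid frames. Runs longer than
# `long_gap` are still filled but reported via the "long_gap_frames" attr.
fill_gaps_spline <- function(v, valid, long_gap = 10) {
  if (all(valid)) return(list(values = v, long = 0L))
  runs <- rle(!valid)
  worst <- max(runs$lengths[runs$values])
  f <- stats::splinefun(which(valid), v[valid], method = "fmm")
  v[!valid] <- f(which(!valid))
  list(values = v, long = if (worst > long_gap) worst else 0L)
}

#' Thigh segment angle from hip and knee markers
#'
#' Computes the sagittal-plane angle of the hip-to-knee vector from the
#' downward vertical: `atan2(horizontal, -vertical)` of `knee - hip`, in
#' degrees. Gap frames are spline-filled; runs longer than 10 frames are
#' filled too but flagged with a warning and recorded in the
#' `"long_gap_frames"` attribute. Invariant to translating both markers and
#' to scaling the segment length.
#'
#' @param traj A [marker_trajectory].
#' @return An `angle_series` (a `uniform_signal` of degrees at the
#'   trajectory's frame rate, start time 0).
#' @export
thigh_angle <- function(traj) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (sum(traj$gap_mask) < 2)
    skn_stop("need >= 2 valid frames", "stepkin_data_error")
  d_a <- traj$knee[, 1] - traj$hip[, 1]
  d_b <- traj$knee[, 2] - traj$hip[, 2]
  fa <- fill_gaps_spline(d_a, traj$gap_mask)
  fb <- fill_gaps_spline(d_b, traj$gap_mask)
  if (fa$long > 0)
    warning(sprintf("spline-filled a %d-frame marker gap (> 10 frames)", fa$long),
            call. = FALSE)
  ang <- atan2(fa$values, -fb$values) * 180 / pi
  out <- uniform_signal(ang, rate = traj$frame_rate, start_time = 0,
                        units = "deg")
  class(out) <- c("angle_series", class(out))
  attr(out, "long_gap_frames") <- fa$long
  out
}

#' Differentiate an angle series into angular velocity
#'
#' Central differences on interior samples, one-sided differences at the
#' ends. For band-limited content well below the Nyquist frequency the
#' central-difference gain is `sin(w dt) / (w dt)`, within 1% of unity for
#' 1 Hz content at 60 Hz.
#'
#' @param angle An `angle_series` (or any `uniform_signal` in degrees).
#' @param provenance Provenance tag for the result, default `"reference"`.
#' @return An `angular_velocity_series` (`uniform_signal`, deg/s).
#' @export
differentiate <- function(angle, provenance = "reference") {
  stopifnot(inherits(angle, "uniform_signal"))
  v <- angle$values
  n <- length(v)
  if (n < 3) skn_stop("need >= 3 samples to differentiate", "stepkin_data_error")
  dt <- 1 / angle$rate
  out <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / dt
  res <- uniform_signal(out, rate = angle$rate, start_time = angle$start_time,
                        units = "deg/s")
  class(res) <- c("angular_velocity_series", class(res))
  set_provenance(res, provenance)
}

#' Reference thigh angular velocity from a marker trajectory
#'
#' The full reference chain: low-pass filter the marker coordinates
#' (zero-lag 2nd-order Butterworth, 6 Hz by default), form the thigh angle,
#' and differentiate. This series is the ground-truth standard against which
#' both phone pipelines are validated.
#'
#' @param traj A [marker_trajectory].
#' @param spec Marker [filter_spec], default order 2, 6 Hz, zero-lag.
#' @return An `angular_velocity_series` tagged `"reference"`.
#' @export
reference_velocity <- function(traj, spec = filter_spec(order = 2, cutoff = 6)) {
  stopifnot(inherits(traj, "marker_trajectory"))
  filt <- traj
  for (m in c("hip", "knee")) for (j in 1:2) {
    filled <- fill_gaps_spline(traj[[m]][, j], traj$gap_mask)
    filt[[m]][, j] <- lowpass_values(filled$values, traj$frame_rate,
                                     spec$cutoff, spec$order)
  }
  filt$gap_mask <- rep(TRUE, nrow(filt$hip))
  differentiate(thigh_angle(filt), provenance = "reference")
}

#' Reference step cycles from a marker trajectory
#'
#' @param traj A [marker_trajectory].
#' @param detector A [peak_detector_spec].
#' @param filter A marker [filter_spec].
#' @param refine Parabolically refine peak times/values? Default TRUE.
#' @return A [cycle_set] tagged `"reference"`.
#' @export
reference_cycles <- function(traj, detector = peak_detector_spec(),
                             filter = filter_spec(order = 2, cutoff = 6),
                             refine = TRUE) {
  detect_cycle_peaks(reference_velocity(traj, filter), detector,
                     refine = refine)
}
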