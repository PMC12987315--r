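# Preliminary treatment of the raw phone stream: duplicate-stamp collapse,
# cubic-spline resampling to a uniform 60 Hz grid, slow-drift removal and
# the anatomical sign convention (positive = thigh elevation).

#' Resample a jittered gyroscope stream to a uniform grid
#'
#' Co-timestamped samples are first collapsed to their mean (unbiased under
#' symmetric noise), then a cubic spline is fitted per axis through the
#' distinct timestamps and evaluated on a uniform grid anchored at the first
#' timestamp. The grid never extends beyond the last raw timestamp (cubic
#' splines extrapolate badly), so a trailing partial interval is dropped.
#'
#' @param raw A [raw_gyro_stream].
#' @param rate Target rate in Hz, default 60 (the reference system's rate).
#' @return A [triaxial_signal] at `rate`.
#' @export
resample_uniform <- function(raw, rate = 60) {
  stopifnot(inherits(raw, "raw_gyro_stream"), rate > 0)
  grp <- match(raw$time, unique(raw$time))
  ut <- unique(raw$time)
  if (length(ut) < 4)
    skn_stop("need >= 4 distinct timestamps for cubic spline resampling",
             "stepkin_data_error")
  collapse <- function(v) as.numeric(tapply(v, grp, mean))
  grid <- ut[1] + seq(0, floor((ut[length(ut)] - ut[1]) * rate + 1e-9)) / rate
  chan <- function(v) {
    f <- stats::splinefun(ut, collapse(v), method = "fmm")
    uniform_signal(f(grid), rate = rate, start_time = ut[1], units = "deg/s")
  }
  triaxial_signal(chan(raw$x), chan(raw$y), chan(raw$z))
}

#' Remove slow sensor drift from a signal
#'
#' Subtracts a zero-lag 2nd-order Butterworth low-pass baseline (default
#' cutoff 0.1 Hz, at least a decade below plausible stepping frequencies of
#' 0.9-1.5 Hz) and then the residual mean, leaving the record zero-mean.
#' A constant signal maps to all zeros.
#'
#' @param sig A `uniform_signal`.
#' @param cutoff Baseline cutoff in Hz, default 0.1.
#' @param order Baseline filter order, default 2.
#' @return A drift-corrected `uniform_signal`.
#' @export
remove_drift <- function(sig, cutoff = 0.1, order = 2) {
  stopifnot(inherits(sig, "uniform_signal"))
  centered <- sig$values - mean(sig$values)  # exact for constant signals
  baseline <- lowpass_values(centered, sig$rate, cutoff, order)
  out <- sig
  resid <- centered - baseline
  out$values <- resid - mean(resid)
  out
}

#' Apply the anatomical sign convention
#'
#' Multiplies each channel by its configured sign so that upward thigh
#' movement (elevation) is positive and downward negative, matching the
#' motion-capture convention. Applying a map twice restores the original.
#'
#' @param tri A [triaxial_signal].
#' @param axis_map Named numeric vector of per-axis signs (+1/-1).
#' @return A [triaxial_signal] with signs applied; the applied map is
#'   recorded in the `"applied_axis_map"` attribute.
#' @export
apply_sign_convention <- function(tri, axis_map = c(x = 1, y = 1, z = 1)) {
  stopifnot(inherits(tri, "triaxial_signal"),
            all(c("x", "y", "z") %in% names(axis_map)),
            all(abs(axis_map[c("x", "y", "z")]) == 1))
  out <- tri
  for (ax in c("x", "y", "z")) out[[ax]]$values <- tri[[ax]]$values * axis_map[[ax]]
  attr(out, "applied_axis_map") <- axis_map
  out
}

#' Preprocess a raw phone stream end to end
#'
#' Convenience wrapper: resample to a uniform grid, apply the sensor's axis
#' sign map, and drift-correct every channel.
#'
#' @param raw A [raw_gyro_stream].
#' @param rate Target rate, default 60 Hz.
#' @param drift_cutoff Drift baseline cutoff, default 0.1 Hz.
#' @return A preprocessed [triaxial_signal].
#' @export
preprocess_phone <- function(raw, rate = 60, drift_cutoff = 0.1) {
  tri <- resample_uniform(raw, rate)
  tri <- apply_sign_convention(tri, raw$axis_map)
  for (ax in c("x", "y", "z"))
    tri[[ax]] <- remove_drift(tri[[ax]], cutoff = drift_cutoff)
  tri
}
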