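# Step-cycle peak detection. One positive omega_peak per step cycle: local
# maxima filtered by height and prominence, then a greedy separation rule
# (keep by descending height, ties to the earlier peak) enforcing the
# physiological minimum of ~0.4 s between successive same-leg cycles.

#' Per-cycle peak table
#'
#' Ordered set of step cycles: one row per detected peak with its time,
#' peak angular velocity, and duration (time to the next peak; `NA` for the
#' last cycle, whose duration is undefined).
#'
#' @param peak_time Strictly increasing peak times in seconds.
#' @param omega_peak Peak angular velocities, deg/s (> 0).
#' @param source Provenance label (e.g. `"reference"`, `"phone-AA"`,
#'   `"phone-ML"`, `"truth"`).
#' @param test_duration Nominal test duration in seconds, default 120.
#' @param duration Optional explicit durations (overrides the default
#'   successive-peak differences, e.g. when carrying anchor durations
#'   through a subset of cycles).
#' @return A data frame of class `cycle_set` with columns `index`,
#'   `peak_time`, `omega_peak`, `duration`.
#' @export
cycle_set <- function(peak_time = numeric(), omega_peak = numeric(),
                      source = "unknown", test_duration = 120,
                      duration = NULL) {
  if (length(peak_time) != length(omega_peak))
    skn_stop("peak_time and omega_peak lengths differ", "stepkin_contract_error")
  if (length(peak_time) > 1 && any(diff(peak_time) <= 0))
    skn_stop("peak times must be strictly increasing", "stepkin_contract_error")
  if (is.null(duration))
    duration <- if (length(peak_time)) c(diff(peak_time), NA_real_) else numeric()
  df <- data.frame(
    index = seq_along(peak_time),
    peak_time = as.numeric(peak_time),
    omega_peak = as.numeric(omega_peak),
    duration = as.numeric(duration)
  )
  structure(df, class = c("cycle_set", "data.frame"),
            source = source, test_duration = test_duration)
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles [%s], test duration %g s\n",
              nrow(x), attr(x, "source"), attr(x, "test_duration")))
  if (nrow(x)) {
    cat(sprintf("  omega_peak %.1f +/- %.1f deg/s; mean DUR %.3f s\n",
                mean(x$omega_peak), stats::sd(x$omega_peak),
                mean(x$duration, na.rm = TRUE)))
  }
  invisible(x)
}

#' Peak detector parameters
#'
#' Defaults derive from stepping physiology: cadence at most ~150
#' cycles/min per leg implies at least 0.4 s between successive peaks, and
#' genuine elevation peaks stand well above noise, hence a height floor of
#' 30% of the series' 95th percentile with half that as prominence floor.
#'
#' @param min_separation Minimum peak spacing in seconds, default 0.40.
#' @param min_height Minimum peak height in deg/s; `NULL` (default) means
#'   30% of the series' 95th percentile, resolved at detection time.
#' @param min_prominence Minimum topographic prominence; `NULL` (default)
#'   means `min_height / 2`.
#' @return An object of class `peak_detector_spec`.
#' @export
peak_detector_spec <- function(min_separation = 0.40, min_height = NULL,
                               min_prominence = NULL) {
  stopifnot(min_separation > 0)
  structure(list(min_separation = min_separation, min_height = min_height,
                 min_prominence = min_prominence),
            class = "peak_detector_spec")
}

# Topographic prominence of candidate peak i: on each side, walk until a
# strictly higher sample (or the edge); the base on that side is the lowest
# value passed. Prominence = height - max(left base, right base).
peak_prominence <- function(v, i) {
  h <- v[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && v[j] <= h) {
    if (v[j] < left_min) left_min <- v[j]
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  n <- length(v)
  while (j <= n && v[j] <= h) {
    if (v[j] < right_min) right_min <- v[j]
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

#' Detect one peak per step cycle
#'
#' Finds strict local maxima satisfying the height and prominence floors,
#' then greedily keeps candidates by descending height (ties to the earlier
#' peak) subject to the minimum separation, so that when two candidates are
#' too close the larger survives. Only positive (elevation-phase) peaks are
#' cycle events; lowering-phase minima are ignored.
#'
#' @param v An `angular_velocity_series` (or `uniform_signal`), deg/s.
#' @param spec A [peak_detector_spec].
#' @param refine Parabolically refine peak times and values through the
#'   three samples around each maximum? Default FALSE.
#' @param test_duration Nominal test duration recorded in the result.
#' @return A [cycle_set]; empty when no sample qualifies.
#' @export
detect_cycle_peaks <- function(v, spec = peak_detector_spec(), refine = FALSE,
                               test_duration = 120) {
  stopifnot(inherits(v, "uniform_signal"))
  src <- if (is.na(provenance(v))) "detected" else provenance(v)
  vals <- v$values
  n <- length(vals)
  min_height <- spec$min_height
  if (is.null(min_height))
    min_height <- 0.3 * stats::quantile(vals, 0.95, names = FALSE)
  min_prom <- spec$min_prominence
  if (is.null(min_prom)) min_prom <- min_height / 2
  if (n < 3 || max(vals) < min_height || min_height <= 0)
    return(cycle_set(source = src, test_duration = test_duration))

  core <- vals[2:(n - 1)]
  cand <- which(core > vals[1:(n - 2)] & core > vals[3:n]) + 1L
  cand <- cand[vals[cand] >= min_height]
  cand <- cand[vapply(cand, function(i) peak_prominence(vals, i), 0) >= min_prom]
  if (!length(cand))
    return(cycle_set(source = src, test_duration = test_duration))

  # greedy by descending height; order() is stable, so ties keep the earlier
  ord <- cand[order(-vals[cand], cand)]
  sep_n <- spec$min_separation * v$rate
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= sep_n)) kept <- c(kept, i)
  }
  kept <- sort(kept)

  times <- v$start_time + (kept - 1) / v$rate
  peaks <- vals[kept]
  if (refine) {
    dt <- 1 / v$rate
    for (k in seq_along(kept)) {
      i <- kept[k]
      if (i > 1 && i < n) {
        pb <- parabolic_peak(vals[i - 1], vals[i], vals[i + 1], dt)
        times[k] <- times[k] + pb$offset
        peaks[k] <- pb$value
      }
    }
  }
  cycle_set(times, peaks, source = src, test_duration = test_duration)
}

#' Parabolic refinement of a sampled peak
#'
#' Fits the unique parabola through three consecutive samples around a
#' sample-level maximum and returns the vertex. The sub-sample offset is
#' `p = 0.5 (y_prev - y_next) / (y_prev - 2 y0 + y_next)` samples and the
#' refined value `y0 - 0.25 (y_prev - y_next) p`; the refined value is never
#' below `y0`. A degenerate (flat) triple returns the sample unchanged.
#'
#' @param y_prev,y0,y_next Samples around the maximum (`y0` >= neighbours).
#' @param dt Sample interval in seconds.
#' @return List with `offset` (seconds relative to the center sample) and
#'   `value` (refined peak, same units as the inputs).
#' @export
parabolic_peak <- function(y_prev, y0, y_next, dt) {
  if (y0 < y_prev || y0 < y_next)
    skn_stop("center sample must be a local maximum", "stepkin_contract_error")
  denom <- y_prev - 2 * y0 + y_next
  if (denom == 0) return(list(offset = 0, value = y0))
  p <- 0.5 * (y_prev - y_next) / denom
  list(offset = p * dt, value = y0 - 0.25 * (y_prev - y_next) * p)
}
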