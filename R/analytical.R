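# Analytical approach (AA): adaptive second-order Butterworth low-pass
# filtering of the phone x axis. The cutoff tracks the dominant cycle
# frequency of a 10 s moving window (1 s overlap) through a linear mapping
# f_c = a * f_d + b fitted by an RMS-vs-reference criterion on training
# data, clamped to the 1-12 Hz candidate range.

#' Moving-window specification for the adaptive filter
#'
#' @param window Window length in seconds, default 10.
#' @param overlap Overlap between successive windows in seconds, default 1
#'   (so the hop is `window - overlap` = 9 s).
#' @param grid Candidate cutoff frequencies in Hz, default
#'   `seq(1, 12, by = 0.1)` (a fine grid over the 1-12 Hz range).
#' @return An object of class `windowing_spec`.
#' @export
windowing_spec <- function(window = 10, overlap = 1,
                           grid = round(seq(1, 12, by = 0.1), 10)) {
  stopifnot(window > 0, overlap > 0, overlap < window, all(grid > 0))
  structure(list(window = window, overlap = overlap, grid = grid),
            class = "windowing_spec")
}

#' Dominant cycle frequency of a window
#'
#' Mean-centers the segment, computes the real-valued discrete Fourier
#' transform, discards the 0 Hz bin and returns the frequency of the
#' maximum-magnitude bin; ties break toward the lower frequency.
#'
#' @param values Numeric segment (at least 1 s of samples) or a
#'   `uniform_signal` (then `rate` is taken from it).
#' @param rate Sampling rate in Hz.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(values, rate = NULL) {
  if (inherits(values, "uniform_signal")) {
    rate <- values$rate
    values <- values$values
  }
  stopifnot(!is.null(rate))
  n <- length(values)
  if (n < rate) skn_stop("segment shorter than 1 s", "stepkin_data_error")
  x <- values - mean(values)
  if (all(abs(x) < 1e-12))
    skn_stop("dominant frequency undefined for a constant segment",
             "stepkin_data_error")
  mag <- Mod(stats::fft(x))[2:(floor(n / 2) + 1)]
  (which.max(mag)) * rate / n
}

# Window start indices for a signal of n samples: full windows advance by
# the hop; a trailing remainder is handled by adaptive_filter directly.
window_starts <- function(n, win_n, hop_n) {
  if (n < win_n) return(integer())
  seq(1L, n - win_n + 1L, by = hop_n)
}

# Per-window (f_d, optimal cutoff) table for one synchronized phone/ref
# pair of equal-length numeric vectors.
cutoff_table <- function(phone, ref, rate, spec) {
  win_n <- round(spec$window * rate)
  hop_n <- round((spec$window - spec$overlap) * rate)
  starts <- window_starts(length(phone), win_n, hop_n)
  grid <- spec$grid[spec$grid < rate / 2]
  filters <- lapply(grid, function(c) signal::butter(2, c / (rate / 2), "low"))
  rows <- lapply(starts, function(s) {
    idx <- s:(s + win_n - 1L)
    pw <- phone[idx]; rw <- ref[idx]
    fd <- tryCatch(dominant_frequency(pw, rate), error = function(e) NA_real_)
    if (is.na(fd)) return(NULL)
    rms <- vapply(seq_along(grid), function(g) {
      sqrt(mean((lowpass_values(pw, rate, grid[g], flt = filters[[g]]) - rw)^2))
    }, 0)
    # argmin with machine-tolerance tie-break toward the lower cutoff
    c_opt <- grid[which(rms <= min(rms) * (1 + 1e-9))[1]]
    data.frame(f_d = fd, c_opt = c_opt)
  })
  do.call(rbind, rows)
}

new_cutoff_map <- function(a, b, clamp, n_windows, resid_rms, table,
                           train_subjects = character(), constant = FALSE) {
  structure(list(a = a, b = b, clamp = clamp, n_windows = n_windows,
                 resid_rms = resid_rms, table = table,
                 train_subjects = train_subjects, constant = constant),
            class = "cutoff_map")
}

#' @export
print.cutoff_map <- function(x, ...) {
  cat(sprintf("<cutoff_map> f_c = %.3f * f_d + %.3f Hz (clamped to [%g, %g]); %d windows, residual RMS %.3f Hz%s\n",
              x$a, x$b, x$clamp[1], x$clamp[2], x$n_windows, x$resid_rms,
              if (x$constant) " [constant]" else ""))
  invisible(x)
}

#' Constant cutoff map
#'
#' A degenerate [fit_cutoff_map()] result applying one fixed cutoff
#' everywhere (slope 0).
#'
#' @param cutoff Fixed cutoff in Hz.
#' @param clamp Clamp range, default `c(1, 12)` Hz.
#' @return A `cutoff_map`.
#' @export
constant_cutoff_map <- function(cutoff, clamp = c(1, 12)) {
  new_cutoff_map(0, cutoff, clamp, 0L, 0, NULL, constant = TRUE)
}

#' Cutoff a map assigns to a dominant frequency
#'
#' @param map A `cutoff_map`.
#' @param f_d Dominant frequency in Hz.
#' @return `clamp(a * f_d + b)` in Hz.
#' @export
map_cutoff <- function(map, f_d) {
  pmin(pmax(map$a * f_d + map$b, map$clamp[1]), map$clamp[2])
}

#' Fit the dominant-frequency to cutoff mapping
#'
#' For every moving window of the synchronized phone signal: compute the
#' dominant cycle frequency, low-pass the window at every candidate cutoff,
#' and score each cutoff by the RMS error against the reference window; the
#' argmin (ties toward the lower cutoff) is that window's optimal cutoff.
#' A least-squares line through the (f_d, optimal cutoff) pairs is the map.
#' If every window shares one dominant frequency the fit is singular and a
#' constant map (slope 0, intercept = median optimal cutoff) is returned.
#'
#' @param phone Phone x-axis `uniform_signal`, synchronized with `ref`
#'   (see [synchronize()] / [align_pair()]); same rate and length.
#' @param ref Reference `angular_velocity_series`.
#' @param spec A [windowing_spec].
#' @param train_subjects Optional subject ids recorded as fit provenance,
#'   enforced later by [run_analytical()].
#' @return A `cutoff_map` with fit diagnostics.
#' @export
fit_cutoff_map <- function(phone, ref, spec = windowing_spec(),
                           train_subjects = character()) {
  stopifnot(inherits(phone, "uniform_signal"), inherits(ref, "uniform_signal"))
  if (phone$rate != ref$rate || length(phone$values) != length(ref$values))
    skn_stop("phone and reference must be synchronized to a common grid",
             "stepkin_contract_error")
  tab <- cutoff_table(phone$values, ref$values, phone$rate, spec)
  fit_cutoff_map_tables(tab, spec, train_subjects)
}

#' Fit a cutoff map from pooled per-window tables
#'
#' Pools per-window (dominant frequency, optimal cutoff) tables from several
#' sessions and fits one line, as when one mapping serves a whole training
#' cohort.
#'
#' @param tab Data frame with columns `f_d`, `c_opt` (rows from one or more
#'   sessions; see [fit_cutoff_map()]).
#' @param spec A [windowing_spec] (supplies the clamp range).
#' @param train_subjects Subject ids recorded as fit provenance.
#' @return A `cutoff_map`.
#' @export
fit_cutoff_map_tables <- function(tab, spec = windowing_spec(),
                                  train_subjects = character()) {
  clamp <- range(spec$grid)
  if (is.null(tab) || nrow(tab) < 2)
    skn_stop("need >= 2 windows to fit a cutoff map", "stepkin_data_error")
  if (stats::var(tab$f_d) < 1e-12) {
    message("all windows share one dominant frequency; using a constant map")
    map <- new_cutoff_map(0, stats::median(tab$c_opt), clamp, nrow(tab), 0,
                          tab, train_subjects, constant = TRUE)
    return(map)
  }
  fit <- stats::lm(c_opt ~ f_d, data = tab)
  new_cutoff_map(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                 clamp, nrow(tab), sqrt(mean(stats::resid(fit)^2)), tab,
                 train_subjects)
}

#' Adaptive (window-wise) low-pass filtering
#'
#' Filters the signal piecewise: each 10 s window is zero-lag low-passed at
#' the cutoff the map assigns to its dominant frequency, and the 1 s overlap
#' between successive windows is merged by a linear crossfade (continuous
#' output, no amplitude doubling). Windows whose dominant frequency is
#' undefined (constant content) reuse the previous window's cutoff, or the
#' clamped intercept for the first. A trailing partial window is filtered at
#' the last full window's cutoff. Output length equals input length.
#'
#' @param sig A `uniform_signal` (phone x axis).
#' @param map A `cutoff_map` (fitted or constant).
#' @param spec A [windowing_spec].
#' @return A filtered `uniform_signal`; per-window cutoffs are recorded in
#'   the `"window_cutoffs"` attribute.
#' @export
adaptive_filter <- function(sig, map, spec = windowing_spec()) {
  stopifnot(inherits(sig, "uniform_signal"), inherits(map, "cutoff_map"))
  rate <- sig$rate
  v <- sig$values
  n <- length(v)
  win_n <- round(spec$window * rate)
  hop_n <- round((spec$window - spec$overlap) * rate)
  if (n < win_n)
    skn_stop("signal shorter than one window", "stepkin_data_error")
  starts <- window_starts(n, win_n, hop_n)
  segs <- lapply(starts, function(s) c(s, s + win_n - 1L))
  last_end <- segs[[length(segs)]][2]
  if (last_end < n)  # trailing partial window, reuses the last cutoff
    segs <- c(segs, list(c(min(starts[length(starts)] + hop_n, n - 1L), n)))

  out <- rep(NA_real_, n)
  prev_cut <- map_cutoff(map, 0)  # clamped intercept fallback
  cuts <- numeric(length(segs))
  covered <- 0L
  for (k in seq_along(segs)) {
    idx <- segs[[k]][1]:segs[[k]][2]
    full <- length(idx) >= win_n
    cut <- if (full) {
      fd <- tryCatch(dominant_frequency(v[idx], rate), error = function(e) NA_real_)
      if (is.na(fd)) prev_cut else map_cutoff(map, fd)
    } else prev_cut
    cut <- min(cut, 0.99 * rate / 2)
    cuts[k] <- prev_cut <- cut
    f <- lowpass_values(v[idx], rate, cut)
    ov <- which(idx <= covered)  # samples already written by the previous window
    if (length(ov)) {
      w <- seq(0, 1, length.out = length(ov))
      out[idx[ov]] <- (1 - w) * out[idx[ov]] + w * f[ov]
      out[idx[-ov]] <- f[-ov]
    } else out[idx] <- f
    covered <- max(covered, segs[[k]][2])
  }
  res <- sig
  res$values <- out
  attr(res, "window_cutoffs") <- cuts
  res
}

new_sync_result <- function(lag, correlation, rate, max_lag, low_confidence) {
  structure(list(lag = lag, correlation = correlation, rate = rate,
                 max_lag = max_lag, low_confidence = low_confidence),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag %.4f s, peak correlation %.3f%s\n",
              x$lag, x$correlation,
              if (x$low_confidence) " [LOW CONFIDENCE]" else ""))
  invisible(x)
}

#' Time-synchronize the phone to the reference
#'
#' Normalized cross-correlation over integer-sample lags within
#' `+/- max_lag`; the argmax is the phone's delay relative to the reference
#' (positive lag = phone events occur later). Downstream pairing shifts the
#' phone series by `-lag`. A peak correlation below 0.2 attaches a
#' low-confidence warning to the result.
#'
#' @param phone,ref `uniform_signal`s at the same rate.
#' @param max_lag Search half-range in seconds, default 2.
#' @return A `sync_result` with fields `lag` (s), `correlation`,
#'   `low_confidence`.
#' @export
synchronize <- function(phone, ref, max_lag = 2) {
  stopifnot(inherits(phone, "uniform_signal"), inherits(ref, "uniform_signal"))
  if (phone$rate != ref$rate)
    skn_stop("phone and reference must share a sampling rate",
             "stepkin_contract_error")
  rate <- phone$rate
  L <- round(max_lag * rate)
  p <- phone$values; r <- ref$values
  np <- length(p); nr <- length(r)
  best <- c(lag = NA_real_, cor = -Inf)
  for (k in -L:L) {
    # phone sample i aligns with ref sample i - k
    i1 <- max(1L, 1L + k); i2 <- min(np, nr + k)
    if (i2 - i1 + 1L < 10 * rate) next
    cc <- suppressWarnings(stats::cor(p[i1:i2], r[(i1 - k):(i2 - k)]))
    if (!is.na(cc) && cc > best["cor"]) best <- c(lag = k / rate, cor = cc)
  }
  if (!is.finite(best["cor"]))
    skn_stop("no lag leaves >= 10 s of overlap", "stepkin_data_error")
  low <- best["cor"] < 0.2
  if (low) warning("synchronization peak correlation below 0.2", call. = FALSE)
  new_sync_result(unname(best["lag"]), unname(best["cor"]), rate, max_lag, low)
}

#' Crop a synchronized pair to its common grid
#'
#' Shifts the phone series by the estimated lag and crops both series to the
#' overlapping span, returning two equal-length signals on the reference
#' time base.
#'
#' @param phone,ref `uniform_signal`s at the same rate (start times assumed
#'   on a common grid; the integer-sample lag comes from `sync`).
#' @param sync A `sync_result` from [synchronize()].
#' @return List with elements `phone` and `ref`.
#' @export
align_pair <- function(phone, ref, sync) {
  rate <- phone$rate
  k <- round(sync$lag * rate)
  np <- length(phone$values); nr <- length(ref$values)
  i1 <- max(1L, 1L + k); i2 <- min(np, nr + k)
  if (i2 <= i1) skn_stop("no overlap after shift", "stepkin_data_error")
  p <- phone; r <- ref
  p$values <- phone$values[i1:i2]
  r$values <- ref$values[(i1 - k):(i2 - k)]
  p$start_time <- r$start_time <- ref$start_time + (i1 - k - 1) / rate
  list(phone = p, ref = r)
}

#' Run the analytical pipeline on a phone signal
#'
#' The deployment path of the analytical approach: take the phone x axis,
#' apply the adaptive filter under a fixed (already fitted) cutoff map, and
#' detect one peak per step cycle. The detected peak values are the AA
#' omega_peak estimates. When the map records its training subjects,
#' evaluating a subject the map was fitted on raises a leakage error.
#'
#' @param phone A preprocessed [triaxial_signal].
#' @param map A fitted `cutoff_map`.
#' @param detector A [peak_detector_spec].
#' @param spec A [windowing_spec].
#' @param sync Optional `sync_result`; when given, peak times are shifted
#'   onto the reference time base (by `-lag`).
#' @param subject Optional subject id for the train/test provenance check.
#' @param test_duration Nominal test duration, default 120 s.
#' @return A [cycle_set] tagged `"phone-AA"`.
#' @export
run_analytical <- function(phone, map, detector = peak_detector_spec(),
                           spec = windowing_spec(), sync = NULL,
                           subject = NULL, test_duration = 120) {
  stopifnot(inherits(phone, "triaxial_signal"))
  if (!is.null(subject) && length(map$train_subjects) &&
      subject %in% map$train_subjects)
    skn_stop(sprintf("subject '%s' was used to fit this cutoff map", subject),
             "stepkin_leakage_error")
  x <- phone$x
  if (length(x$values) < round(spec$window * x$rate))
    return(cycle_set(source = "phone-AA", test_duration = test_duration))
  filtered <- adaptive_filter(x, map, spec)
  filtered <- set_provenance(filtered, "phone-AA")
  cycles <- detect_cycle_peaks(filtered, detector, test_duration = test_duration)
  if (!is.null(sync) && nrow(cycles)) {
    shifted <- cycles$peak_time - sync$lag
    cycles <- cycle_set(shifted, cycles$omega_peak, source = "phone-AA",
                        test_duration = test_duration)
  }
  cycles
}
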