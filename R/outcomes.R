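# 2MST outcome variables computed from a cycle table: step count (STP),
# cycle duration (DUR) statistics, cadence, rate of performance change
# (RPC) with strategy classification, and coefficients of variation.

#' RPC configuration
#'
#' @param edge_window Length of the initial/final averaging windows in
#'   seconds, default 20; must not exceed half the test duration.
#' @param band Steady-band half-width in deg/s, default 11.5; the boundary
#'   is inclusive (an RPC of exactly +/- band is "steady").
#' @return An object of class `rpc_config`.
#' @export
rpc_config <- function(edge_window = 20, band = 11.5) {
  stopifnot(edge_window > 0, band >= 0)
  structure(list(edge_window = edge_window, band = band), class = "rpc_config")
}

#' Classify the rate of performance change
#'
#' The three labels partition the real line: `|rpc| <= band` is `"steady"`
#' (inclusive boundary), `rpc > band` is `"ascending"`, `rpc < -band` is
#' `"descending"`.
#'
#' @param rpc RPC value in deg/s (finite).
#' @param cfg An [rpc_config].
#' @return One of `"steady"`, `"ascending"`, `"descending"`.
#' @export
classify_rpc <- function(rpc, cfg = rpc_config()) {
  stopifnot(is.finite(rpc))
  if (abs(rpc) <= cfg$band) "steady" else if (rpc > cfg$band) "ascending"
  else "descending"
}

#' Summarize a 2MST cycle set
#'
#' Computes the outcome variables: STP (cycle count), DUR statistics over
#' the defined durations (the last cycle's duration is undefined), cadence
#' over the nominal test duration, mean/SD/CV of omega_peak, and RPC — the
#' difference between the mean omega_peak of cycles peaking in the final
#' `edge_window` seconds and those peaking in the initial `edge_window`
#' seconds, reported in deg/s (the units of the classification band); the
#' per-second slope between window centers is reported alongside. Window
#' membership is by peak time. An empty edge window leaves RPC `NA` with
#' `rpc_defined = FALSE`; a zero mean leaves the CV `NA`.
#'
#' @param cycles A [cycle_set] with >= 2 cycles.
#' @param cfg An [rpc_config].
#' @return An object of class `outcome_summary`.
#' @export
summarize_cycles <- function(cycles, cfg = rpc_config()) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (nrow(cycles) < 2)
    skn_stop("need >= 2 cycles to summarize", "stepkin_data_error")
  td <- attr(cycles, "test_duration")
  if (cfg$edge_window > td / 2)
    skn_stop("edge window exceeds half the test duration", "stepkin_parameter_error")
  cyc <- cycles[order(cycles$peak_time), ]
  durs <- cyc$duration[!is.na(cyc$duration)]
  om <- cyc$omega_peak
  cv <- function(v) {
    m <- mean(v)
    if (abs(m) < 1e-12) NA_real_ else 100 * stats::sd(v) / m
  }
  init <- om[cyc$peak_time <= cfg$edge_window]
  fin <- om[cyc$peak_time >= td - cfg$edge_window]
  rpc_defined <- length(init) > 0 && length(fin) > 0
  rpc <- if (rpc_defined) mean(fin) - mean(init) else NA_real_
  structure(list(
    stp = nrow(cyc),
    mean_dur = mean(durs), sd_dur = stats::sd(durs), cv_dur = cv(durs),
    cadence = nrow(cyc) / (td / 60),
    mean_omega_peak = mean(om), sd_omega_peak = stats::sd(om),
    cv_omega_peak = cv(om),
    rpc = rpc,
    rpc_slope = if (rpc_defined) rpc / (td - cfg$edge_window) else NA_real_,
    rpc_class = if (rpc_defined) classify_rpc(rpc, cfg) else NA_character_,
    rpc_defined = rpc_defined,
    edge_window = cfg$edge_window, band = cfg$band,
    test_duration = td, source = attr(cycles, "source")
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> [%s] STP %d, cadence %.1f cycles/min\n",
              x$source, x$stp, x$cadence))
  cat(sprintf("  DUR %.3f +/- %.3f s (CV %.1f%%); omega_peak %.1f +/- %.1f deg/s (CV %.1f%%)\n",
              x$mean_dur, x$sd_dur, x$cv_dur,
              x$mean_omega_peak, x$sd_omega_peak, x$cv_omega_peak))
  if (x$rpc_defined)
    cat(sprintf("  RPC %.1f deg/s -> %s (band +/- %g)\n", x$rpc, x$rpc_class, x$band))
  invisible(x)
}
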