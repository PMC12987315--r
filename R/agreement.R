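# Bland-Altman method agreement between paired per-cycle measurements from
# two sources, with proportional-bias diagnostics.

#' Bland-Altman agreement analysis
#'
#' Differences are first-named minus second (`a - b`); the report records
#' the orientation so signs stay auditable. Bias is the mean difference,
#' `sd_diff` the sample SD (n - 1), and the 95% limits of agreement are
#' `bias +/- 1.96 sd_diff`. Proportional bias is the slope of the
#' regression of differences on pair means (with its p-value), and a
#' heteroscedasticity indicator is reported as the correlation between
#' absolute regression residuals and pair means.
#'
#' @param a,b Paired numeric vectors of equal length (>= 3), paired by
#'   cycle.
#' @param labels Character 2-vector naming the sources of `a` and `b`.
#' @return An object of class `agreement_report`.
#' @export
bland_altman <- function(a, b, labels = c("a", "b")) {
  if (length(a) != length(b))
    skn_stop("paired series must have equal length", "stepkin_pairing_error")
  if (length(a) < 3)
    skn_stop("need >= 3 pairs for agreement analysis", "stepkin_data_error")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  slope <- 0; p <- NA_real_; het <- NA_real_
  if (sd_diff > 1e-12 && stats::var(m) > 1e-12) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    p <- suppressWarnings(summary(fit)$coefficients[2, 4])
    ar <- abs(stats::resid(fit))
    if (stats::sd(ar) > 1e-12) het <- stats::cor(ar, m)
  }
  structure(list(
    n = length(a), bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    prop_bias_slope = slope, prop_bias_p = p,
    abs_resid_cor = het,
    orientation = sprintf("%s - %s", labels[1], labels[2]),
    labels = labels
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$orientation, x$n))
  cat(sprintf("  bias %.2f, 95%% LoA [%.2f, %.2f] (sd_diff %.2f)\n",
              x$bias, x$loa_low, x$loa_high, x$sd_diff))
  cat(sprintf("  proportional bias slope %.4f (p = %s)\n", x$prop_bias_slope,
              if (is.na(x$prop_bias_p)) "NA" else sprintf("%.3g", x$prop_bias_p)))
  invisible(x)
}
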