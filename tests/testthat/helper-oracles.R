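# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive expected values through a different route
# than the package implementation.

# Brute-force peak oracle: enumerate strict local maxima, filter by height
# and (loop-computed) prominence, then greedily keep by descending height
# subject to the separation constraint. Plain loops throughout.
oracle_peaks <- function(values, rate, min_separation, min_height, min_prom) {
  n <- length(values)
  cand <- integer()
  for (i in 2:(n - 1)) {
    if (values[i] > values[i - 1] && values[i] > values[i + 1] &&
        values[i] >= min_height) cand <- c(cand, i)
  }
  proms <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- values[i]
    lmin <- h
    for (j in seq(i - 1, 1)) {
      if (values[j] > h) break
      if (values[j] < lmin) lmin <- values[j]
    }
    rmin <- h
    for (j in seq(i + 1, n)) {
      if (values[j] > h) break
      if (values[j] < rmin) rmin <- values[j]
    }
    proms[k] <- h - max(lmin, rmin)
  }
  cand <- cand[proms >= min_prom]
  ord <- cand[order(-values[cand], cand)]
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) if (abs(i - j) < min_separation * rate) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Squared Butterworth magnitude response of a zero-lag (forward-backward)
# 2nd-order low-pass: |H(f)|^2 = 1 / (1 + (f/fc)^4).
zerolag_butter2_gain <- function(f, fc) 1 / (1 + (f / fc)^4)

# Amplitude of a sinusoid in the interior of a signal (avoids edge
# transients) via least squares on sin/cos regressors.
fitted_amplitude <- function(values, rate, freq, trim = 1) {
  n <- length(values)
  idx <- seq(round(trim * rate) + 1, n - round(trim * rate))
  t <- (idx - 1) / rate
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- solve(crossprod(X), crossprod(X, values[idx]))
  sqrt(sum(cf^2))
}

# Exact vertex of the parabola through points (-1, y1), (0, y2), (1, y3),
# solved from the Vandermonde system (independent of the closed form used
# in the package).
oracle_parabola_vertex <- function(y1, y2, y3) {
  A <- rbind(c(1, -1, 1), c(0, 0, 1), c(1, 1, 1))
  abc <- solve(A, c(y1, y2, y3))
  xv <- -abc[2] / (2 * abc[1])
  list(x = xv, y = abc[1] * xv^2 + abc[2] * xv + abc[3])
}

# A noise-free session spec: every channel defect switched off (overridable).
clean_spec <- function(...) {
  defaults <- list(marker_noise_sd = 0, compression = 0,
                   crosstalk = c(y = 0, z = 0), noise_sd = 0, drift_rate = 0,
                   jitter_sd = 0, dup_prob = 0, lag = 0, omega_peak_sd = 0,
                   cycle_duration_sd = 0, device_x_sign = 1)
  do.call(session_spec, utils::modifyList(defaults, list(...)))
}

make_uniform <- function(values, rate = 60, start = 0) {
  uniform_signal(values, rate = rate, start_time = start)
}

sine_signal <- function(freq, amp = 1, dur = 10, rate = 60, start = 0) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  make_uniform(amp * sin(2 * pi * freq * t), rate, start)
}
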