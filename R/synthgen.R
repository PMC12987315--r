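# Synthetic paired-session generator. Each step cycle is a raised-cosine
# thigh elevation pulse 0 -> theta_max -> 0 over its duration T, so the
# angular velocity is a single sine period with closed-form peak
# omega = pi * theta_max / T at T/4 into the cycle. Ground-truth per-cycle
# peaks therefore come from pulse calculus, never from peak-picking on
# sampled data, which makes the generator a valid oracle for both phone
# pipelines. The phone channel model reproduces the defects seen in real
# sensor logs: amplitude nonlinearity (soft saturation), inter-axis
# crosstalk, additive noise, slow drift, 58-62 Hz timestamp jitter,
# duplicate stamps, a constant inter-device lag, and a flipped device axis.

#' Synthetic session specification
#'
#' Defaults describe one 120 s 2MST by a typical healthy adult: mean cycle
#' duration 0.84 s, mean peak thigh angular velocity 303 deg/s.
#'
#' @param duration Test duration in seconds, default 120.
#' @param rate Sampling/frame rate in Hz, default 60.
#' @param cycle_duration_mean,cycle_duration_sd Per-cycle duration
#'   distribution in seconds (truncated normal, >= 0.4 s).
#' @param omega_peak_mean,omega_peak_sd Per-cycle true peak angular
#'   velocity distribution, deg/s.
#' @param trend First-to-last-cycle difference in peak velocity, deg/s
#'   (controls the RPC class; 0 = steady).
#' @param thigh_length Hip-to-knee marker distance, meters.
#' @param hip_height Hip marker height, meters.
#' @param marker_noise_sd Marker position noise SD, meters.
#' @param gain Phone amplitude gain (1 = faithful).
#' @param compression Saturating-compression coefficient kappa in
#'   `v -> v / (1 + kappa |v| / 300)`; the 300 deg/s scale places the
#'   nonlinearity in the observed peak range.
#' @param crosstalk Named fractions of the x signal leaking into y and z.
#' @param noise_sd Additive phone sensor noise SD, deg/s.
#' @param drift_rate Slow drift ramp, deg/s per minute.
#' @param jitter_sd Timestamp interval jitter SD, seconds.
#' @param dup_prob Probability that a sample repeats the previous timestamp.
#' @param lag Constant inter-device lag (phone behind reference), seconds.
#' @param padding Phone recording margin before/after the test, seconds.
#' @param device_x_sign Sign of the device x axis relative to the
#'   anatomical convention (the reader's axis map undoes it).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(duration = 120, rate = 60,
                         cycle_duration_mean = 0.84, cycle_duration_sd = 0.05,
                         omega_peak_mean = 303, omega_peak_sd = 15,
                         trend = 0,
                         thigh_length = 0.40, hip_height = 0.95,
                         marker_noise_sd = 0.001,
                         gain = 1, compression = 0.10,
                         crosstalk = c(y = 0.06, z = 0.03),
                         noise_sd = 8, drift_rate = 3,
                         jitter_sd = 0.002, dup_prob = 0.01,
                         lag = 0.18, padding = 1.0,
                         device_x_sign = -1) {
  stopifnot(duration > 0, cycle_duration_mean > 0, cycle_duration_sd >= 0,
            omega_peak_sd >= 0, compression >= 0, noise_sd >= 0,
            jitter_sd >= 0, dup_prob >= 0, dup_prob < 1, padding >= 0)
  if (cycle_duration_mean > duration)
    skn_stop("mean cycle duration exceeds the test duration", "stepkin_spec_error")
  structure(as.list(environment()), class = "session_spec")
}

compress_amplitude <- function(v, kappa) v / (1 + kappa * abs(v) / 300)

#' Simulate one paired phone + motion-capture session
#'
#' Draws cycle durations (truncated normal, >= 0.4 s) until the test
#' duration is filled, assigns each cycle a true peak velocity (linear
#' first-to-last trend plus noise) and the implied raised-cosine pulse
#' amplitude, then renders (a) the marker trajectory from the closed-form
#' thigh angle plus marker noise and (b) the phone stream through the
#' channel model (gain, saturating compression, crosstalk, noise, drift,
#' timestamp jitter, duplicate stamps, lag, device axis sign). All
#' randomness derives from `seed`; the same spec and seed reproduce the
#' session bit for bit.
#'
#' @param spec A [session_spec].
#' @param seed Integer seed.
#' @param subject Subject id attached to the session.
#' @return An object of class `synthetic_session`: `truth` (a [cycle_set]
#'   of closed-form peaks), `phone` (a [raw_gyro_stream]), `markers` (a
#'   [marker_trajectory]), the continuous truth functions `v_true(t)` and
#'   `angle_true(t)`, plus the spec, seed and subject.
#' @export
simulate_session <- function(spec = session_spec(), seed = 1, subject = "s1") {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(seed)

  # cycle skeleton
  draw_T <- function() {
    repeat {
      t <- stats::rnorm(1, spec$cycle_duration_mean, spec$cycle_duration_sd)
      if (t >= 0.4) return(t)
    }
  }
  Ts <- numeric()
  total <- 0
  repeat {
    t <- draw_T()
    if (total + t > spec$duration) break
    Ts <- c(Ts, t)
    total <- total + t
  }
  m <- length(Ts)
  if (m < 2) skn_stop("spec yields fewer than 2 cycles", "stepkin_spec_error")
  starts <- cumsum(c(0, Ts[-m]))
  pos <- if (m > 1) (seq_len(m) - 1) / (m - 1) else 0.5
  omega <- spec$omega_peak_mean + spec$trend * (pos - 0.5) +
    stats::rnorm(m, 0, spec$omega_peak_sd)
  omega <- pmax(omega, 20)
  theta <- omega * Ts / pi          # raised-cosine pulse amplitude, degrees
  peak_times <- starts + Ts / 4

  cyc_at <- function(t) {
    i <- findInterval(t, starts)
    i[t < 0 | t >= total] <- 0L
    i
  }
  v_true <- function(t) {
    i <- cyc_at(t)
    out <- numeric(length(t))
    ok <- i > 0
    out[ok] <- omega[i[ok]] * sin(2 * pi * (t[ok] - starts[i[ok]]) / Ts[i[ok]])
    out
  }
  angle_true <- function(t) {
    i <- cyc_at(t)
    out <- numeric(length(t))
    ok <- i > 0
    out[ok] <- theta[i[ok]] / 2 *
      (1 - cos(2 * pi * (t[ok] - starts[i[ok]]) / Ts[i[ok]]))
    out
  }

  # marker trajectory on the reference clock
  ft <- seq(0, spec$duration, by = 1 / spec$rate)
  ang <- angle_true(ft) * pi / 180
  nfr <- length(ft)
  mn <- function() matrix(stats::rnorm(2 * nfr, 0, spec$marker_noise_sd), ncol = 2)
  hip <- cbind(0, spec$hip_height)[rep(1, nfr), ] + mn()
  knee <- cbind(spec$thigh_length * sin(ang),
                spec$hip_height - spec$thigh_length * cos(ang)) + mn()
  markers <- marker_trajectory(hip, knee, frame_rate = spec$rate)

  # phone stream on its own jittered clock
  n_est <- ceiling((spec$duration + 2 * spec$padding) * spec$rate * 1.2)
  dts <- pmin(pmax(stats::rnorm(n_est, 1 / spec$rate, spec$jitter_sd),
                   0.5 / spec$rate), 1.5 / spec$rate)
  actual <- cumsum(c(0, dts))
  actual <- actual[actual <= spec$duration + 2 * spec$padding]
  np <- length(actual)
  stamps <- actual
  dup <- which(stats::runif(np) < spec$dup_prob & seq_len(np) > 1)
  stamps[dup] <- stamps[dup - 1L]

  tt <- actual - spec$padding - spec$lag     # truth time of each sample
  x_sig <- spec$gain * compress_amplitude(v_true(tt), spec$compression)
  drift <- spec$drift_rate * actual / 60
  x <- spec$device_x_sign * (x_sig + drift + stats::rnorm(np, 0, spec$noise_sd))
  y <- spec$crosstalk[["y"]] * x_sig + drift + stats::rnorm(np, 0, spec$noise_sd)
  z <- spec$crosstalk[["z"]] * x_sig + drift + stats::rnorm(np, 0, spec$noise_sd)
  phone <- raw_gyro_stream(stamps, x, y, z,
                           axis_map = c(x = spec$device_x_sign, y = 1, z = 1))

  truth <- cycle_set(peak_times, omega, source = "truth",
                     test_duration = spec$duration)
  structure(list(truth = truth, phone = phone, markers = markers,
                 v_true = v_true, angle_true = angle_true,
                 spec = spec, seed = seed, subject = subject),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> subject %s (seed %d): %d true cycles, omega_peak %.1f +/- %.1f deg/s\n",
              x$subject, x$seed, nrow(x$truth), mean(x$truth$omega_peak),
              stats::sd(x$truth$omega_peak)))
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject session parameters are drawn from population distributions
#' describing healthy adults performing the 2MST: subject mean peak
#' velocity ~ Normal(303, 39) deg/s, mean cycle duration ~ Normal(0.84,
#' 0.11) s, within-subject duration CV ~ Normal(3.9, 1.6)%%, and a
#' 40/40/20 steady/descending/ascending mixture of pacing-strategy trends.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed driving all draws.
#' @param spec Base [session_spec]; per-subject draws override the cycle
#'   duration, peak velocity and trend fields.
#' @return List of `synthetic_session` objects with subject ids
#'   `"s01", "s02", ...`.
#' @export
default_cohort <- function(n_subjects, seed = 1, spec = session_spec()) {
  if (n_subjects < 2)
    skn_stop("a cohort needs >= 2 subjects", "stepkin_spec_error")
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  omega_means <- pmin(pmax(stats::rnorm(n_subjects, 303, 39), 204), 444)
  dur_means <- pmin(pmax(stats::rnorm(n_subjects, 0.84, 0.11), 0.65), 1.06)
  dur_cvs <- pmin(pmax(stats::rnorm(n_subjects, 3.9, 1.6), 1.5), 9.7)
  classes <- sample(c("steady", "descending", "ascending"), n_subjects,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
  trends <- vapply(classes, function(cl) {
    switch(cl,
           steady = stats::rnorm(1, 0, 4),
           descending = min(stats::rnorm(1, -25, 4), -20),
           ascending = max(stats::rnorm(1, 33, 5), 25))
  }, 0)
  lapply(seq_len(n_subjects), function(i) {
    s <- spec
    s$omega_peak_mean <- omega_means[i]
    s$omega_peak_sd <- 0.05 * omega_means[i]
    s$cycle_duration_mean <- dur_means[i]
    s$cycle_duration_sd <- dur_cvs[i] / 100 * dur_means[i]
    s$trend <- trends[i]
    sess <- simulate_session(s, seed = session_seeds[i],
                             subject = sprintf("s%02d", i))
    attr(sess, "strategy_class") <- classes[i]
    sess
  })
}

#' Write a synthetic session to disk through the package writers
#'
#' Exercises the file readers end to end: the phone stream and marker
#' trajectory go through [write_gyro_csv()] / [write_marker_csv()], the
#' ground-truth cycles through [write_cycles_csv()], and the spec (minus
#' the closure fields) through JSON.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$subject
  write_gyro_csv(session$phone, file.path(dir, sprintf("phone_%s.csv", id)))
  write_marker_csv(session$markers, file.path(dir, sprintf("markers_%s.csv", id)))
  write_cycles_csv(session$truth, file.path(dir, sprintf("truth_%s.csv", id)))
  meta <- session$spec
  meta$subject <- id
  meta$seed <- session$seed
  jsonlite::write_json(unclass(meta), file.path(dir, sprintf("spec_%s.json", id)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
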