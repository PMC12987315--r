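test_that("thigh angle follows the vertical-reference convention", {
  hip <- rbind(c(0, 1), c(0, 1), c(0, 1))
  knee <- rbind(c(0, 0),                      # knee straight below: 0 deg
                c(1, 1),                      # thigh horizontal, knee forward: 90
                c(sqrt(2) / 2, 1 - sqrt(2) / 2))  # 45
  ang <- thigh_angle(marker_trajectory(hip, knee, frame_rate = 60))
  expect_equal(ang$values, c(0, 90, 45), tolerance = 1e-10)
})

test_that("thigh angle is invariant to translation and segment scaling", {
  set.seed(2)
  n <- 50
  theta <- seq(0, 80, length.out = n) * pi / 180
  hip <- cbind(rep(0, n), rep(1, n))
  knee <- hip + 0.4 * cbind(sin(theta), -cos(theta))
  base <- thigh_angle(marker_trajectory(hip, knee))$values
  shift <- cbind(rep(3.2, n), rep(-1.7, n))
  moved <- thigh_angle(marker_trajectory(hip + shift, knee + shift))$values
  scaled <- thigh_angle(marker_trajectory(hip, hip + 2.5 * (knee - hip)))$values
  expect_equal(moved, base, tolerance = 1e-10)
  expect_equal(scaled, base, tolerance = 1e-10)
})

test_that("degenerate (coincident) markers are rejected", {
  hip <- rbind(c(0, 1), c(0, 1))
  expect_error(marker_trajectory(hip, hip), "coincide",
               class = "stepkin_data_error")
})

test_that("short marker gaps are spline-filled, long gaps warned about", {
  n <- 120
  theta <- (40 + 40 * sin(2 * pi * (0:(n - 1)) / 60)) * pi / 180
  hip <- cbind(rep(0, n), rep(1, n))
  knee <- hip + 0.4 * cbind(sin(theta), -cos(theta))
  knee_gap <- knee
  knee_gap[50:52, ] <- NA
  ang <- thigh_angle(marker_trajectory(hip, knee_gap, gap_mask = NULL))
  truth <- thigh_angle(marker_trajectory(hip, knee))
  expect_lt(max(abs(ang$values - truth$values)), 0.5)

  knee_gap[30:44, ] <- NA  # 15-frame gap
  expect_warning(thigh_angle(marker_trajectory(hip, knee_gap)), "15-frame")
})

test_that("zero-lag Butterworth gains match the squared analytic response", {
  spec <- filter_spec(order = 2, cutoff = 6)
  const <- make_uniform(rep(7, 300))
  expect_equal(butterworth_lowpass(const, spec)$values, rep(7, 300),
               tolerance = 1e-9)

  s1 <- sine_signal(1, amp = 1, dur = 20, rate = 60)
  g1 <- fitted_amplitude(butterworth_lowpass(s1, spec)$values, 60, 1)
  expect_equal(g1, 1, tolerance = 0.01)
  expect_equal(g1, zerolag_butter2_gain(1, 6), tolerance = 0.005)
  # phase: zero-lag output stays in phase with the input (shift < 1 deg)
  y <- butterworth_lowpass(s1, spec)$values
  t <- signal_times(s1)
  idx <- seq(300, length(t) - 300)
  ph <- atan2(sum(y[idx] * cos(2 * pi * t[idx])), sum(y[idx] * sin(2 * pi * t[idx])))
  expect_lt(abs(ph) * 180 / pi, 1)

  s30 <- sine_signal(30, amp = 1, dur = 20, rate = 120)
  g30 <- fitted_amplitude(butterworth_lowpass(s30, spec)$values, 120, 30)
  expect_lt(g30, 0.01)

  expect_error(butterworth_lowpass(s1, filter_spec(cutoff = 40)),
               "Nyquist", class = "stepkin_parameter_error")
})

test_that("differentiation matches closed-form derivatives", {
  ramp <- make_uniform(10 * (0:299) / 60)
  class(ramp) <- c("angle_series", class(ramp))
  v <- differentiate(ramp)
  expect_equal(v$values[2:299], rep(10, 298), tolerance = 1e-9)
  expect_identical(provenance(v), "reference")

  const <- make_uniform(rep(42, 100))
  expect_equal(differentiate(const)$values, rep(0, 100))

  A <- 30; f <- 1
  ang <- sine_signal(f, amp = A, dur = 30, rate = 60)
  amp <- fitted_amplitude(differentiate(ang)$values, 60, f)
  expect_equal(amp, 2 * pi * f * A, tolerance = 0.01)
})

test_that("differentiate inverts cumulative integration for band-limited signals", {
  set.seed(4)
  rate <- 60
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  v <- 40 * sin(2 * pi * 1.2 * t) + 15 * sin(2 * pi * 2.7 * t + 0.4)
  integral <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2)) / rate  # trapezoid
  rec <- differentiate(make_uniform(integral, rate))$values
  idx <- 10:(length(v) - 10)
  expect_lt(sqrt(mean((rec[idx] - v[idx])^2)) / sqrt(mean(v^2)), 0.02)
})

test_that("the reference chain recovers closed-form peaks on clean sessions", {
  sess <- simulate_session(clean_spec(), seed = 9)
  cycles <- reference_cycles(sess$markers)
  expect_equal(nrow(cycles), nrow(sess$truth))
  expect_lt(max(abs(cycles$omega_peak - sess$truth$omega_peak) /
                  sess$truth$omega_peak), 0.01)
})
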