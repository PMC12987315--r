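test_that("a clean stepping sine yields one peak per period", {
  t <- seq(0, 120 - 1 / 60, by = 1 / 60)
  v <- make_uniform(300 * sin(2 * pi * 1 * t))
  cycles <- detect_cycle_peaks(v)
  expect_equal(nrow(cycles), 120)
  expect_true(all(abs(cycles$omega_peak - 300) <= 1))
  expect_equal(cycles$duration[-120], rep(1, 119), tolerance = 1e-6)
})

test_that("the separation rule suppresses spurious bumps near true peaks", {
  rate <- 60
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  v <- 300 * sin(2 * pi * t)
  # a half-height bump 0.1 s after each true peak
  bump_idx <- round((which(abs(t %% 1 - 0.25) < 1e-9) - 1) + 0.1 * rate) + 1
  bump <- numeric(length(t))
  for (b in bump_idx) {
    win <- max(1, b - 3):min(length(t), b + 3)
    bump[win] <- bump[win] + 150 * exp(-((win - b) / 1.5)^2)
  }
  sig <- make_uniform(v + bump)
  cycles <- detect_cycle_peaks(sig)
  expect_equal(nrow(cycles), 120)
  spec <- peak_detector_spec()
  mh <- 0.3 * quantile(sig$values, 0.95, names = FALSE)
  oracle <- oracle_peaks(sig$values, rate, spec$min_separation, mh, mh / 2)
  expect_equal(round((cycles$peak_time) * rate) + 1, oracle)
})

test_that("degenerate series yield empty cycle sets", {
  expect_equal(nrow(detect_cycle_peaks(make_uniform(rep(0, 500)))), 0)
  expect_equal(nrow(detect_cycle_peaks(make_uniform(c(0, 1)))), 0)
})

test_that("the detector agrees with the brute-force oracle on random series", {
  set.seed(123)
  flt <- signal::butter(2, 0.1, "low")
  for (i in 1:40) {
    n <- sample(500:4000, 1)
    raw <- rnorm(n)
    smooth <- as.numeric(signal::filtfilt(flt, raw)) * 100
    sig <- make_uniform(smooth, rate = 60)
    spec <- peak_detector_spec(min_separation = runif(1, 0.2, 0.6))
    got <- detect_cycle_peaks(sig, spec)
    mh <- 0.3 * quantile(smooth, 0.95, names = FALSE)
    if (mh <= 0) next
    want <- oracle_peaks(smooth, 60, spec$min_separation, mh, mh / 2)
    expect_equal(round(got$peak_time * 60) + 1, want)
  }
})

test_that("parabolic refinement matches the exact vertex and never lowers a peak", {
  expect_equal(parabolic_peak(1, 3, 1, 1 / 60), list(offset = 0, value = 3))
  expect_equal(parabolic_peak(2, 2, 2, 1 / 60), list(offset = 0, value = 2))

  got <- parabolic_peak(1, 3, 2, dt = 1)
  vert <- oracle_parabola_vertex(1, 3, 2)
  expect_equal(got$offset, vert$x, tolerance = 1e-12)
  expect_equal(got$value, vert$y, tolerance = 1e-12)
  expect_equal(got$offset, 1 / 6, tolerance = 1e-12)

  expect_error(parabolic_peak(3, 1, 2, 1), class = "stepkin_contract_error")

  set.seed(11)
  for (i in 1:200) {
    y0 <- runif(1, 1, 10)
    yp <- y0 - runif(1, 0, 5)
    yn <- y0 - runif(1, 0, 5)
    r <- parabolic_peak(yp, y0, yn, 1 / 60)
    expect_gte(r$value, y0 - 1e-12)
    expect_lt(abs(r$offset), 0.5 / 60 + 1e-12)
  }
})

test_that("cycle sets validate ordering and expose durations", {
  expect_error(cycle_set(c(1, 1), c(2, 2)), "strictly increasing",
               class = "stepkin_contract_error")
  cs <- cycle_set(c(0.2, 1.1, 1.9), c(300, 310, 305))
  expect_equal(cs$duration, c(0.9, 0.8, NA))
})
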