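test_that("identical spec and seed reproduce a session bit for bit", {
  s1 <- simulate_session(session_spec(duration = 30), seed = 77)
  s2 <- simulate_session(session_spec(duration = 30), seed = 77)
  expect_identical(s1$phone$time, s2$phone$time)
  expect_identical(s1$phone$x, s2$phone$x)
  expect_identical(s1$markers$knee, s2$markers$knee)
  expect_identical(s1$truth$omega_peak, s2$truth$omega_peak)
})

test_that("cycle count follows the renewal expectation", {
  counts <- vapply(1:5, function(i)
    nrow(simulate_session(session_spec(), seed = 200 + i)$truth), 0L)
  expect_true(all(abs(counts - 120 / 0.84) <= 3))
})

test_that("closed-form ground truth matches peak-picking on clean sessions", {
  sess <- simulate_session(clean_spec(), seed = 55)
  v <- reference_velocity(sess$markers)
  det <- detect_cycle_peaks(v, refine = TRUE,
                            test_duration = sess$spec$duration)
  expect_equal(nrow(det), nrow(sess$truth))
  expect_lt(max(abs(det$omega_peak - sess$truth$omega_peak) /
                  sess$truth$omega_peak), 0.01)
  # ground truth equals the pulse calculus directly: omega = pi * theta / T
  i <- which.max(sess$truth$omega_peak)
  t_fine <- seq(sess$truth$peak_time[i] - 0.05, sess$truth$peak_time[i] + 0.05,
                by = 1e-4)
  expect_equal(max(sess$v_true(t_fine)), sess$truth$omega_peak[i],
               tolerance = 1e-4)
})

test_that("the phone channel model produces the configured defects", {
  spec <- session_spec(dup_prob = 0.05, jitter_sd = 0.003)
  sess <- simulate_session(spec, seed = 31)
  dt <- diff(sess$phone$time)
  expect_gt(sum(dt == 0), 0)                       # duplicate stamps
  expect_gt(sd(dt[dt > 0]), 0.0005)                # jitter
  rate_obs <- 1 / mean(dt)
  expect_true(rate_obs > 57 && rate_obs < 63)
  # device x axis is flipped; the reader's axis map undoes it
  expect_identical(sess$phone$axis_map[["x"]], -1)
})

test_that("infeasible specs are rejected", {
  expect_error(session_spec(cycle_duration_mean = 200),
               class = "stepkin_spec_error")
  expect_error(default_cohort(1), class = "stepkin_spec_error")
})

test_that("cohorts match their population distributions", {
  cohort <- default_cohort(50, seed = 99)
  expect_length(cohort, 50)
  expect_identical(vapply(cohort, `[[`, "", "subject")[1:2], c("s01", "s02"))
  mean_om <- mean(vapply(cohort, function(s) mean(s$truth$omega_peak), 0))
  mean_dur <- mean(vapply(cohort, function(s)
    mean(s$truth$duration, na.rm = TRUE), 0))
  expect_lt(abs(mean_om - 303), 3 * 39 / sqrt(50))
  expect_lt(abs(mean_dur - 0.84), 3 * 0.11 / sqrt(50))
})

test_that("strategy-class frequencies follow the configured mixture", {
  cohort <- default_cohort(200, seed = 7)
  cls <- vapply(cohort, function(s)
    summarize_cycles(s$truth)$rpc_class, "")
  configured <- vapply(cohort, function(s) attr(s, "strategy_class"), "")
  n <- length(configured)
  for (cl in c("steady", "descending", "ascending")) {
    p <- c(steady = 0.4, descending = 0.4, ascending = 0.2)[[cl]]
    k <- sum(configured == cl)
    # 99% binomial bounds: wide enough that a fair draw rarely trips them
    expect_lt(abs(k - n * p), 2.58 * sqrt(n * p * (1 - p)) + 1e-9)
  }
  # and the realized ground-truth classification agrees with the configured
  # class for the vast majority of subjects
  expect_gt(mean(cls == configured), 0.85)
})

test_that("stronger phone noise widens analytical limits of agreement", {
  widths <- vapply(c(2, 8, 20), function(ns) {
    spec <- session_spec(noise_sd = ns, compression = 0.1)
    sess <- simulate_session(spec, seed = 61)
    tri <- preprocess_phone(sess$phone)
    aa <- run_analytical(tri, constant_cutoff_map(6),
                         test_duration = spec$duration)
    pr <- stepkin:::pair_cycles(sess$truth, aa)
    rep <- bland_altman(sess$truth$omega_peak[pr$a], aa$omega_peak[pr$b],
                        c("truth", "AA"))
    rep$loa_high - rep$loa_low
  }, 0)
  expect_true(all(diff(widths) > 0))
})
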