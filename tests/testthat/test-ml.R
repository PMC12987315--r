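# Build a small multi-subject feature table once for the ML tests.
ml_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sessions <- lapply(1:4, function(i)
      simulate_session(session_spec(duration = 60, compression = 0.12),
                       seed = 100 + i, subject = sprintf("m%02d", i)))
    rows <- do.call(rbind, lapply(sessions, function(s) {
      p <- prepare_session(s$phone, s$markers, subject = s$subject,
                           test_duration = 60)
      extract_features(p$phone, p$ref_cycles, subject = s$subject)
    }))
    cache <<- rows
    rows
  }
})

test_that("feature extraction computes the documented time-domain summaries", {
  rate <- 60
  n <- 1200
  tri <- triaxial_signal(make_uniform(rep(10, n)), make_uniform(rep(10, n)),
                         make_uniform(rep(10, n)))
  anchors <- cycle_set(c(5, 10), c(10, 10), test_duration = 20)
  rows <- extract_features(tri, anchors, prefiltered = TRUE, subject = "c")
  expect_equal(nrow(rows), 2)
  expect_equal(rows$x_mean, c(10, 10))
  expect_equal(rows$x_sd, c(0, 0))
  expect_equal(rows$x_rms, c(10, 10))
  expect_equal(rows$x_p10, c(10, 10))
  expect_equal(rows$x_p90, c(10, 10))
  expect_equal(rows$x_zc, c(0, 0))

  # one full sine period inside the 15-sample window: RMS = A / sqrt(2)
  A <- 100
  t <- (0:(n - 1)) / rate
  period <- 15 / rate
  v <- A * sin(2 * pi * (t - 5) / period)
  tri2 <- triaxial_signal(make_uniform(v), make_uniform(v), make_uniform(v))
  anchor_t <- 5 + 7 / rate  # center the 15-sample window on one period
  rows2 <- extract_features(tri2, cycle_set(anchor_t, A, test_duration = 20),
                            prefiltered = TRUE)
  expect_equal(rows2$x_rms, A / sqrt(2), tolerance = 0.02 * A / sqrt(2))
  expect_equal(rows2$x_energy, sum(v[round(5 * rate + 1):(5 * rate + 15)]^2) / rate,
               tolerance = 1e-6)
})

test_that("clipped anchor windows are dropped with a message", {
  tri <- triaxial_signal(make_uniform(rnorm(600)), make_uniform(rnorm(600)),
                         make_uniform(rnorm(600)))
  anchors <- cycle_set(c(0.05, 5), c(1, 1), test_duration = 10)
  expect_message(rows <- extract_features(tri, anchors, prefiltered = TRUE),
                 "dropped 1")
  expect_equal(nrow(rows), 1)
  far <- cycle_set(0.01, 1, test_duration = 10)
  expect_error(suppressMessages(extract_features(tri, far, prefiltered = TRUE)),
               class = "stepkin_data_error")
})

test_that("cycle-level split partitions rows and records test keys", {
  rows <- ml_fixture()
  sp <- split_cycles(rows, split_plan(seed = 5))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rows))
  expect_equal(nrow(sp$train), round(0.7 * nrow(rows)))
  expect_length(intersect(stepkin:::row_keys(sp$train),
                          stepkin:::row_keys(sp$test)), 0)
  expect_error(train_stacked(rows, sp$plan), class = "stepkin_leakage_error")
  expect_error(train_stacked(sp$train[sp$train$subject == "m01", ], split_plan()),
               class = "stepkin_grouping_error")
})

test_that("the stack learns an identity mapping to sub-deg/s accuracy", {
  rows <- ml_fixture()
  rows$target <- rows$x_parab
  train <- rows[rows$subject != "m04", ]
  test <- rows[rows$subject == "m04", ]
  model <- train_stacked(train, split_plan(seed = 3))
  pred <- predict_peaks(model, test, test_duration = 60)
  expect_lt(sqrt(mean((pred$omega_peak - test$target)^2)), 1)
})

test_that("predictions are deterministic and preserve anchors", {
  rows <- ml_fixture()
  train <- rows[rows$subject != "m04", ]
  test <- rows[rows$subject == "m04", ]
  model <- train_stacked(train, split_plan(seed = 3))
  p1 <- predict_peaks(model, test, test_duration = 60)
  p2 <- predict_peaks(model, test, test_duration = 60)
  expect_identical(p1$omega_peak, p2$omega_peak)
  expect_true(all(p1$omega_peak > 0))
  expect_equal(p1$peak_time, test$peak_time)
  expect_equal(p1$duration, test$duration)

  bad <- test[, setdiff(names(test), "x_parab")]
  expect_error(predict_peaks(model, bad), class = "stepkin_schema_error")
})

test_that("isotonic calibration is monotone, exact on clean relations, clipped", {
  p <- c(1, 2, 3, 4, 5)
  m_id <- calibrate_isotonic(p, p)
  expect_equal(predict(m_id, p), p)

  targ <- p
  m2 <- calibrate_isotonic(2 * targ, targ)
  expect_equal(predict(m2, 2 * targ), targ, tolerance = 0.01)
  # clipping below/above the training range
  expect_equal(predict(m2, 0), targ[1])
  expect_equal(predict(m2, 100), targ[5])

  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(40)
    y <- x + rnorm(40, 0, 0.5)
    m <- calibrate_isotonic(x, y)
    q <- sort(runif(50, min(x) - 1, max(x) + 1))
    v <- predict(m, q)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("tail correction recovers constructed tail relations", {
  set.seed(8)
  cal <- runif(2000, 100, 400)
  tc <- fit_tail_correction(cal, cal / 0.9 )
  expect_equal(tc$slope, 1 / 0.9, tolerance = 1e-9)
  expect_equal(tc$intercept, 0, tolerance = 1e-6)
  expect_equal(tc$threshold, quantile(cal, 0.95, names = FALSE))
  # applied only above the threshold
  v <- c(tc$threshold - 1, tc$threshold + 9)
  out <- stepkin:::apply_tail(tc, v)
  expect_equal(out[1], v[1])
  expect_equal(out[2], (tc$threshold + 9) / 0.9, tolerance = 1e-6)

  noisy <- cal + rnorm(2000, 0, 2)
  tcn <- fit_tail_correction(cal, noisy)
  expect_equal(tcn$slope, 1, tolerance = 0.2)

  expect_error(fit_tail_correction(cal[1:10], cal[1:10]),
               class = "stepkin_data_error")
  expect_message(tc0 <- fit_tail_correction(rep(c(1, 2), 50), rep(c(1, 2), 50)),
                 "disabled")
  expect_false(tc0$enabled)
})
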