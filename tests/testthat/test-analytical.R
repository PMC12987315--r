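test_that("dominant frequency picks the strongest non-DC bin", {
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)  # 600 samples: 0.1 Hz bins
  expect_equal(dominant_frequency(sin(2 * pi * 1.2 * t) + 3, rate = 60), 1.2)
  expect_equal(dominant_frequency(2 * sin(2 * pi * 1 * t) +
                                    1 * sin(2 * pi * 3 * t), rate = 60), 1.0)
  expect_error(dominant_frequency(rep(7, 600), rate = 60),
               "constant", class = "stepkin_data_error")
  expect_error(dominant_frequency(sin(1:30), rate = 60),
               "1 s", class = "stepkin_data_error")
})

test_that("cutoff map fitting: grid argmin, tie-break, diagnostics", {
  # phone == ref: RMS error decreases with cutoff, and the tie-break picks
  # the first cutoff within machine tolerance of the minimum
  rate <- 60
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  clean <- 200 * sin(2 * pi * 1.2 * t)
  ref <- make_uniform(clean, rate)
  ref <- stepkin:::set_provenance(ref, "reference")
  map <- fit_cutoff_map(make_uniform(clean, rate), ref)
  expect_s3_class(map, "cutoff_map")
  expect_equal(map$n_windows, 3)
  # exhaustive oracle for the first window
  spec <- windowing_spec()
  w <- clean[1:(10 * rate)]
  rms <- vapply(spec$grid, function(cc)
    sqrt(mean((stepkin:::lowpass_values(w, rate, cc) - w)^2)), 0)
  want <- spec$grid[which(rms <= min(rms) * (1 + 1e-9))[1]]
  expect_equal(map$table$c_opt[1], want)

  expect_error(fit_cutoff_map(make_uniform(clean[1:600], rate),
                              make_uniform(clean[1:600], rate)),
               ">= 2 windows", class = "stepkin_data_error")
})

test_that("faster stepping demands higher optimal cutoffs (positive slope)", {
  rate <- 60
  set.seed(21)
  tabs <- list()
  for (cad in c(0.8, 1.0, 1.2, 1.4)) {
    t <- seq(0, 30 - 1 / rate, by = 1 / rate)
    clean <- 250 * sin(2 * pi * cad * t)
    noisy <- clean + 20 * sin(2 * pi * 15 * t + runif(1, 0, 2 * pi))
    tabs[[length(tabs) + 1]] <-
      stepkin:::cutoff_table(noisy, clean, rate, windowing_spec())
  }
  map <- fit_cutoff_map_tables(do.call(rbind, tabs))
  expect_gt(map$a, 0)
  # per-window argmin table is itself monotone in cadence on average
  tab <- map$table
  expect_gt(cor(tab$f_d, tab$c_opt), 0.5)
})

test_that("a single shared dominant frequency degrades to a constant map", {
  tab <- data.frame(f_d = rep(1.2, 5), c_opt = c(4, 5, 6, 5, 4))
  expect_message(map <- fit_cutoff_map_tables(tab), "constant map")
  expect_true(map$constant)
  expect_equal(map$a, 0)
  expect_equal(map$b, 5)
})

test_that("applied cutoffs always stay inside the clamp range", {
  map <- fit_cutoff_map_tables(data.frame(f_d = c(0.5, 1, 2), c_opt = c(2, 5, 11)))
  for (fd in c(-10, 0, 0.3, 1.7, 5, 50, 1e6))
    expect_true(map_cutoff(map, fd) >= 1 && map_cutoff(map, fd) <= 12)
})

test_that("adaptive filtering under a constant map matches a global filter", {
  rate <- 60
  set.seed(31)
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  v <- 300 * sin(2 * pi * 1.1 * t) + rnorm(length(t), 0, 10)
  sig <- make_uniform(v, rate)
  adap <- adaptive_filter(sig, constant_cutoff_map(6))
  glob <- butterworth_lowpass(sig, filter_spec(order = 2, cutoff = 6))
  expect_equal(length(adap$values), length(v))
  rms_disc <- sqrt(mean((adap$values - glob$values)^2))
  expect_lt(rms_disc, 0.01 * sqrt(mean(v^2)))
})

test_that("DC passes any map unchanged and crossfade is exact when windows agree", {
  sig <- make_uniform(rep(12, 1200), 60)
  out <- adaptive_filter(sig, constant_cutoff_map(3))
  expect_equal(out$values, rep(12, 1200), tolerance = 1e-9)
})

test_that("adaptive filtering strips high-frequency noise from stepping signals", {
  rate <- 60
  set.seed(32)
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  clean <- 300 * sin(2 * pi * 1 * t)
  noise <- rnorm(length(t), 0, 25)
  noise_hf <- noise - stepkin:::lowpass_values(noise, rate, 10)
  out <- adaptive_filter(make_uniform(clean + noise_hf, rate),
                         constant_cutoff_map(5))
  expect_lt(sqrt(mean((out$values - clean)^2)),
            0.35 * sqrt(mean(noise_hf^2)))
})

test_that("cross-correlation synchronization recovers constructed lags", {
  rate <- 60
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  v <- 300 * sin(2 * pi * 1.05 * t) * (1 + 0.2 * sin(2 * pi * 0.05 * t))
  ref <- make_uniform(v, rate)
  sync0 <- synchronize(ref, ref)
  expect_equal(sync0$lag, 0)
  expect_equal(sync0$correlation, 1, tolerance = 1e-12)

  shift_n <- round(0.25 * rate)
  phone <- make_uniform(c(rep(0, shift_n), v[1:(length(v) - shift_n)]), rate)
  sync <- synchronize(phone, ref)
  expect_equal(sync$lag, 0.25, tolerance = 1 / rate + 1e-9)

  set.seed(41)
  noise <- make_uniform(rnorm(length(v), 0, 100), rate)
  expect_warning(syncn <- synchronize(noise, ref), "below 0.2")
  expect_true(syncn$low_confidence)
})

test_that("run_analytical honours provenance and handles edge inputs", {
  map <- fit_cutoff_map_tables(data.frame(f_d = c(1, 1.5), c_opt = c(4, 6)),
                               train_subjects = c("s01", "s02"))
  sess <- simulate_session(clean_spec(), seed = 13)
  tri <- preprocess_phone(sess$phone)
  expect_error(run_analytical(tri, map, subject = "s01"),
               class = "stepkin_leakage_error")

  cycles <- run_analytical(tri, map, subject = "s99",
                           test_duration = sess$spec$duration)
  expect_equal(nrow(cycles), nrow(sess$truth))

  short <- triaxial_signal(make_uniform(rep(0, 60)), make_uniform(rep(0, 60)),
                           make_uniform(rep(0, 60)))
  expect_equal(nrow(run_analytical(short, map)), 0)
})

test_that("amplitude compression makes the analytical estimate a mean underestimate", {
  spec <- clean_spec(compression = 0.15, noise_sd = 4)
  sess <- simulate_session(spec, seed = 17)
  tri <- preprocess_phone(sess$phone)
  cycles <- run_analytical(tri, constant_cutoff_map(6),
                           test_duration = spec$duration)
  expect_equal(nrow(cycles), nrow(sess$truth))
  expect_lt(mean(cycles$omega_peak), mean(sess$truth$omega_peak))
})
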