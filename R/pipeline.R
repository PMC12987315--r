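# High-level orchestration: prepare a paired session (preprocess, reference
# kinematics, synchronization), and run the full evaluation protocol — a
# 70/30 split, the analytical and ML pipelines, and Bland-Altman agreement
# against the reference — on a set of sessions.

#' Prepare one paired phone/reference session
#'
#' Preprocesses the raw phone stream (resampling, axis signs, drift
#' removal), derives the reference angular velocity and reference cycles
#' from the markers, estimates the inter-device lag by cross-correlation,
#' and puts the phone on the reference time base.
#'
#' @param phone A [raw_gyro_stream].
#' @param markers A [marker_trajectory].
#' @param subject Subject id.
#' @param detector A [peak_detector_spec].
#' @param max_lag Synchronization search half-range, seconds.
#' @param test_duration Nominal test duration, seconds.
#' @return A list of class `prepared_session`: `phone` (a
#'   [triaxial_signal] shifted onto the reference time base, full span),
#'   `ref_v`, `ref_cycles`, `sync`, `pair` (lag-aligned, cropped phone-x /
#'   reference signals for cutoff-map fitting), `subject`.
#' @export
prepare_session <- function(phone, markers, subject = "s1",
                            detector = peak_detector_spec(), max_lag = 2,
                            test_duration = 120) {
  tri <- preprocess_phone(phone)
  ref_v <- reference_velocity(markers)
  sync <- synchronize(tri$x, ref_v, max_lag = max_lag)
  pair <- align_pair(tri$x, ref_v, sync)
  shifted <- tri
  for (ax in c("x", "y", "z")) shifted[[ax]]$start_time <- tri[[ax]]$start_time - sync$lag
  ref_cycles <- detect_cycle_peaks(ref_v, detector, refine = TRUE,
                                   test_duration = test_duration)
  structure(list(phone = shifted, ref_v = ref_v, ref_cycles = ref_cycles,
                 sync = sync, pair = pair, subject = subject,
                 test_duration = test_duration),
            class = "prepared_session")
}

#' Pair two cycle sets by peak time
#'
#' One-to-one greedy pairing in time order: each cycle of `a` is matched to
#' the next unmatched cycle of `b` whose peak lies within `tol` seconds.
#' Both sets must be on the same time base (see [prepare_session()]).
#'
#' @param a,b [cycle_set] objects.
#' @param tol Matching tolerance in seconds, default 0.3.
#' @return List of index vectors `a` and `b` of equal length.
#' @export
pair_cycles <- function(a, b, tol = 0.3) {
  ia <- integer(); ib <- integer()
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$peak_time[j] < a$peak_time[i] - tol) j <- j + 1L
    if (j <= nrow(b) && abs(b$peak_time[j] - a$peak_time[i]) <= tol) {
      ia <- c(ia, i); ib <- c(ib, j)
      j <- j + 1L
    }
  }
  list(a = ia, b = ib)
}

#' Run the full two-pipeline evaluation on a set of sessions
#'
#' The replication protocol: subjects are partitioned 70/30 into training
#' and held-out test sets. The analytical pipeline's cutoff map is fitted
#' by pooling per-window (dominant frequency, optimal cutoff) tables over
#' the training subjects; the stacked ML model is trained on the training
#' subjects' per-cycle features under grouped (subject-disjoint) folds.
#' Both pipelines then estimate per-cycle peak velocities for the held-out
#' subjects, and agreement with the reference is summarized by
#' Bland-Altman reports oriented reference-minus-estimate (positive bias =
#' underestimation by the phone pipeline).
#'
#' @param sessions List of `synthetic_session` objects (or any objects with
#'   `$phone`, `$markers`, `$subject`, optionally `$truth`).
#' @param train_frac Fraction of subjects used for fitting, default 0.70.
#' @param seed Seed for the subject partition and all model fitting.
#' @param detector A [peak_detector_spec].
#' @param windowing A [windowing_spec] for the analytical pipeline.
#' @param features A [feature_window_spec] for the ML pipeline.
#' @param rpc An [rpc_config].
#' @return A list of class `study_result`: `counts` (per-session cycle
#'   counts by method), `aa_report` / `ml_report` (agreement vs reference on
#'   held-out cycles), `aa_truth_report` / `ml_truth_report` (agreement vs
#'   generator ground truth when available), `outcomes` (per-session
#'   reference outcome summaries), `map`, `model`, `train_subjects`,
#'   `test_subjects`.
#' @export
replicate_study <- function(sessions, train_frac = 0.70, seed = 1,
                            detector = peak_detector_spec(),
                            windowing = windowing_spec(),
                            features = feature_window_spec(),
                            rpc = rpc_config()) {
  stopifnot(length(sessions) >= 3)
  prepared <- lapply(sessions, function(s)
    prepare_session(s$phone, s$markers, subject = s$subject,
                    detector = detector,
                    test_duration = if (!is.null(s$spec)) s$spec$duration else 120))
  names(prepared) <- vapply(prepared, `[[`, "", "subject")
  subjects <- names(prepared)

  set.seed(seed)
  n_train <- max(2L, round(train_frac * length(subjects)))
  train_subjects <- sort(sample(subjects, n_train))
  test_subjects <- setdiff(subjects, train_subjects)

  # analytical pipeline: pooled cutoff map from training subjects
  tabs <- do.call(rbind, lapply(prepared[train_subjects], function(p)
    cutoff_table(p$pair$phone$values, p$pair$ref$values, p$pair$phone$rate,
                 windowing)))
  map <- fit_cutoff_map_tables(tabs, windowing, train_subjects = train_subjects)

  # ML pipeline: per-cycle features anchored at reference peaks
  rows <- lapply(prepared, function(p)
    extract_features(p$phone, p$ref_cycles, features, subject = p$subject))
  train_rows <- do.call(rbind, rows[train_subjects])
  plan <- split_plan(train_frac = train_frac, seed = seed)
  model <- train_stacked(train_rows, plan)

  # held-out evaluation
  ref_om <- aa_om <- ml_om <- tr_om_aa <- tr_ref_aa <- numeric()
  counts <- data.frame(subject = character(), truth = integer(),
                       reference = integer(), aa = integer(), ml = integer())
  for (sj in test_subjects) {
    p <- prepared[[sj]]
    aa <- run_analytical(p$phone, map, detector, windowing, subject = sj,
                         test_duration = p$test_duration)
    ml <- predict_peaks(model, rows[[sj]], test_duration = p$test_duration)
    truth_n <- NA_integer_
    sess <- sessions[[which(subjects == sj)]]
    if (!is.null(sess$truth)) truth_n <- nrow(sess$truth)
    counts <- rbind(counts, data.frame(
      subject = sj, truth = truth_n, reference = nrow(p$ref_cycles),
      aa = nrow(aa), ml = nrow(ml)))
    pr <- pair_cycles(p$ref_cycles, aa)
    ref_om <- c(ref_om, p$ref_cycles$omega_peak[pr$a])
    aa_om <- c(aa_om, aa$omega_peak[pr$b])
    ml_om <- c(ml_om, ml$omega_peak)
    if (!is.null(sess$truth)) {
      pt <- pair_cycles(sess$truth, aa)
      tr_om_aa <- c(tr_om_aa, sess$truth$omega_peak[pt$a])
      tr_ref_aa <- c(tr_ref_aa, aa$omega_peak[pt$b])
    }
  }
  # ML rows are anchored 1:1 at reference cycles, so the reference pairing
  # for ML is positional
  ml_ref_om <- unlist(lapply(test_subjects, function(sj)
    prepared[[sj]]$ref_cycles$omega_peak[
      rows[[sj]]$cycle]))

  aa_report <- bland_altman(ref_om, aa_om, labels = c("reference", "AA"))
  ml_report <- bland_altman(ml_ref_om, ml_om, labels = c("reference", "ML"))

  aa_truth_report <- ml_truth_report <- NULL
  if (length(tr_om_aa) >= 3)
    aa_truth_report <- bland_altman(tr_om_aa, tr_ref_aa,
                                    labels = c("truth", "AA"))
  truth_ml <- unlist(lapply(test_subjects, function(sj) {
    sess <- sessions[[which(subjects == sj)]]
    if (is.null(sess$truth)) return(NULL)
    pr <- pair_cycles(sess$truth, prepared[[sj]]$ref_cycles)
    sess$truth$omega_peak[pr$a][rows[[sj]]$cycle %in% pr$b]
  }))
  if (length(truth_ml) == length(ml_om) && length(ml_om) >= 3)
    ml_truth_report <- bland_altman(truth_ml, ml_om, labels = c("truth", "ML"))

  outcomes <- lapply(prepared, function(p) summarize_cycles(p$ref_cycles, rpc))

  structure(list(counts = counts, aa_report = aa_report, ml_report = ml_report,
                 aa_truth_report = aa_truth_report,
                 ml_truth_report = ml_truth_report,
                 aa_pairs = data.frame(reference = ref_om, aa = aa_om),
                 ml_pairs = data.frame(reference = ml_ref_om, ml = ml_om),
                 outcomes = outcomes, map = map, model = model,
                 train_subjects = train_subjects,
                 test_subjects = test_subjects,
                 n_test_cycles = length(ml_om), seed = seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d train / %d test subjects, %d held-out cycles\n",
              length(x$train_subjects), length(x$test_subjects), x$n_test_cycles))
  cat(sprintf("  AA: bias %.1f, LoA [%.1f, %.1f]\n", x$aa_report$bias,
              x$aa_report$loa_low, x$aa_report$loa_high))
  cat(sprintf("  ML: bias %.1f, LoA [%.1f, %.1f]\n", x$ml_report$bias,
              x$ml_report$loa_low, x$ml_report$loa_high))
  invisible(x)
}

#' Load sessions written by [write_session()] from a directory
#'
#' @param dir Directory containing `phone_<id>.csv`, `markers_<id>.csv` and
#'   optionally `truth_<id>.csv` triples.
#' @return List of session-like lists (`phone`, `markers`, `truth`,
#'   `subject`).
#' @export
load_session_dir <- function(dir) {
  phones <- sort(list.files(dir, "^phone_.*\\.csv$", full.names = TRUE))
  if (!length(phones))
    skn_stop(paste("no phone_<id>.csv files in", dir), "stepkin_io_error")
  lapply(phones, function(pf) {
    id <- sub("^phone_(.*)\\.csv$", "\\1", basename(pf))
    mf <- file.path(dir, sprintf("markers_%s.csv", id))
    if (!file.exists(mf))
      skn_stop(paste("missing marker file for subject", id), "stepkin_io_error")
    tf <- file.path(dir, sprintf("truth_%s.csv", id))
    sf <- file.path(dir, sprintf("spec_%s.json", id))
    axis_map <- c(x = 1, y = 1, z = 1)
    duration <- 120
    if (file.exists(sf)) {
      meta <- jsonlite::read_json(sf, simplifyVector = TRUE)
      if (!is.null(meta$device_x_sign)) axis_map[["x"]] <- meta$device_x_sign
      if (!is.null(meta$duration)) duration <- meta$duration
    }
    list(phone = read_gyro_csv(pf, axis_map = axis_map),
         markers = read_marker_csv(mf),
         truth = if (file.exists(tf))
           read_cycles_csv(tf, source = "truth", test_duration = duration)
         else NULL,
         subject = id,
         spec = list(duration = duration))
  })
}
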