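# Machine-learning approach: per-cycle time-domain features from all three
# phone axes in +/-0.12 s windows anchored at reference peaks, a stacked
# regression (elastic-net + histogram gradient-boosted trees, ridge
# meta-learner fitted on subject-wise out-of-fold predictions), isotonic
# calibration with out-of-range clipping, and a top-5% tail correction.

#' Feature-window specification
#'
#' @param half_width Window half-width in seconds, default 0.12 (at 60 Hz:
#'   7 samples each side, a 15-sample window fully inside +/-0.12 s).
#' @param prefilter [filter_spec] applied to every phone axis before
#'   windowing; default zero-lag 2nd-order 6 Hz.
#' @param percentiles Percentiles included as features, default
#'   `c(0.10, 0.25, 0.50, 0.75, 0.90)`.
#' @return An object of class `feature_window_spec`.
#' @export
feature_window_spec <- function(half_width = 0.12,
                                prefilter = filter_spec(order = 2, cutoff = 6),
                                percentiles = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  stopifnot(half_width > 0)
  structure(list(half_width = half_width, prefilter = prefilter,
                 percentiles = percentiles), class = "feature_window_spec")
}

axis_features <- function(w, rate, percentiles, prefix) {
  pk <- max(w)
  j <- which.max(w)
  parab <- if (j > 1 && j < length(w) && w[j] >= w[j - 1] && w[j] >= w[j + 1])
    parabolic_peak(w[j - 1], w[j], w[j + 1], 1 / rate)$value else pk
  out <- c(
    peak = pk,
    stats::quantile(w, percentiles, names = FALSE),
    mean = mean(w),
    sd = stats::sd(w),
    rms = sqrt(mean(w^2)),
    energy = sum(w^2) / rate,                   # sum of squares x sample interval
    hw = sum(w >= 0.5 * pk) / rate,             # time above 50% of window peak
    zc = sum(w[-1] * w[-length(w)] < 0),        # sign-change count
    parab = parab
  )
  names(out) <- paste(prefix,
                      c("peak", paste0("p", round(100 * percentiles)),
                        "mean", "sd", "rms", "energy", "hw", "zc", "parab"),
                      sep = "_")
  out
}

#' Extract per-cycle features from the phone signal
#'
#' For each anchor (a reference peak detected on the x axis, used as the
#' temporal anchor for all axes) a fixed window of `+/- half_width` seconds
#' is cut from every 6 Hz-prefiltered phone axis and summarized with
#' time-domain features: window peak, the configured percentiles, mean, SD,
#' RMS, signal energy, high-amplitude width (time above 50% of the window
#' peak), zero-crossing count and the parabolically interpolated peak; the
#' cycle duration is copied from the anchor set. Anchors whose full window
#' does not fit inside the signal are dropped with a message.
#'
#' @param phone A preprocessed [triaxial_signal] (on the reference time base;
#'   see [align_pair()]).
#' @param anchors A [cycle_set] of reference peaks.
#' @param spec A [feature_window_spec].
#' @param subject Subject id attached to every row (grouped CV key).
#' @param targets Attach `anchors$omega_peak` as the supervised target?
#'   Default TRUE (set FALSE at deployment).
#' @param prefiltered Set TRUE if `phone` is already prefiltered.
#' @return A data frame of class `feature_rows`: ids, `peak_time`,
#'   `duration`, per-axis features and optionally `target`.
#' @export
extract_features <- function(phone, anchors, spec = feature_window_spec(),
                             subject = "s1", targets = TRUE,
                             prefiltered = FALSE) {
  stopifnot(inherits(phone, "triaxial_signal"), inherits(anchors, "cycle_set"))
  if (!nrow(anchors))
    skn_stop("no anchors to extract features from", "stepkin_data_error")
  rate <- phone$x$rate
  half_n <- floor(spec$half_width * rate)
  chans <- lapply(phone[c("x", "y", "z")], function(ch) {
    if (prefiltered) ch$values else butterworth_lowpass(ch, spec$prefilter)$values
  })
  n <- length(chans$x)
  start <- phone$x$start_time
  rows <- vector("list", nrow(anchors))
  dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    ctr <- round((anchors$peak_time[i] - start) * rate) + 1L
    if (ctr - half_n < 1L || ctr + half_n > n) {
      dropped <- dropped + 1L
      next
    }
    idx <- (ctr - half_n):(ctr + half_n)
    feats <- c(axis_features(chans$x[idx], rate, spec$percentiles, "x"),
               axis_features(chans$y[idx], rate, spec$percentiles, "y"),
               axis_features(chans$z[idx], rate, spec$percentiles, "z"))
    rows[[i]] <- data.frame(subject = subject, cycle = anchors$index[i],
                            peak_time = anchors$peak_time[i],
                            duration = anchors$duration[i],
                            t(feats),
                            target = if (targets) anchors$omega_peak[i] else NA_real_)
  }
  if (dropped)
    message(sprintf("dropped %d anchor(s) with clipped windows", dropped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || !nrow(out))
    skn_stop("no anchor window fits inside the signal", "stepkin_data_error")
  if (!targets) out$target <- NULL
  class(out) <- c("feature_rows", "data.frame")
  out
}

feature_columns <- function(rows) {
  setdiff(names(rows), c("subject", "cycle", "peak_time", "duration", "target"))
}

#' Train/test split plan
#'
#' @param train_frac Training fraction of cycles, default 0.70.
#' @param seed Random seed for the cycle-level partition and all model
#'   fitting randomness.
#' @param k_folds Grouped-fold count cap; the effective K is
#'   `min(#training subjects, k_folds)` with subject-disjoint folds, i.e.
#'   pure leave-one-subject-out when subjects <= `k_folds`.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(train_frac = 0.70, seed = 1, k_folds = 10) {
  stopifnot(train_frac > 0, train_frac < 1)
  structure(list(train_frac = train_frac, seed = as.integer(seed),
                 k_folds = as.integer(k_folds), test_keys = character()),
            class = "split_plan")
}

row_keys <- function(rows) paste(rows$subject, rows$cycle, sep = "#")

#' Random cycle-level 70/30 partition
#'
#' Partitions feature rows into independent training and test subsets at
#' the cycle level. Test keys are recorded in the returned plan so that any
#' later fitting call on test rows can be detected as leakage.
#'
#' @param rows A `feature_rows` table.
#' @param plan A [split_plan].
#' @return List with `train`, `test` (both `feature_rows`) and the updated
#'   `plan` carrying `test_keys`.
#' @export
split_cycles <- function(rows, plan = split_plan()) {
  set.seed(plan$seed)
  n <- nrow(rows)
  tr <- sort(sample.int(n, round(plan$train_frac * n)))
  te <- setdiff(seq_len(n), tr)
  plan$test_keys <- row_keys(rows)[te]
  list(train = rows[tr, , drop = FALSE], test = rows[te, , drop = FALSE],
       plan = plan)
}

# Preprocessing chain fitted on training features: median imputation ->
# near-zero-variance filtering -> standardization.
fit_prep <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]
  v <- apply(X, 2, stats::var)
  keep <- which(v > 1e-10)
  ctr <- colMeans(X[, keep, drop = FALSE])
  scl <- sqrt(v[keep])
  list(medians = med, keep = keep, center = ctr, scale = scl)
}

apply_prep <- function(prep, X) {
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- prep$medians[j]
  scale(X[, prep$keep, drop = FALSE], center = prep$center, scale = prep$scale)
}

det_foldid <- function(n, k = 5) sample(rep_len(seq_len(k), n))

fit_elasticnet <- function(X, y) {
  prep <- fit_prep(X)
  cv <- glmnet::cv.glmnet(apply_prep(prep, X), y, alpha = 0.5,
                          foldid = det_foldid(length(y)), standardize = FALSE)
  list(prep = prep, fit = cv)
}

predict_elasticnet <- function(m, X) {
  as.numeric(stats::predict(m$fit, apply_prep(m$prep, X), s = "lambda.min"))
}

xgb_params <- function() {
  list(objective = "reg:squarederror", tree_method = "hist", max_depth = 4,
       eta = 0.05, subsample = 0.9, colsample_bytree = 0.9,
       min_child_weight = 5, nthread = 1)
}

fit_gbt <- function(X, y) {
  prep <- fit_prep(X)
  Xs <- apply_prep(prep, X)
  fit <- xgboost::xgb.train(params = xgb_params(),
                            data = xgboost::xgb.DMatrix(Xs, label = y),
                            nrounds = 300, verbose = 0)
  list(prep = prep, fit = fit)
}

predict_gbt <- function(m, X) {
  as.numeric(stats::predict(m$fit, xgboost::xgb.DMatrix(apply_prep(m$prep, X))))
}

subject_folds <- function(subjects, k) {
  us <- sample(unique(subjects))   # seeded by the caller
  k <- min(length(us), k)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(us)), us)
  unname(fold_of[as.character(subjects)])
}

#' Train the stacked regression model
#'
#' Subject-disjoint grouped folds (leave-one-subject-out logic; K capped by
#' `plan$k_folds`) generate out-of-fold predictions from both base learners
#' (an elastic-net linear model behind median imputation, variance filtering
#' and standardization; and histogram gradient-boosted regression trees).
#' A ridge meta-learner is fitted only on those out-of-fold predictions;
#' the base learners are then refitted on the full training partition.
#' Isotonic calibration and the top-5% tail correction are fitted on the
#' training partition's (out-of-fold) stacked predictions only.
#'
#' @param rows Training `feature_rows` with targets.
#' @param plan A [split_plan]; if it carries `test_keys` (from
#'   [split_cycles()]), passing any test row raises a leakage error.
#' @return An object of class `stacked_model`.
#' @export
train_stacked <- function(rows, plan = split_plan()) {
  stopifnot(inherits(rows, "data.frame"))
  if (!"target" %in% names(rows) || anyNA(rows$target))
    skn_stop("training rows must carry targets", "stepkin_contract_error")
  if (length(plan$test_keys) && any(row_keys(rows) %in% plan$test_keys))
    skn_stop("test-partition rows passed to train_stacked", "stepkin_leakage_error")
  if (length(unique(rows$subject)) < 2)
    skn_stop("grouped cross-validation needs >= 2 subjects", "stepkin_grouping_error")
  if (any(rows$target <= 0))
    skn_stop("targets must be positive peak velocities", "stepkin_contract_error")

  feats <- feature_columns(rows)
  X <- as.matrix(rows[, feats, drop = FALSE])
  y <- rows$target
  set.seed(plan$seed)
  folds <- subject_folds(rows$subject, plan$k_folds)

  oof <- matrix(NA_real_, nrow(rows), 2, dimnames = list(NULL, c("en", "gb")))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    oof[!tr, "en"] <- predict_elasticnet(
      fit_elasticnet(X[tr, , drop = FALSE], y[tr]), X[!tr, , drop = FALSE])
    oof[!tr, "gb"] <- predict_gbt(
      fit_gbt(X[tr, , drop = FALSE], y[tr]), X[!tr, , drop = FALSE])
  }

  meta <- glmnet::cv.glmnet(oof, y, alpha = 0,
                            foldid = det_foldid(length(y)), standardize = FALSE)
  en_full <- fit_elasticnet(X, y)
  gb_full <- fit_gbt(X, y)

  stacked_oof <- as.numeric(stats::predict(meta, oof, s = "lambda.min"))
  iso <- calibrate_isotonic(stacked_oof, y)
  calibrated <- predict(iso, stacked_oof)
  tail_fit <- fit_tail_correction(calibrated, y)

  structure(list(
    en = en_full, gb = gb_full, meta = meta, iso = iso, tail = tail_fit,
    feature_names = feats,
    provenance = list(subjects = sort(unique(rows$subject)),
                      k_folds = length(unique(folds)), seed = plan$seed,
                      n_rows = nrow(rows),
                      test_keys = plan$test_keys)
  ), class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d features; %d subjects, %d grouped folds (seed %d)\n",
              length(x$feature_names), length(x$provenance$subjects),
              x$provenance$k_folds, x$provenance$seed))
  cat(sprintf("  tail correction: %s (threshold %.1f deg/s)\n",
              if (x$tail$enabled) sprintf("slope %.3f, intercept %.2f",
                                          x$tail$slope, x$tail$intercept)
              else "disabled", x$tail$threshold))
  invisible(x)
}

#' Isotonic calibration map
#'
#' Fits a monotone non-decreasing map from predictions to targets by
#' isotonic regression (pool-adjacent-violators); queries outside the
#' training prediction range are clipped to the range endpoints before
#' linear interpolation between knots.
#'
#' @param predictions,targets Paired numeric vectors (>= 2 pairs).
#' @return An object of class `isotonic_map` with a `predict()` method.
#' @export
calibrate_isotonic <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets), length(predictions) >= 2)
  ir <- stats::isoreg(predictions, targets)
  xk <- if (is.null(ir$ord)) ir$x else ir$x[ir$ord]
  yk <- ir$yf
  # collapse tied knots to a single (x, mean fitted) pair
  ux <- unique(xk)
  uy <- vapply(ux, function(v) mean(yk[xk == v]), 0)
  structure(list(x = ux, y = uy), class = "isotonic_map")
}

#' @export
predict.isotonic_map <- function(object, newdata, ...) {
  q <- pmin(pmax(newdata, object$x[1]), object$x[length(object$x)])
  if (length(object$x) == 1) return(rep(object$y, length(q)))
  stats::approx(object$x, object$y, xout = q, rule = 2, ties = "ordered")$y
}

#' Upper-tail linear correction
#'
#' Least-squares regression of the target on the calibrated prediction over
#' the top-(1 - quantile) tail of the calibrated training predictions.
#' Applied only above the threshold at prediction time. With fewer than 2
#' tail pairs the correction is disabled (identity) with a message.
#'
#' @param calibrated Calibrated training predictions (>= 20 pairs).
#' @param targets Training targets.
#' @param quantile Tail threshold quantile, default 0.95 (top 5%).
#' @return List with `threshold`, `slope`, `intercept`, `enabled`.
#' @export
fit_tail_correction <- function(calibrated, targets, quantile = 0.95) {
  stopifnot(length(calibrated) == length(targets))
  if (length(calibrated) < 20)
    skn_stop("tail correction needs >= 20 pairs", "stepkin_data_error")
  thr <- stats::quantile(calibrated, quantile, names = FALSE)
  sel <- calibrated > thr
  if (sum(sel) < 2 || stats::var(calibrated[sel]) < 1e-12) {
    message("tail correction disabled (degenerate upper tail)")
    return(list(threshold = thr, slope = 1, intercept = 0, enabled = FALSE))
  }
  fit <- stats::lm(targets[sel] ~ calibrated[sel])
  list(threshold = thr, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), enabled = TRUE)
}

apply_tail <- function(tail_fit, v) {
  if (!tail_fit$enabled) return(v)
  hi <- v > tail_fit$threshold
  v[hi] <- tail_fit$intercept + tail_fit$slope * v[hi]
  v
}

#' Predict per-cycle peaks with a trained stacked model
#'
#' Base predictions are combined by the ridge meta-learner, passed through
#' the isotonic map (with out-of-range clipping) and the tail correction.
#' Anchor times and durations pass through unchanged: the ML path
#' re-estimates only the peak magnitude, so cycle count and durations are
#' identical to the anchor set.
#'
#' @param model A `stacked_model`.
#' @param rows `feature_rows` (targets not required).
#' @param test_duration Nominal test duration recorded in the result.
#' @return A [cycle_set] tagged `"phone-ML"`.
#' @export
predict_peaks <- function(model, rows, test_duration = 120) {
  stopifnot(inherits(model, "stacked_model"))
  if (!all(model$feature_names %in% names(rows)))
    skn_stop("feature schema mismatch between model and rows",
             "stepkin_schema_error")
  X <- as.matrix(rows[, model$feature_names, drop = FALSE])
  base <- cbind(en = predict_elasticnet(model$en, X),
                gb = predict_gbt(model$gb, X))
  stacked <- as.numeric(stats::predict(model$meta, base, s = "lambda.min"))
  pred <- apply_tail(model$tail, predict(model$iso, stacked))
  cycle_set(rows$peak_time, pred, source = "phone-ML",
            test_duration = test_duration, duration = rows$duration)
}
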