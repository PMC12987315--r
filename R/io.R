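# Readers and writers for the external file dialects: sensor-log gyroscope
# CSVs, marker-trajectory CSVs, cycle tables and outcome/agreement reports.
# All readers convert to canonical units (seconds, deg/s, meters) at the
# boundary and are lossless: duplicate timestamps are retained for the
# resampler to resolve, gap frames are flagged rather than dropped.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr(";", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
}

#' Read a smartphone gyroscope log
#'
#' Reads a sensor-log style CSV (header row, comma or semicolon delimited,
#' decimal point `.`) into a [raw_gyro_stream]. Timestamps are rebased to
#' start at zero and values converted to deg/s. Duplicate timestamps are
#' retained; [resample_uniform()] resolves them by averaging.
#'
#' @param path File path.
#' @param dialect Named list mapping roles to column names:
#'   `list(time = , x = , y = , z = )`.
#' @param unit Source angular unit, `"deg"` (default) or `"rad"`.
#' @param axis_map Per-axis signs applied later by [apply_sign_convention()].
#' @return A [raw_gyro_stream].
#' @export
read_gyro_csv <- function(path,
                          dialect = list(time = "time", x = "x", y = "y", z = "z"),
                          unit = c("deg", "rad"),
                          axis_map = c(x = 1, y = 1, z = 1)) {
  unit <- match.arg(unit)
  if (!file.exists(path)) skn_stop(paste("no such file:", path), "stepkin_io_error")
  df <- data.table::fread(path, sep = detect_sep(path), dec = ".",
                          header = TRUE, data.table = FALSE)
  need <- unlist(dialect[c("time", "x", "y", "z")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    skn_stop(paste("missing column(s):", paste(missing_cols, collapse = ", ")),
             "stepkin_format_error")
  tm <- as.numeric(df[[dialect$time]])
  raw_gyro_stream(
    time = tm - tm[1],
    x = convert_angular(as.numeric(df[[dialect$x]]), unit, "deg"),
    y = convert_angular(as.numeric(df[[dialect$y]]), unit, "deg"),
    z = convert_angular(as.numeric(df[[dialect$z]]), unit, "deg"),
    axis_map = axis_map
  )
}

#' Write a gyroscope stream to CSV
#'
#' Full-precision (`%.17g`) writer so that a read round-trip is bit-exact.
#'
#' @param stream A [raw_gyro_stream].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(stream, path) {
  stopifnot(inherits(stream, "raw_gyro_stream"))
  lines <- c("time,x,y,z",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     stream$time, stream$x, stream$y, stream$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker-trajectory CSV
#'
#' Columns `frame,hip_a,hip_b,knee_a,knee_b` where `a`/`b` are the two
#' sagittal-plane coordinates (anterior-horizontal, vertical) in meters.
#' Blank cells mark occlusion gaps; gap frames are flagged in the returned
#' `gap_mask`, never dropped. Runs of more than `long_gap` consecutive gap
#' frames trigger a warning (long gaps are where gap filling becomes
#' unreliable).
#'
#' @param path File path.
#' @param frame_rate Frames per second of the capture, default 60.
#' @param plane Label recording which lab plane the coordinates span
#'   (documentation only; the file is already planar).
#' @param long_gap Consecutive-gap warning threshold, default 10 frames.
#' @return A [marker_trajectory].
#' @export
read_marker_csv <- function(path, frame_rate = 60, plane = "vertical-anterior",
                            long_gap = 10) {
  if (!file.exists(path)) skn_stop(paste("no such file:", path), "stepkin_io_error")
  df <- data.table::fread(path, sep = detect_sep(path), dec = ".",
                          header = TRUE, data.table = FALSE)
  need <- c("hip_a", "hip_b", "knee_a", "knee_b")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    skn_stop(paste("missing column(s):", paste(missing_cols, collapse = ", ")),
             "stepkin_format_error")
  hip <- cbind(as.numeric(df$hip_a), as.numeric(df$hip_b))
  knee <- cbind(as.numeric(df$knee_a), as.numeric(df$knee_b))
  gap_mask <- stats::complete.cases(hip) & stats::complete.cases(knee)
  runs <- rle(!gap_mask)
  worst <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (worst > long_gap)
    warning(sprintf("marker gap of %d consecutive frames (> %d)", worst, long_gap),
            call. = FALSE)
  traj <- marker_trajectory(hip, knee, frame_rate = frame_rate,
                            gap_mask = gap_mask)
  attr(traj, "plane") <- plane
  traj
}

#' Write a marker trajectory to CSV
#'
#' Gap frames are written as blank cells. Full precision, so reading the
#' file back reproduces the valid coordinates exactly.
#'
#' @param traj A [marker_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("frame,hip_a,hip_b,knee_a,knee_b",
             paste(seq_len(nrow(traj$hip)),
                   fmt(traj$hip[, 1]), fmt(traj$hip[, 2]),
                   fmt(traj$knee[, 1]), fmt(traj$knee[, 2]), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write an outcome or agreement report
#'
#' Serializes an [outcome_summary] (from [summarize_cycles()]) or an
#' `agreement_report` (from [bland_altman()]) either as a delimited
#' metric/value table (`format = "csv"`) or as structured JSON
#' (`format = "json"`). Numeric fields are stored at full precision so a
#' round-trip read is field-identical, and identical objects always produce
#' byte-identical files.
#'
#' @param summary An `outcome_summary` or `agreement_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(summary, "agreement_report") && summary$n < 1)
    skn_stop("refusing to write an agreement report with no pairs",
             "stepkin_contract_error")
  fields <- unclass(summary)
  fields <- fields[!vapply(fields, is.function, TRUE)]
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null", na = "null")
  } else {
    lines <- unlist(lapply(names(fields), function(nm) {
      v <- fields[[nm]]
      nms <- if (length(v) > 1) paste0(nm, seq_along(v)) else nm
      txt <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      paste(nms, txt, sep = ",")
    }))
    writeLines(c("metric,value", lines), path)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension if missing.
#' @return A named list of fields (numeric where parseable).
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") return(jsonlite::read_json(path, simplifyVector = TRUE))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- lapply(df$value, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  stats::setNames(vals, df$metric)
}

#' Write a cycle table to CSV
#'
#' @param cycles A [cycle_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  stopifnot(inherits(cycles, "cycle_set"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("index,peak_time,omega_peak,duration",
             paste(seq_len(nrow(cycles)), fmt(cycles$peak_time),
                   fmt(cycles$omega_peak), fmt(cycles$duration), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cycle table written by [write_cycles_csv()]
#'
#' @param path File path.
#' @param source Provenance label for the resulting set.
#' @param test_duration Nominal test duration in seconds.
#' @return A [cycle_set].
#' @export
read_cycles_csv <- function(path, source = "file", test_duration = 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cycle_set(peak_time = df$peak_time, omega_peak = df$omega_peak,
            source = source, test_duration = test_duration)
}
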