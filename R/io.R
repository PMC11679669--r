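#' Read a force-plate text export
#'
#' Parses the tab- or whitespace-delimited text files exported by plate
#' acquisition software: a header row naming the channels, one row per
#' sample. At least `Fz`, `Mx`, `My` must be present; `Fx`, `Fy`, `Mz`
#' default to zero when absent. A leading time column (`t`, `time`,
#' `abs time (s)`, ...) is ignored for the channel data but, when present,
#' is used to infer the sampling rate unless one is given explicitly.
#'
#' Protocol metadata (test type, eyes condition, support foot) is never in
#' the export itself and is supplied through the arguments; it is never
#' guessed from the file name.
#'
#' @param path Path to the export file.
#' @param test_type,eyes,support_foot,ybt_direction,participant Trial
#'   metadata; see [plate_trial()].
#' @param sampling_rate Sampling rate in Hz. `NULL` (default) infers it from
#'   a time column when one exists, else falls back to `default_rate`.
#' @param default_rate Fallback sampling rate (Hz) when the file carries no
#'   time column; default 1000, typical for laboratory plates.
#' @param dialect Optional named character vector renaming file columns to
#'   the canonical `Fx`,...,`Mz` (e.g. `c(ForceZ = "Fz")` maps a `ForceZ`
#'   column to `Fz`).
#'
#' @return A [plate_trial()].
#' @seealso [write_plate_export()]
#' @export
read_plate_export <- function(path, test_type, eyes = "n/a",
                              support_foot = "right", ybt_direction = "n/a",
                              participant = "unknown",
                              sampling_rate = NULL, default_rate = 1000,
                              dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- tryCatch(
    read.table(path, header = TRUE, sep = "", check.names = FALSE,
               colClasses = "numeric"),
    error = function(e) {
      # rescan to locate the offending line for the error message
      raw <- readLines(path)
      for (i in seq_along(raw)[-1]) {
        cells <- strsplit(trimws(raw[i]), "[\t ]+")[[1]]
        if (length(cells) && anyNA(suppressWarnings(as.numeric(cells)))) {
          stop(sprintf("non-numeric value on line %d of %s", i, path),
               call. = FALSE)
        }
      }
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (!is.null(dialect)) {
    idx <- match(names(dialect), names(dat))
    names(dat)[idx[!is.na(idx)]] <- unname(dialect[!is.na(idx)])
  }
  time_col <- intersect(c("t", "time", "Time", "abs time (s)"), names(dat))[1]
  if (is.null(sampling_rate)) {
    if (!is.na(time_col) && nrow(dat) > 1) {
      dt <- mean(diff(dat[[time_col]]))
      if (is.finite(dt) && dt > 0) sampling_rate <- 1 / dt
    }
    if (is.null(sampling_rate)) sampling_rate <- default_rate
  }
  if (is.null(dat[["Fz"]])) stop("required channel Fz absent", call. = FALSE)
  chan_names <- intersect(c("Fx", "Fy", "Fz", "Mx", "My", "Mz"), names(dat))
  plate_trial(participant = participant, test_type = test_type,
              channels = dat[chan_names], sampling_rate = sampling_rate,
              eyes = eyes, support_foot = support_foot,
              ybt_direction = ybt_direction)
}

#' Write a plate trial as a tab-delimited text export
#'
#' Inverse of [read_plate_export()]: writes a time column and the six
#' channels with full stored precision, so a write/read round trip
#' reproduces the channel values exactly.
#'
#' @param trial A [plate_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_export <- function(trial, path) {
  stopifnot(inherits(trial, "plate_trial"))
  n <- nrow(trial$channels)
  out <- cbind(t = (seq_len(n) - 1) / trial$sampling_rate, trial$channels)
  # format() would truncate doubles; write full precision explicitly
  fmt <- vapply(out, function(col) sprintf("%.17g", col), character(n))
  dim(fmt) <- c(n, ncol(out))
  lines <- c(paste(names(out), collapse = "\t"),
             apply(fmt, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker trajectory CSV
#'
#' Reads a two-column (x, y) pixel trajectory as digitized by video motion
#' software and converts it to cm with the supplied calibration factor
#' (derived from the 1 m reference marks in the camera field).
#'
#' @param path CSV with numeric columns `x` and `y` (header required).
#' @param marker Landmark name; see [marker_track()].
#' @param calibration_cm_per_px Positive cm-per-pixel scale factor. Use 1 if
#'   the file already stores centimetres.
#' @return A [marker_track()] in cm.
#' @seealso [write_marker_track()]
#' @export
read_marker_track <- function(path, marker, calibration_cm_per_px = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- read.csv(path)
  if (is.null(dat$x) || is.null(dat$y)) {
    stop("marker CSV must have columns 'x' and 'y'", call. = FALSE)
  }
  marker_track(marker, dat$x, dat$y,
               calibration_cm_per_px = calibration_cm_per_px)
}

#' Write a marker track as CSV (cm)
#'
#' Positions are written in cm (calibration already applied), so reading the
#' file back with calibration 1 reproduces the track.
#'
#' @param track A [marker_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_track <- function(track, path) {
  stopifnot(inherits(track, "marker_track"))
  write.csv(data.frame(x = track$x, y = track$y), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' CSV with one row per participant and columns `nickname`, `sex`, `age`,
#' `foot_size`, `leg_length` (required) plus optional `dominant_foot`,
#' `height`, `weight`. Rows are validated as [participant_profile()]s; ages
#' outside the 6-9 year inclusion window warn but do not fail.
#'
#' @param path CSV path.
#' @return A `data.frame` of validated profiles, one row per participant.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("nickname", "sex", "age", "foot_size", "leg_length")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    stop(sprintf("cohort table missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(dat$nickname)) {
    dup <- unique(dat$nickname[duplicated(dat$nickname)])
    stop(sprintf("duplicate nickname(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(dat)), function(i) {
    participant_profile(
      nickname = as.character(dat$nickname[i]), sex = dat$sex[i],
      age = dat$age[i], foot_size = dat$foot_size[i],
      leg_length = dat$leg_length[i],
      dominant_foot = if (is.null(dat$dominant_foot)) "right" else dat$dominant_foot[i],
      height = if (is.null(dat$height)) NA_real_ else dat$height[i],
      weight = if (is.null(dat$weight)) NA_real_ else dat$weight[i])
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("imep_cohort", "data.frame")
  out
}

#' Write a cohort table
#' @param cohort Profile `data.frame` as returned by [read_cohort_table()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

SCALE_FIELDS <- c("test_type", "cte", "fc_intercept", "fc_male", "fc_age",
                  "fc_footsize", "smoothing", "adjusted_min", "adjusted_max",
                  "log_base")

#' Read a scale definition from JSON
#'
#' The document must contain exactly the [scale_definition()] fields;
#' unknown keys are rejected so that typos in hand-edited scales fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path JSON path.
#' @return A [scale_definition()].
#' @seealso [write_scale()], [imep_scale()]
#' @export
read_scale <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), SCALE_FIELDS)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in scale definition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(SCALE_FIELDS, names(doc))
  if (length(missing)) {
    stop(sprintf("scale definition missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  do.call(scale_definition, doc[SCALE_FIELDS])
}

#' Write a scale definition to JSON
#' @param scale A [scale_definition()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  jsonlite::write_json(unclass(scale)[SCALE_FIELDS], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write score reports
#'
#' Serializes one or more [score_participant()] reports mirroring the web
#' form's contract: identification and per-test movement input in, the 1-10
#' score plus every intermediate quantity out.
#'
#' @param reports A single report or a list of reports.
#' @param path Output path; `.json` or `.csv` by `format`.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_score_reports <- function(reports, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(reports, "score_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) as.data.frame(unclass(r)))
  tab <- do.call(rbind, rows)
  if (format == "json") {
    jsonlite::write_json(lapply(reports, unclass), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
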