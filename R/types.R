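#' Construct a participant profile
#'
#' A profile carries the demographics that drive the correction factor
#' (sex, age, foot size) and the leg length used to normalize YBT reaches.
#'
#' @param nickname Non-empty identifier (the web form uses pseudonyms).
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (decimal); must be positive. Ages outside the
#'   6-9 year inclusion window are accepted with a warning.
#' @param foot_size EU shoe size (decimal); must be positive.
#' @param leg_length Trochanter-to-talus distance in cm; must be positive.
#' @param dominant_foot `"right"` or `"left"`.
#' @param height Standing height in m (optional).
#' @param weight Body mass in kg (optional).
#'
#' @return A one-row `data.frame` of class `participant_profile`.
#' @examples
#' participant_profile("ana", "female", age = 7.2, foot_size = 32, leg_length = 66)
#' @export
participant_profile <- function(nickname, sex, age, foot_size, leg_length,
                                dominant_foot = "right",
                                height = NA_real_, weight = NA_real_) {
  sex <- match.arg(sex, c("female", "male"))
  dominant_foot <- match.arg(dominant_foot, c("right", "left"))
  if (!is.character(nickname) || length(nickname) != 1L || !nzchar(nickname)) {
    stop("nickname must be a non-empty string", call. = FALSE)
  }
  for (nm in c("age", "foot_size", "leg_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
    }
  }
  if (age < 6 || age > 9) {
    warning(sprintf("participant '%s' has age %.2f outside the 6-9 year inclusion window",
                    nickname, age), call. = FALSE)
  }
  out <- data.frame(nickname = nickname, sex = sex, age = age,
                    foot_size = foot_size, leg_length = leg_length,
                    dominant_foot = dominant_foot,
                    height = height, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("participant_profile", class(out))
  out
}

#' Construct a force-plate trial
#'
#' One balance attempt's six-channel force/moment time series plus the
#' protocol metadata needed downstream (test type, eyes condition, support
#' foot, YBT direction, sampling rate).
#'
#' @param participant Nickname of the participant.
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @param channels A `data.frame` (or list) with equal-length numeric columns
#'   `Fx`, `Fy`, `Fz` (N) and `Mx`, `My`, `Mz` (N m). Missing `Fx`, `Fy`, `Mz`
#'   default to zero; `Fz`, `Mx`, `My` are required.
#' @param sampling_rate Samples per second (Hz), positive.
#' @param eyes `"open"`, `"closed"` or `"n/a"` (YBT).
#' @param support_foot `"right"`, `"left"` or `"both"` (TBT).
#' @param ybt_direction `"anterior"`, `"posteromedial"`, `"posterolateral"`
#'   or `"n/a"` for static tests.
#' @param nominal_duration Nominal trial length in s; defaults to the protocol
#'   value for the test type (16 s static, 5 s YBT).
#'
#' @return An object of class `plate_trial`.
#' @export
plate_trial <- function(participant, test_type, channels, sampling_rate,
                        eyes = "n/a", support_foot = "right",
                        ybt_direction = "n/a",
                        nominal_duration = NULL) {
  test_type <- match.arg(test_type, TEST_TYPES)
  eyes <- match.arg(eyes, EYES_LEVELS)
  support_foot <- match.arg(support_foot, FOOT_LEVELS)
  ybt_direction <- match.arg(ybt_direction, c(YBT_DIRECTIONS, "n/a"))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (Hz)", call. = FALSE)
  }
  channels <- as.data.frame(channels)
  for (req in c("Fz", "Mx", "My")) {
    if (is.null(channels[[req]])) {
      stop(sprintf("required channel %s absent", req), call. = FALSE)
    }
  }
  n <- length(channels$Fz)
  for (opt in c("Fx", "Fy", "Mz")) {
    if (is.null(channels[[opt]])) channels[[opt]] <- numeric(n)
  }
  channels <- channels[, c("Fx", "Fy", "Fz", "Mx", "My", "Mz")]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all six channels must have the same length", call. = FALSE)
  }
  if (!all(vapply(channels, is.numeric, logical(1)))) {
    stop("all channels must be numeric", call. = FALSE)
  }
  if (is.null(nominal_duration)) {
    nominal_duration <- if (test_type == "YBT") 5 else 16
  }
  structure(
    list(participant = participant, test_type = test_type, eyes = eyes,
         support_foot = support_foot, ybt_direction = ybt_direction,
         sampling_rate = sampling_rate, channels = channels,
         nominal_duration = nominal_duration),
    class = "plate_trial")
}

#' @export
print.plate_trial <- function(x, ...) {
  cat(sprintf("<plate_trial> %s %s (eyes %s, foot %s%s): %d samples @ %g Hz\n",
              x$participant, x$test_type, x$eyes, x$support_foot,
              if (x$ybt_direction != "n/a") paste0(", ", x$ybt_direction) else "",
              nrow(x$channels), x$sampling_rate))
  invisible(x)
}

#' Construct a marker track
#'
#' A digitized X/Y trajectory of one bony-landmark marker, in calibrated cm.
#' Calibration (cm per pixel, from the 1 m reference marks in the camera
#' field) is applied at construction/read time.
#'
#' @param marker One of `"acromion"`, `"umbilicus"`, `"trochanter"`, `"L3"`.
#' @param x,y Equal-length numeric position series. Interpreted as pixels and
#'   multiplied by `calibration_cm_per_px`; pass positions already in cm with
#'   the default calibration of 1.
#' @param calibration_cm_per_px Positive scale factor (cm per pixel).
#'
#' @return An object of class `marker_track` with `x`, `y` in cm.
#' @export
marker_track <- function(marker, x, y, calibration_cm_per_px = 1) {
  marker <- match.arg(marker, ALL_MARKERS)
  if (!is.numeric(calibration_cm_per_px) || length(calibration_cm_per_px) != 1L ||
      is.na(calibration_cm_per_px) || calibration_cm_per_px <= 0) {
    stop("calibration_cm_per_px must be a positive number", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  structure(
    list(marker = marker,
         x = as.numeric(x) * calibration_cm_per_px,
         y = as.numeric(y) * calibration_cm_per_px,
         calibration_cm_per_px = calibration_cm_per_px),
    class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track> %s: %d samples (cm)\n", x$marker, length(x$x)))
  invisible(x)
}

#' Construct a scale definition
#'
#' The complete constant set that deterministically maps raw measurements to
#' the 1-10 IMEP score: the inversion constant `cte`, the demographic
#' correction-factor regression coefficients, the smoothing factor applied to
#' the correction factor, and the adjusted-score range used for min-max
#' rescaling.
#'
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @param cte Inversion constant: movement units (cm) for SLB/TBT, log-scale
#'   offset for YBT.
#' @param fc_intercept,fc_male,fc_age,fc_footsize Coefficients of the linear
#'   correction-factor model
#'   `FC = fc_intercept + fc_male*[sex == male] + fc_age*age + fc_footsize*foot_size`.
#' @param adjusted_min,adjusted_max Bounds of the adjusted-score range used in
#'   rescaling; `adjusted_max` must exceed `adjusted_min`.
#' @param smoothing Factor in (0, 1] multiplying the correction factor before
#'   subtraction (default 0.5).
#' @param log_base `"natural"` or `"base10"`; log used by the YBT raw score.
#'
#' @return An object of class `scale_definition`.
#' @seealso [imep_scale()] for the published scales, [build_scale()] to derive
#'   one from a cohort.
#' @export
scale_definition <- function(test_type, cte, fc_intercept, fc_male, fc_age,
                             fc_footsize, adjusted_min, adjusted_max,
                             smoothing = 0.5, log_base = "natural") {
  test_type <- match.arg(test_type, TEST_TYPES)
  log_base <- match.arg(log_base, c("natural", "base10"))
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("%s must be a single number", nm), call. = FALSE)
    }
    as.numeric(v)
  }
  cte <- num1(cte, "cte")
  fc_intercept <- num1(fc_intercept, "fc_intercept")
  fc_male <- num1(fc_male, "fc_male")
  fc_age <- num1(fc_age, "fc_age")
  fc_footsize <- num1(fc_footsize, "fc_footsize")
  adjusted_min <- num1(adjusted_min, "adjusted_min")
  adjusted_max <- num1(adjusted_max, "adjusted_max")
  smoothing <- num1(smoothing, "smoothing")
  if (adjusted_max <= adjusted_min) {
    stop("adjusted_max must be strictly greater than adjusted_min", call. = FALSE)
  }
  if (smoothing <= 0 || smoothing > 1) {
    stop("smoothing must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(test_type = test_type, cte = cte,
         fc_intercept = fc_intercept, fc_male = fc_male,
         fc_age = fc_age, fc_footsize = fc_footsize,
         smoothing = smoothing,
         adjusted_min = adjusted_min, adjusted_max = adjusted_max,
         log_base = log_base),
    class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: cte = %g, adjusted range [%g, %g]\n",
              x$test_type, x$cte, x$adjusted_min, x$adjusted_max))
  cat(sprintf("  FC = %g %+g*[male] %+g*age %+g*foot_size (smoothing %g, log %s)\n",
              x$fc_intercept, x$fc_male, x$fc_age, x$fc_footsize,
              x$smoothing, x$log_base))
  invisible(x)
}

#' Published IMEP scales
#'
#' Returns the scale definition published with the instrument for a given
#' test: inversion constants cte = 350 (SLB), 300 (TBT), 80 (YBT); the fitted
#' demographic correction coefficients; and the cohort adjusted-score ranges
#' SLB (-72, 230), TBT (-54, 206), YBT (-175, 526).
#'
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @return A [scale_definition()].
#' @examples
#' imep_scale("SLB")
#' @export
imep_scale <- function(test_type = TEST_TYPES) {
  test_type <- match.arg(test_type)
  path <- system.file("extdata", "scales",
                      paste0(tolower(test_type), ".json"),
                      package = "imep", mustWork = TRUE)
  read_scale(path)
}
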