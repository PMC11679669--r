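#' YBT composite score
#'
#' The standard leg-length-normalized composite of the three reach
#' directions: `(anterior + posteromedial + posterolateral) / (3 * leg_length) * 10`.
#' A child whose every reach equals their leg length scores exactly 10.
#'
#' @param anterior,posteromedial,posterolateral Reach distances in cm (>= 0).
#' @param leg_length Leg length in cm (> 0).
#' @param divisor Number of directions dividing the leg length (default 3,
#'   the standard composite).
#' @return Dimensionless composite score.
#' @examples
#' ybt_composite(60, 55, 50, leg_length = 67) # ~8.209
#' @export
ybt_composite <- function(anterior, posteromedial, posterolateral, leg_length,
                          divisor = 3) {
  if (!is.numeric(leg_length) || leg_length <= 0) {
    stop("leg_length must be positive", call. = FALSE)
  }
  if (any(c(anterior, posteromedial, posterolateral) < 0)) {
    stop("reach distances must be non-negative", call. = FALSE)
  }
  (anterior + posteromedial + posterolateral) / (divisor * leg_length) * 10
}

#' Per-direction normalized YBT score
#'
#' `reach / leg_length * 10`; used for reporting and as the scale of the
#' synthetic generator's per-direction calibration.
#'
#' @param reach Reach distance in cm (>= 0).
#' @param leg_length Leg length in cm (> 0).
#' @return Dimensionless score.
#' @export
ybt_normalized <- function(reach, leg_length) {
  if (!is.numeric(leg_length) || leg_length <= 0) {
    stop("leg_length must be positive", call. = FALSE)
  }
  if (any(reach < 0)) stop("reach must be non-negative", call. = FALSE)
  reach / leg_length * 10
}

#' Raw score for the static tests (SLB, TBT)
#'
#' More movement means worse balance, so the total movement is inverted by
#' subtraction from a constant chosen above the cohort maximum:
#' `raw = cte - total_movement`. Under the published scales a motionless
#' participant scores the cte itself (350 for SLB, 300 for TBT).
#'
#' @param total_movement Test total movement in cm (>= 0).
#' @param cte Inversion constant (movement units).
#' @return Raw score. May be negative for movement beyond the derivation
#'   cohort's maximum; rescaling clamps the final score.
#' @export
raw_score_static <- function(total_movement, cte) {
  if (any(total_movement < 0)) {
    stop("total_movement must be non-negative", call. = FALSE)
  }
  cte - total_movement
}

#' Raw score for the YBT
#'
#' Reach scores grow with performance, so no inversion is needed; the summed
#' six direction scores (3 directions x 2 legs) are log-transformed and
#' offset: `raw = log(sum) - cte`.
#'
#' @param direction_scores Six per-attempt scores (normalized composite
#'   inputs); their sum must be positive.
#' @param cte Log-scale offset (published value 80).
#' @param log_base `"natural"` or `"base10"`.
#' @return Raw score.
#' @export
raw_score_ybt <- function(direction_scores, cte, log_base = "natural") {
  log_base <- match.arg(log_base, c("natural", "base10"))
  s <- sum(direction_scores)
  if (!is.finite(s) || s <= 0) {
    stop("sum of YBT direction scores must be positive", call. = FALSE)
  }
  (if (log_base == "natural") log(s) else log10(s)) - cte
}

#' Demographic correction factor
#'
#' The fitted linear prediction of the raw score from sex, age and foot
#' size; half of it (by default) is subtracted from the raw score so that a
#' child is compared against peers of the same demographic profile rather
#' than the whole cohort.
#'
#' @param profile A [participant_profile()] (or one-row data.frame with
#'   `sex`, `age`, `foot_size`).
#' @param scale A [scale_definition()] carrying the coefficients.
#' @return FC value.
#' @examples
#' p <- participant_profile("ana", "female", 7.23, 32.48, 67.28)
#' correction_factor(p, imep_scale("SLB")) # ~262.47
#' @export
correction_factor <- function(profile, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  for (nm in c("sex", "age", "foot_size")) {
    v <- profile[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("profile is missing demographic field '%s'", nm),
           call. = FALSE)
    }
  }
  scale$fc_intercept +
    scale$fc_male * as.numeric(profile$sex == "male") +
    scale$fc_age * profile$age +
    scale$fc_footsize * profile$foot_size
}

#' Adjusted score
#'
#' `adjusted = raw - smoothing * FC`; the smoothing factor (0.5 by default)
#' softens the demographic correction's impact.
#'
#' @param raw Raw score.
#' @param fc Correction factor.
#' @param smoothing Factor in (0, 1].
#' @return Adjusted score.
#' @export
adjusted_score <- function(raw, fc, smoothing = 0.5) {
  raw - smoothing * fc
}

#' Final 1-10 score
#'
#' Min-max rescaling of the adjusted score onto the instrument's 1-10
#' range: `1 + 9 * (adjusted - min) / (max - min)`, clamped to \[1, 10\] so
#' that children beyond the derivation cohort's extremes still receive a
#' score on the scale (1 = greatest imbalance, 10 = greatest balance).
#'
#' @param adjusted Adjusted score.
#' @param scale A [scale_definition()] carrying `adjusted_min`/`adjusted_max`.
#' @return Score in \[1, 10\].
#' @export
final_score <- function(adjusted, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  s <- 1 + 9 * (adjusted - scale$adjusted_min) /
    (scale$adjusted_max - scale$adjusted_min)
  pmin(10, pmax(1, s))
}

#' Score one participant on one test
#'
#' Composes the full scoring chain and reports every intermediate quantity:
#' the movement input, raw score, correction factor, adjusted score and the
#' final 1-10 score. Scoring is a pure function of its inputs.
#'
#' For the static tests supply the test's [test_total_movement()] (or a
#' plain total in cm); for the YBT supply the six per-attempt direction
#' scores.
#'
#' @param profile A [participant_profile()].
#' @param movement For SLB/TBT: a `test_movement` or a single total in cm.
#'   Ignored for YBT.
#' @param ybt_scores For YBT: six per-attempt direction scores. Ignored for
#'   static tests.
#' @param scale A [scale_definition()]; defaults to the published scale for
#'   its test type.
#' @return An object of class `score_report`.
#' @examples
#' p <- participant_profile("ana", "female", 7.23, 32.48, 67.28)
#' score_participant(p, movement = 0, scale = imep_scale("SLB"))
#' @export
score_participant <- function(profile, movement = NULL, ybt_scores = NULL,
                              scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (scale$test_type == "YBT") {
    if (is.null(ybt_scores)) {
      stop("YBT scoring requires ybt_scores", call. = FALSE)
    }
    if (length(ybt_scores) != EXERCISES_PER_TEST[["YBT"]]) {
      stop(sprintf("YBT requires %d direction scores, got %d",
                   EXERCISES_PER_TEST[["YBT"]], length(ybt_scores)),
           call. = FALSE)
    }
    input <- sum(ybt_scores)
    raw <- raw_score_ybt(ybt_scores, scale$cte, scale$log_base)
  } else {
    if (is.null(movement)) {
      stop(sprintf("%s scoring requires movement", scale$test_type),
           call. = FALSE)
    }
    if (inherits(movement, "test_movement")) {
      if (movement$test_type != scale$test_type) {
        stop(sprintf("movement is for %s but scale is for %s",
                     movement$test_type, scale$test_type), call. = FALSE)
      }
      input <- movement$total
    } else {
      input <- as.numeric(movement)
    }
    raw <- raw_score_static(input, scale$cte)
  }
  fc <- correction_factor(profile, scale)
  adj <- adjusted_score(raw, fc, scale$smoothing)
  structure(
    list(participant = profile$nickname, test_type = scale$test_type,
         input = input, raw_score = raw, fc = fc, adjusted_score = adj,
         final_score = final_score(adj, scale)),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s %s: input %.2f -> raw %.2f, FC %.2f, adjusted %.2f, final %.2f / 10\n",
              x$participant, x$test_type, x$input, x$raw_score, x$fc,
              x$adjusted_score, x$final_score))
  invisible(x)
}
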