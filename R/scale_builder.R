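#' Choose the inversion constant from cohort movement totals
#'
#' The constant that inverts the movement scale is picked from the cohort's
#' range of variation: the smallest multiple of 50 strictly greater than the
#' observed maximum, which guarantees every raw score in the derivation
#' cohort is positive. Applied to the published cohort maxima this yields
#' 350 (SLB, max 347.53) and 300 (TBT, max 288.80).
#'
#' @param cohort_totals Non-empty vector of test total movements (cm, >= 0).
#' @param step Rounding step (default 50).
#' @return The constant.
#' @examples
#' choose_cte(c(120.4, 347.53, 88.1)) # 350
#' @export
choose_cte <- function(cohort_totals, step = 50) {
  if (length(cohort_totals) == 0) {
    stop("cohort_totals is empty", call. = FALSE)
  }
  if (any(!is.finite(cohort_totals)) || any(cohort_totals < 0)) {
    stop("cohort_totals must be finite and non-negative", call. = FALSE)
  }
  m <- max(cohort_totals)
  (floor(m / step) + 1) * step
}

#' Fit the demographic correction model
#'
#' Ordinary least squares of the raw scores on a male indicator, age, and
#' foot size. The fitted values of this model are each participant's
#' correction factor FC.
#'
#' @param raw_scores Numeric vector, one raw score per participant.
#' @param profiles Profile `data.frame` (columns `sex`, `age`, `foot_size`),
#'   same number of rows.
#' @param min_n Minimum cohort size (default 10).
#' @return List with `coefficients` (named: `fc_intercept`, `fc_male`,
#'   `fc_age`, `fc_footsize`), `se` (standard errors, same names), `sigma`
#'   (residual SD), and the underlying `fit` (an `lm`).
#' @export
fit_correction_model <- function(raw_scores, profiles, min_n = 10) {
  profiles <- as.data.frame(profiles)
  n <- length(raw_scores)
  if (nrow(profiles) != n) {
    stop("raw_scores and profiles disagree in length", call. = FALSE)
  }
  if (n < min_n) {
    stop(sprintf("need at least %d participants to fit the correction model, got %d",
                 min_n, n), call. = FALSE)
  }
  dat <- data.frame(raw = raw_scores,
                    male = as.numeric(profiles$sex == "male"),
                    age = profiles$age,
                    foot_size = profiles$foot_size)
  # a constant predictor makes the design rank-deficient; name the culprit
  for (nm in c("male", "age", "foot_size")) {
    if (length(unique(dat[[nm]])) < 2) {
      stop(sprintf("degenerate predictor '%s': constant across the cohort (design is rank-deficient)",
                   nm), call. = FALSE)
    }
  }
  fit <- lm(raw ~ male + age + foot_size, data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("degenerate predictor '%s': aliased in the design",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  smry <- summary(fit)
  nm_out <- c("fc_intercept", "fc_male", "fc_age", "fc_footsize")
  co <- setNames(as.numeric(coef(fit)), nm_out)
  se <- setNames(as.numeric(smry$coefficients[, "Std. Error"]), nm_out)
  list(coefficients = co, se = se, sigma = smry$sigma, fit = fit)
}

#' Cohort adjusted-score range
#'
#' The min and max of the cohort's adjusted scores, rounded outward to
#' integers (floor and ceiling) — the published scales report integer
#' bounds against fractional raw data.
#'
#' @param adjusted_scores Non-empty numeric vector.
#' @return Named numeric vector `c(adjusted_min, adjusted_max)`.
#' @export
adjusted_range <- function(adjusted_scores) {
  if (length(adjusted_scores) == 0) {
    stop("adjusted_scores is empty", call. = FALSE)
  }
  c(adjusted_min = floor(min(adjusted_scores)),
    adjusted_max = ceiling(max(adjusted_scores)))
}

#' Derive a complete scale from a cohort
#'
#' Re-runs the published scale-construction procedure on any cohort:
#' choose the inversion constant from the movement totals, invert to raw
#' scores (log-transform for YBT), fit the demographic correction
#' regression, compute each participant's adjusted score, and take the
#' outward-rounded adjusted range. Rescoring the derivation cohort with the
#' resulting scale spans \[1, 10\] up to the range-rounding slack.
#'
#' For the static tests the constant follows the multiple-of-50 rule; no
#' comparable rule reproduces the published YBT constant from its maximum,
#' so for YBT the constant is taken from `ybt_cte` (default 80, the
#' published value).
#'
#' @param profiles Profile `data.frame`, one row per participant.
#' @param totals For SLB/TBT: movement totals (cm), one per participant.
#'   For YBT: the summed six direction scores, one per participant.
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @param smoothing Smoothing factor for the correction (default 0.5).
#' @param log_base YBT log base (default natural).
#' @param ybt_cte Explicit YBT constant (default 80).
#' @return List with `scale` (a [scale_definition()]), `fit` (from
#'   [fit_correction_model()]), and per-participant `raw_scores` and
#'   `adjusted_scores`.
#' @export
build_scale <- function(profiles, totals, test_type, smoothing = 0.5,
                        log_base = "natural", ybt_cte = 80) {
  test_type <- match.arg(test_type, TEST_TYPES)
  profiles <- as.data.frame(profiles)
  if (nrow(profiles) != length(totals)) {
    stop("profiles and totals disagree in length", call. = FALSE)
  }
  if (test_type == "YBT") {
    cte <- ybt_cte
    raw <- vapply(totals, function(s) {
      if (s <= 0) stop("YBT summed scores must be positive", call. = FALSE)
      (if (log_base == "natural") log(s) else log10(s)) - cte
    }, numeric(1))
  } else {
    cte <- choose_cte(totals)
    raw <- raw_score_static(totals, cte)
  }
  fit <- fit_correction_model(raw, profiles)
  fc <- as.numeric(fit$fit$fitted.values)
  adjusted <- raw - smoothing * fc
  rng <- adjusted_range(adjusted)
  scale <- scale_definition(
    test_type = test_type, cte = cte,
    fc_intercept = fit$coefficients[["fc_intercept"]],
    fc_male = fit$coefficients[["fc_male"]],
    fc_age = fit$coefficients[["fc_age"]],
    fc_footsize = fit$coefficients[["fc_footsize"]],
    adjusted_min = rng[["adjusted_min"]],
    adjusted_max = rng[["adjusted_max"]],
    smoothing = smoothing, log_base = log_base)
  list(scale = scale, fit = fit, raw_scores = raw, adjusted_scores = adjusted)
}
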