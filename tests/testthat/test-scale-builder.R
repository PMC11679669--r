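test_that("the constant rule picks the next multiple of 50 above the maximum", {
  expect_equal(choose_cte(c(120.4, 347.53, 88.1)), 350)
  expect_equal(choose_cte(288.80), 300)
  expect_equal(choose_cte(300), 350) # strictly greater at the boundary
  expect_error(choose_cte(numeric(0)), "empty")
  expect_error(choose_cte(c(10, -1)), "non-negative")
  # always strictly above the max, so raw scores stay positive
  set.seed(41)
  for (i in 1:20) {
    tot <- runif(30, 0, 500)
    expect_gt(choose_cte(tot), max(tot))
  }
})

test_that("adjusted range rounds outward to integers", {
  expect_equal(adjusted_range(c(-71.2, 103.0, 229.4)),
               c(adjusted_min = -72, adjusted_max = 230))
  expect_equal(adjusted_range(3.7), c(adjusted_min = 3, adjusted_max = 4))
  expect_error(adjusted_range(numeric(0)), "empty")
})

test_that("correction model fits exactly on noise-free data and errors on degenerate designs", {
  cohort <- generate_cohort(generator_config(n = 40), seed = 101)
  truth <- c(intercept = 400, male = 5, age = -20, footsize = -6)
  raw <- truth["intercept"] + truth["male"] * (cohort$sex == "male") +
    truth["age"] * cohort$age + truth["footsize"] * cohort$foot_size
  # a noise-free design interpolates exactly (lm warns about the perfect fit)
  fit <- suppressWarnings(fit_correction_model(raw, cohort))
  expect_equal(unname(fit$coefficients),
               unname(truth), tolerance = 1e-6)

  females <- cohort[cohort$sex == "female", ]
  expect_error(
    fit_correction_model(raw[cohort$sex == "female"], females),
    "male")
  expect_error(fit_correction_model(raw[1:5], cohort[1:5, ]), "at least 10")
})

test_that("correction model recovers known coefficients within 3 SE under noise", {
  cfg <- generator_config(
    n = 200,
    fc_truth = list(intercept = 400, male = 5, age = -20, footsize = -6,
                    sd = 10, cte_ref = 350))
  cohort <- generate_cohort(cfg, seed = 7)
  totals <- simulate_test_totals(cohort, "SLB", cfg, seed = 8)
  built <- build_scale(cohort, totals, "SLB")
  co <- built$fit$coefficients
  se <- built$fit$se
  # the intercept is relative to the chosen cte; slopes are cte-invariant
  shift <- built$scale$cte - cfg$fc_truth$cte_ref
  expect_lt(abs(co[["fc_intercept"]] - (400 + shift)), 3 * se[["fc_intercept"]])
  expect_lt(abs(co[["fc_male"]] - 5), 3 * se[["fc_male"]])
  expect_lt(abs(co[["fc_age"]] - (-20)), 3 * se[["fc_age"]])
  expect_lt(abs(co[["fc_footsize"]] - (-6)), 3 * se[["fc_footsize"]])
})

test_that("the fit is equivariant under demographic recentring", {
  cohort <- generate_cohort(generator_config(n = 60), seed = 5)
  set.seed(6)
  raw <- 300 - 15 * cohort$age - 4 * cohort$foot_size +
    3 * (cohort$sex == "male") + rnorm(60, 0, 5)
  f0 <- fit_correction_model(raw, cohort)
  shifted <- cohort
  shifted$age <- shifted$age + 1
  f1 <- fit_correction_model(raw, shifted)
  expect_equal(f1$coefficients[["fc_age"]], f0$coefficients[["fc_age"]],
               tolerance = 1e-9)
  expect_equal(f1$coefficients[["fc_intercept"]],
               f0$coefficients[["fc_intercept"]] - f0$coefficients[["fc_age"]],
               tolerance = 1e-9)
})

test_that("a cohort rescored with its own scale spans [1, 10]", {
  cfg <- generator_config(n = 75)
  cohort <- generate_cohort(cfg, seed = 11)
  totals <- simulate_test_totals(cohort, "SLB", cfg, seed = 12)
  built <- build_scale(cohort, totals, "SLB")

  finals <- vapply(seq_len(nrow(cohort)), function(i) {
    score_participant(cohort[i, ], movement = totals[i],
                      scale = built$scale)$final_score
  }, numeric(1))
  expect_true(all(finals >= 1 & finals <= 10))
  # outward integer rounding of the range costs at most ~0.15 at the ends
  expect_lt(min(finals), 1 + 0.15)
  expect_gt(max(finals), 10 - 0.15)
})

test_that("build_scale works on the YBT branch with its explicit constant", {
  cfg <- generator_config(n = 50)
  cohort <- generate_cohort(cfg, seed = 21)
  sums <- simulate_test_totals(cohort, "YBT", cfg, seed = 22)
  built <- build_scale(cohort, sums, "YBT")
  expect_equal(built$scale$cte, 80)
  expect_equal(built$raw_scores, log(sums) - 80, tolerance = 1e-12)
  finals <- vapply(seq_len(nrow(cohort)), function(i) {
    score_participant(cohort[i, ], ybt_scores = rep(sums[i] / 6, 6),
                      scale = built$scale)$final_score
  }, numeric(1))
  expect_true(all(finals >= 1 & finals <= 10))
})

test_that("two disjoint cohorts from one generator agree on the correction model", {
  cfg <- generator_config(
    n = 200,
    fc_truth = list(intercept = 400, male = 5, age = -20, footsize = -6,
                    sd = 10, cte_ref = 350))
  a <- build_scale(generate_cohort(cfg, seed = 31),
                   simulate_test_totals(generate_cohort(cfg, seed = 31),
                                        "SLB", cfg, seed = 32), "SLB")
  b <- build_scale(generate_cohort(cfg, seed = 33),
                   simulate_test_totals(generate_cohort(cfg, seed = 33),
                                        "SLB", cfg, seed = 34), "SLB")
  shift <- b$scale$cte - a$scale$cte
  for (nm in c("fc_male", "fc_age", "fc_footsize")) {
    joint_se <- sqrt(a$fit$se[[nm]]^2 + b$fit$se[[nm]]^2)
    expect_lt(abs(a$fit$coefficients[[nm]] - b$fit$coefficients[[nm]]),
              3 * joint_se)
  }
  expect_lt(abs((a$fit$coefficients[["fc_intercept"]] + shift) -
                  b$fit$coefficients[["fc_intercept"]]),
            3 * sqrt(a$fit$se[["fc_intercept"]]^2 + b$fit$se[["fc_intercept"]]^2))
})
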