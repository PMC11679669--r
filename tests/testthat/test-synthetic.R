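test_that("cohort generation is deterministic and respects the inclusion window", {
  cfg <- generator_config()
  a <- generate_cohort(cfg, seed = 1)
  b <- generate_cohort(cfg, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 75L)
  expect_true(all(a$age >= 6 & a$age <= 9))
  expect_true(all(a$foot_size > 0 & a$leg_length > 0))
  expect_false(identical(a, generate_cohort(cfg, seed = 2)))
  expect_equal(nrow(generate_cohort(generator_config(n = 0), seed = 1)), 0L)
})

test_that("cohort demographics match the configured population", {
  cfg <- generator_config()
  cohort <- generate_cohort(cfg, seed = 1)
  d <- cfg$demographics
  expect_lt(abs(mean(cohort$age) - d$age_mean), 3 * d$age_sd / sqrt(75))
  expect_lt(abs(mean(cohort$foot_size) - d$foot_mean), 3 * d$foot_sd / sqrt(75))
  expect_lt(abs(mean(cohort$leg_length) - d$leg_mean), 3 * d$leg_sd / sqrt(75))
  expect_lt(abs(mean(cohort$sex == "female") - d$prop_female),
            3 * sqrt(d$prop_female * (1 - d$prop_female) / 75))
})

test_that("generator config validates overrides", {
  cfg <- generator_config(n = 10, sway = list(base_amplitude_cm = 0.3))
  expect_equal(cfg$n, 10)
  expect_equal(cfg$sway$base_amplitude_cm, 0.3)
  expect_equal(cfg$sway$theta, 1.0) # untouched default
  expect_error(generator_config(bogus_section = 1), "unknown")
})

test_that("simulated trials invert through cop_path and pass the pipeline", {
  cfg <- generator_config()
  p <- make_profile(weight = 27)
  sim <- generate_static_trial(p, "SLB", eyes = "open", config = cfg, seed = 3)
  expect_s3_class(sim$trial, "plate_trial")
  expect_equal(nrow(sim$trial$channels), 16 * cfg$sway$fs)

  w <- segment_window("SLB", 16, cfg$sway$fs, nrow(sim$trial$channels))
  cp <- cop_path(sim$trial, w)
  expect_equal(cp$n_dropped, 0L)
  expect_lt(max(abs(cp$cop_x - sim$cop$x[w])), 1e-6)
  expect_lt(max(abs(cp$cop_y - sim$cop$y[w])), 1e-6)

  feats <- plate_features(sim$trial, filter_channels = FALSE)
  expect_gt(feats$tf, 0)
  expect_gt(feats$cop_a, 0)

  # same seed -> identical trial
  sim2 <- generate_static_trial(p, "SLB", eyes = "open", config = cfg, seed = 3)
  expect_identical(sim$trial$channels, sim2$trial$channels)
})

test_that("eyes-closed sway exceeds eyes-open sway on paired simulations", {
  cfg <- generator_config()
  p <- make_profile(weight = 27)
  diffs <- vapply(1:100, function(i) {
    op <- generate_static_trial(p, "SLB", eyes = "open", config = cfg,
                                seed = 1000 + i)
    cl <- generate_static_trial(p, "SLB", eyes = "closed", config = cfg,
                                seed = 2000 + i)
    w <- segment_window("SLB", 16, cfg$sway$fs, nrow(op$trial$channels))
    exercise_movement(cl$tracks, w)$mvt - exercise_movement(op$tracks, w)$mvt
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("zero sway amplitude yields zero movement and raw score = cte", {
  cfg <- generator_config(sway = list(base_amplitude_cm = 0))
  p <- make_profile(weight = 27)
  proto <- simulate_protocol(p, cfg, seed = 9)
  mv <- protocol_movements(proto)
  expect_equal(mv$SLB$total, 0)
  expect_equal(raw_score_static(mv$SLB$total, imep_scale("SLB")$cte), 350)
})

test_that("YBT attempts are calibrated, ordered, and reproducible", {
  cfg <- generator_config()
  cohort <- generate_cohort(cfg, seed = 1)
  att <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    generate_ybt_scores(cohort[i, ], cfg, seed = 500 + i)
  }))
  means <- tapply(att$normalized_score, att$direction, mean)
  se3 <- 3 * cfg$ybt$attempt_sd / sqrt(2 * nrow(cohort))
  expect_lt(abs(means[["anterior"]] - 18.57), se3 + 0.05)
  expect_lt(abs(means[["posteromedial"]] - 17.47), se3 + 0.05)
  expect_lt(abs(means[["posterolateral"]] - 16.30), se3 + 0.05)
  expect_gt(means[["anterior"]], means[["posteromedial"]])
  expect_gt(means[["posteromedial"]], means[["posterolateral"]])
  # reaches back out of the normalized scale through leg length
  expect_equal(att$reach[1:6],
               att$normalized_score[1:6] * cohort$leg_length[1] / 10,
               tolerance = 1e-12)

  a1 <- generate_ybt_scores(cohort[1, ], cfg, seed = 77)
  a2 <- generate_ybt_scores(cohort[1, ], cfg, seed = 77)
  expect_identical(a1, a2)
})

test_that("a simulated protocol has the 14-slot structure", {
  cfg <- generator_config()
  p <- make_profile(weight = 27)
  proto <- simulate_protocol(p, cfg, seed = 4)
  expect_length(proto$records, 14L)
  tts <- vapply(proto$records, function(r) r$trial$test_type, character(1))
  expect_equal(as.vector(table(tts)[c("SLB", "TBT", "YBT")]), c(4L, 4L, 6L))
  eyes <- vapply(proto$records[1:4], function(r) r$trial$eyes, character(1))
  expect_equal(sort(eyes), c("closed", "closed", "open", "open"))
  dirs <- vapply(proto$records[9:14], function(r) r$trial$ybt_direction,
                 character(1))
  expect_equal(sort(unique(dirs)), sort(YBT_DIRECTIONS))
  expect_equal(nrow(proto$ybt_attempts), 6L)

  mv <- protocol_movements(proto)
  expect_equal(vapply(mv, function(m) length(m$exercises), integer(1)),
               c(SLB = 4L, TBT = 4L, YBT = 6L))
  expect_true(all(vapply(mv, function(m) m$total, numeric(1)) > 0))
})

test_that("fixture emission writes the full file set and round-trips", {
  cfg <- generator_config(n = 2)
  out <- withr::local_tempdir()
  res <- emit_fixture_set(cfg, out, seed = 6)
  plates <- list.files(out, pattern = "_plate\\.txt$")
  expect_length(plates, 28L) # 2 participants x 14 trials
  markers <- list.files(out, pattern = "_(acromion|umbilicus|trochanter|L3)\\.csv$")
  expect_length(markers, 28L * 4L)
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))

  cohort <- read_cohort_table(file.path(out, "cohort.csv"))
  expect_equal(cohort$nickname, res$cohort$nickname)
  expect_equal(cohort$age, res$cohort$age, tolerance = 1e-9)

  # re-read one trial and confirm byte-stable values
  proto <- simulate_protocol(res$cohort[1, ], cfg,
                             seed = (6 + 7919L) %% 2147483647L)
  f <- file.path(out, sprintf("%s_trial01_plate.txt", cohort$nickname[1]))
  back <- read_plate_export(f, test_type = "SLB")
  expect_equal(back$channels, proto$records[[1]]$trial$channels)

  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_equal(truth$config$sway$base_amplitude_cm,
               cfg$sway$base_amplitude_cm)
})
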