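#' Generator configuration
#'
#' Assembles the parameter set driving the synthetic cohort and trial
#' generator. Defaults reproduce the study conditions of the instrument's
#' derivation cohort: 75 children aged 6-9 (age 7.27 +/- 0.74 y, foot size
#' 32.95 +/- 2.14 EU, leg length 67.45 +/- 4.62 cm, 44/75 female), and YBT
#' per-direction normalized-score means 18.57 (anterior), 17.47
#' (posteromedial), 16.30 (posterolateral).
#'
#' The published per-direction dispersions are standard errors of cohort
#' means, not per-attempt SDs, so the per-attempt SD is a free parameter
#' (default 2.0 score units). Sway parameters (amplitude, eyes-closed
#' multiplier, age slope, test multipliers) are likewise free: the study
#' reports no raw per-trial dispersions.
#'
#' @param ... Overrides, as nested lists matching the default structure,
#'   e.g. `demographics = list(age_mean = 7.5)`,
#'   `sway = list(base_amplitude_cm = 0)`.
#' @return A nested list of class `generator_config`.
#' @section Structure:
#' * `n`: cohort size (default 75).
#' * `demographics`: `age_mean/age_sd` (truncated to `age_range`),
#'   `foot_mean/foot_sd`, `leg_mean/leg_sd`, `height_mean/height_sd`,
#'   `weight_mean/weight_sd`, `prop_female`, `prop_right_footed`.
#' * `sway`: `base_amplitude_cm` (stationary COP SD per axis),
#'   `eyes_closed_mult`, `age_slope` (per year, around `age_mean`),
#'   `test_mult` (named, SLB/TBT/YBT), `theta` (mean-reversion rate, 1/s),
#'   `fs` (Hz), `marker_gain` (marker-to-COP excursion ratios),
#'   `marker_noise` (marker jitter SD as a fraction of sway amplitude),
#'   `fz_noise_n` (vertical-force noise SD, N).
#' * `ybt`: `direction_means` (named), `attempt_sd`.
#' * `fc_truth`: `NULL`, or a list `intercept`, `male`, `age`, `footsize`,
#'   `sd`, `cte_ref` defining a known raw-score model for
#'   parameter-recovery runs.
#' @export
generator_config <- function(...) {
  defaults <- list(
    n = 75L,
    demographics = list(
      age_mean = 7.27, age_sd = 0.74, age_range = c(6, 9),
      foot_mean = 32.95, foot_sd = 2.14,
      leg_mean = 67.45, leg_sd = 4.62,
      height_mean = 1.28, height_sd = 0.06,
      weight_mean = 27.25, weight_sd = 7.37,
      prop_female = 44 / 75, prop_right_footed = 68 / 75),
    sway = list(
      base_amplitude_cm = 0.5, eyes_closed_mult = 1.5, age_slope = 0.1,
      test_mult = c(SLB = 1.0, TBT = 1.2, YBT = 1.5),
      theta = 1.0, fs = 100,
      marker_gain = c(acromion = 6, umbilicus = 4, trochanter = 3, L3 = 3.5),
      marker_noise = 0.05, fz_noise_n = 5),
    ybt = list(
      direction_means = c(anterior = 18.57, posteromedial = 17.47,
                          posterolateral = 16.30),
      attempt_sd = 2.0),
    fc_truth = NULL)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown generator config section(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  stopifnot(cfg$n >= 0, cfg$demographics$prop_female >= 0,
            cfg$demographics$prop_female <= 1,
            cfg$sway$base_amplitude_cm >= 0, cfg$ybt$attempt_sd >= 0)
  structure(cfg, class = c("generator_config", "list"))
}

# truncated-normal draw by inverse-CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` participant profiles from the configured demographic
#' distributions: truncated-normal age (respecting the 6-9 year inclusion
#' window), normal foot size, leg length, height and weight (truncated to
#' positive), Bernoulli sex and foot dominance. Deterministic given the
#' seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Profile `data.frame`, one row per participant, nicknames
#'   `"sim001"`, `"sim002"`, ...
#' @examples
#' cohort <- generate_cohort(generator_config(n = 5), seed = 1)
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$demographics
  n <- as.integer(config$n)
  if (n == 0) {
    out <- data.frame(nickname = character(), sex = character(),
                      age = numeric(), foot_size = numeric(),
                      leg_length = numeric(), dominant_foot = character(),
                      height = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("imep_cohort", "data.frame")
    return(out)
  }
  out <- withr::with_seed(seed, {
    data.frame(
      nickname = sprintf("sim%03d", seq_len(n)),
      sex = ifelse(runif(n) < d$prop_female, "female", "male"),
      age = rtruncnorm(n, d$age_mean, d$age_sd,
                       d$age_range[1], d$age_range[2]),
      foot_size = rtruncnorm(n, d$foot_mean, d$foot_sd, lower = 1),
      leg_length = rtruncnorm(n, d$leg_mean, d$leg_sd, lower = 1),
      dominant_foot = ifelse(runif(n) < d$prop_right_footed,
                             "right", "left"),
      height = rtruncnorm(n, d$height_mean, d$height_sd, lower = 0.5),
      weight = rtruncnorm(n, d$weight_mean, d$weight_sd, lower = 10),
      stringsAsFactors = FALSE)
  })
  class(out) <- c("imep_cohort", "data.frame")
  out
}

# per-trial sway amplitude (stationary COP SD, cm) for a participant/condition
sway_amplitude <- function(profile, test_type, eyes, config) {
  s <- config$sway
  a <- s$base_amplitude_cm * s$test_mult[[test_type]]
  if (identical(eyes, "closed")) a <- a * s$eyes_closed_mult
  a * max(0, 1 + s$age_slope * (profile$age - config$demographics$age_mean))
}

# exact stationary OU simulation: stationary SD `amp`, reversion rate theta
simulate_ou <- function(n, amp, theta, dt) {
  if (amp == 0 || n == 0) return(numeric(n))
  phi <- exp(-theta * dt)
  innov_sd <- amp * sqrt(1 - phi^2)
  x <- numeric(n)
  z <- rnorm(n)
  x[1] <- amp * z[1]
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + innov_sd * z[i + 1]
  x
}

#' Simulate one balance trial (plate + markers)
#'
#' Simulates quiet-standing sway as a mean-reverting (Ornstein-Uhlenbeck)
#' 2-D COP process with the configured stationary amplitude, scaled up for
#' eyes-closed and by the age slope, and larger for TBT and YBT than SLB.
#' The vertical force is the participant's weight under gravity plus noise,
#' and the plate moments are back-computed from the simulated COP, so
#' [cop_path()] recovers it exactly. Marker trajectories follow the COP
#' scaled by per-landmark gains (trunk landmarks swing several times the
#' COP excursion) plus jitter proportional to the sway amplitude.
#'
#' @param profile A one-row profile (needs `age`; `weight` used when
#'   present, else the configured mean).
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"` (YBT trials run 5 s, static
#'   16 s).
#' @param eyes `"open"`, `"closed"`, or `"n/a"`.
#' @param support_foot Support foot metadata.
#' @param ybt_direction Direction metadata for YBT slots.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with `trial` (a [plate_trial()]), `tracks` (list of four
#'   [marker_track()]s), and `cop` (the simulated COP in cm, for
#'   verification).
#' @export
generate_static_trial <- function(profile, test_type, eyes = "open",
                                  support_foot = "right",
                                  ybt_direction = "n/a",
                                  config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  test_type <- match.arg(test_type, TEST_TYPES)
  s <- config$sway
  duration <- if (test_type == "YBT") 5 else 16
  n <- round(duration * s$fs)
  dt <- 1 / s$fs
  amp <- sway_amplitude(profile, test_type, eyes, config)
  weight <- profile$weight
  if (is.null(weight) || is.na(weight)) weight <- config$demographics$weight_mean
  withr::with_seed(seed, {
    cop_x <- simulate_ou(n, amp, s$theta, dt)
    cop_y <- simulate_ou(n, amp, s$theta, dt)
    fz <- weight * 9.81 + rnorm(n, 0, s$fz_noise_n)
    # moments consistent with the simulated COP (COP in m on the plate)
    channels <- data.frame(
      Fx = rnorm(n, 0, s$fz_noise_n / 5), Fy = rnorm(n, 0, s$fz_noise_n / 5),
      Fz = fz,
      Mx = cop_y / 100 * fz, My = -cop_x / 100 * fz,
      Mz = rnorm(n, 0, 0.1))
    noise_sd <- s$marker_noise * amp
    tracks <- lapply(names(s$marker_gain), function(m) {
      g <- s$marker_gain[[m]]
      marker_track(m,
                   x = g * cop_x + rnorm(n, 0, noise_sd),
                   y = g * cop_y + rnorm(n, 0, noise_sd))
    })
    names(tracks) <- names(s$marker_gain)
    list(trial = plate_trial(profile$nickname, test_type, channels,
                             sampling_rate = s$fs, eyes = eyes,
                             support_foot = support_foot,
                             ybt_direction = ybt_direction),
         tracks = tracks,
         cop = list(x = cop_x, y = cop_y))
  })
}

#' Simulate a participant's six YBT attempts
#'
#' Draws per-direction normalized scores (reach / leg length * 10) from the
#' configured direction means with the per-attempt SD, one attempt per
#' direction per leg, and back-computes reaches via
#' `reach = score * leg_length / 10`. Scores are truncated at zero.
#'
#' @param profile A one-row profile (needs `leg_length`).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `direction`, `leg`, `reach` (cm),
#'   `normalized_score`, six rows (anterior, posteromedial, posterolateral
#'   x right, left).
#' @export
generate_ybt_scores <- function(profile, config = generator_config(),
                                seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  y <- config$ybt
  grid <- expand.grid(direction = YBT_DIRECTIONS, leg = c("right", "left"),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    # draw each attempt around its direction mean, truncated at 0
    score <- vapply(seq_len(nrow(grid)), function(i) {
      rtruncnorm(1, y$direction_means[[grid$direction[i]]], y$attempt_sd,
                 lower = 0)
    }, numeric(1))
    data.frame(grid,
               reach = score * profile$leg_length / 10,
               normalized_score = score,
               stringsAsFactors = FALSE)
  })
}

#' Simulate movement totals for a whole cohort
#'
#' The fast path for scale-building studies: per-participant test totals
#' without simulating full time series.
#'
#' With `fc_truth` unset, each participant's total is the analytic expected
#' excursion of the sway model (averaged over the test's eyes/leg
#' conditions) perturbed by lognormal trial-to-trial variation. With
#' `fc_truth` set, raw scores are drawn from the known linear model
#' `intercept + male*[male] + age*age + footsize*foot_size + N(0, sd)` and
#' converted to totals under the reference constant `cte_ref`
#' (`total = cte_ref - raw`, clamped at 0; for YBT,
#' `sum = exp(raw + cte_ref)`), giving a ground truth that
#' [build_scale()] should recover.
#'
#' @param profiles Profile `data.frame`.
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Numeric vector of totals (cm for static tests, summed direction
#'   scores for YBT), one per participant.
#' @export
simulate_test_totals <- function(profiles, test_type,
                                 config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  test_type <- match.arg(test_type, TEST_TYPES)
  profiles <- as.data.frame(profiles)
  n <- nrow(profiles)
  tr <- config$fc_truth
  withr::with_seed(seed, {
    if (!is.null(tr)) {
      male <- as.numeric(profiles$sex == "male")
      raw <- tr$intercept + tr$male * male + tr$age * profiles$age +
        tr$footsize * profiles$foot_size + rnorm(n, 0, tr$sd)
      if (test_type == "YBT") {
        exp(raw + tr$cte_ref)
      } else {
        pmax(0, tr$cte_ref - raw)
      }
    } else if (test_type == "YBT") {
      y <- config$ybt
      vapply(seq_len(n), function(i) {
        sum(vapply(rep(YBT_DIRECTIONS, 2), function(d) {
          rtruncnorm(1, y$direction_means[[d]], y$attempt_sd, lower = 0)
        }, numeric(1)))
      }, numeric(1))
    } else {
      s <- config$sway
      # expected per-exercise mvt: each marker's displacement is about
      # gain * excursion * sqrt(2), excursion ~ 3.5 stationary SDs over 10 s
      gain_sum <- sum(s$marker_gain[SCORING_MARKERS])
      vapply(seq_len(n), function(i) {
        p <- profiles[i, ]
        amps <- c(sway_amplitude(p, test_type, "open", config),
                  sway_amplitude(p, test_type, "open", config),
                  sway_amplitude(p, test_type, "closed", config),
                  sway_amplitude(p, test_type, "closed", config))
        sum(amps * 3.5 * sqrt(2) * gain_sum * exp(rnorm(4, 0, 0.25)))
      }, numeric(1))
    }
  })
}

# protocol slot table: 14 trials per participant
protocol_slots <- function() {
  rbind(
    data.frame(slot = 1:4, test_type = "SLB",
               eyes = c("open", "open", "closed", "closed"),
               support_foot = c("right", "left", "right", "left"),
               ybt_direction = "n/a", stringsAsFactors = FALSE),
    data.frame(slot = 5:8, test_type = "TBT",
               eyes = c("open", "open", "closed", "closed"),
               support_foot = c("right", "left", "right", "left"),
               ybt_direction = "n/a", stringsAsFactors = FALSE),
    data.frame(slot = 9:14, test_type = "YBT", eyes = "n/a",
               support_foot = rep(c("right", "left"), 3),
               ybt_direction = rep(YBT_DIRECTIONS, each = 2),
               stringsAsFactors = FALSE))
}

#' Simulate a participant's full 14-trial protocol
#'
#' One trial per protocol slot: 4 SLB (eyes open/closed x both legs),
#' 4 TBT, and 6 YBT (3 directions x both legs), each with its plate trial
#' and four marker tracks, plus the participant's YBT reach attempts.
#'
#' @param profile A one-row profile.
#' @param config A [generator_config()].
#' @param seed Integer seed; per-slot seeds are derived from it.
#' @return List with `records` (one per slot: `slot`, `test_type`, `eyes`,
#'   `support_foot`, `ybt_direction`, `trial`, `tracks`, `cop`) and
#'   `ybt_attempts` (from [generate_ybt_scores()]).
#' @export
simulate_protocol <- function(profile, config = generator_config(), seed = 1) {
  slots <- protocol_slots()
  records <- lapply(seq_len(nrow(slots)), function(i) {
    s <- slots[i, ]
    rec <- generate_static_trial(profile, s$test_type, eyes = s$eyes,
                                 support_foot = s$support_foot,
                                 ybt_direction = s$ybt_direction,
                                 config = config,
                                 seed = (seed * 101L + s$slot) %% 2147483647L)
    c(list(slot = s$slot), rec)
  })
  list(records = records,
       ybt_attempts = generate_ybt_scores(profile, config,
                                          seed = (seed * 131L) %% 2147483647L))
}

#' Movement totals from a simulated protocol
#'
#' Runs the marker-motion pipeline over a protocol's records: segments each
#' trial's scored window, computes each exercise's movement from the three
#' scoring markers, and sums per test.
#'
#' @param protocol Output of [simulate_protocol()].
#' @return Named list of [test_total_movement()] objects (`SLB`, `TBT`,
#'   `YBT`).
#' @export
protocol_movements <- function(protocol) {
  recs <- protocol$records
  by_test <- split(recs, vapply(recs, function(r) r$trial$test_type,
                                character(1)))
  out <- lapply(TEST_TYPES, function(tt) {
    exs <- lapply(by_test[[tt]], function(r) {
      w <- segment_window(tt, r$trial$nominal_duration,
                          r$trial$sampling_rate, nrow(r$trial$channels))
      exercise_movement(r$tracks, window = w, exercise_id = r$slot)
    })
    test_total_movement(exs, tt)
  })
  setNames(out, TEST_TYPES)
}

#' Write a synthetic fixture set to disk
#'
#' Emits, for each generated participant, the full 14-trial protocol as
#' plate text exports and marker CSVs, together with the cohort table and a
#' ground-truth JSON recording every generator parameter (and the known
#' correction-model coefficients when `fc_truth` is configured).
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the cohort and the written file paths.
#' @export
emit_fixture_set <- function(config = generator_config(), out_dir,
                             seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, seed)
  write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
  paths <- c(file.path(out_dir, "cohort.csv"))
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    proto <- simulate_protocol(p, config,
                               seed = (seed + 7919L * i) %% 2147483647L)
    for (r in proto$records) {
      stem <- file.path(out_dir, sprintf("%s_trial%02d", p$nickname, r$slot))
      write_plate_export(r$trial, paste0(stem, "_plate.txt"))
      paths <- c(paths, paste0(stem, "_plate.txt"))
      for (m in names(r$tracks)) {
        f <- paste0(stem, "_", m, ".csv")
        write_marker_track(r$tracks[[m]], f)
        paths <- c(paths, f)
      }
    }
    f <- file.path(out_dir, sprintf("%s_ybt_attempts.csv", p$nickname))
    write.csv(proto$ybt_attempts, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  truth <- list(seed = seed, config = unclass(config))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths <- c(paths, file.path(out_dir, "ground_truth.json"))
  invisible(list(cohort = cohort, paths = paths))
}
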