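---
title: "Balance scoring with imep: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balance scoring with imep: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imep)
```

## The instrument

IMEP scores static and dynamic balance in children aged 6-9 on a 1-10
scale, from two synchronized observation streams:

* a **force platform** recording six channels (forces Fx, Fy, Fz in N,
  moments Mx, My, Mz in N m), from which the package computes total force
  (TF), total moment (MT), the center-of-pressure (COP) path, and the COP
  95% ellipse area;
* **video marker tracking** of four bony landmarks (acromion, umbilicus,
  greater trochanter, and L3), from which it computes the movement
  quantities that the score is actually built on.

The protocol has 14 trials per child: four single-leg balance trials (SLB:
eyes open/closed on each leg, 16 s each), four tandem balance trials (TBT,
same structure), and six Y balance reaches (YBT: anterior, posteromedial
and posterolateral directions on each leg, 5 s each).

## From signals to movement

**Plate chain.** Channels are cleaned with a 10-50 Hz bandpass filter,
realized here as a zero-phase forward-backward Butterworth of order 4 per
pass (`bandpass()`); zero-phase filtering avoids shifting signal landmarks
in time. The RMS of the cleaned channels is reported per channel. Trials
are segmented before feature computation (`segment_window()`): static
trials drop the first and last 3 s of the 16 s (start-up peaks, end-of-trial
fatigue); YBT trials keep the initial 4 s covering the reach.

A practical subtlety: a 10-50 Hz passband removes DC, so filtered channels
cannot carry the static load. COP (`cop_x = -My/Fz`, `cop_y = Mx/Fz`, m
converted to cm) and the TF/MT resultant-magnitude RMS are therefore always
computed from the **unfiltered** channels, and the filtered-RMS stream is
reported separately. Postural sway itself concentrates below ~2 Hz, so the
filtered stream should be read as a high-frequency "signal activity"
summary, not as sway. Samples with `Fz` at or below 20 N (configurable) are
treated as unloaded and dropped, with the drop count reported.

**COP area.** The sway-area summary `cop_area_95()` is the 95% prediction
ellipse of the COP cloud, `pi * qchisq(0.95, 2) * sqrt(det(S))` with `S`
the sample covariance — the most common stabilometric definition. The
coverage quantile is configurable. A convex-hull area would also have been
defensible; the ellipse was chosen for robustness to single outlying
samples and for its closed form.

**Marker movement.** For each trial the displacement of a marker is the
max-min excursion along each image axis over the scored window, combined by
the Pythagorean theorem (`marker_displacement()`). The excursion range is
what a rater reads off a tracking overlay; path length was rejected because
it grows with frame rate and tracker jitter. An alternative
(`deviation = "max_from_start"`) is available. The three scoring markers
(acromion, umbilicus, trochanter) are summed into the exercise movement
`mvt`; L3 is read and reported but never scored. Per-test totals sum 4
exercises for SLB and TBT and 6 for YBT.

## From movement to a 1-10 score

For the static tests, more movement is worse, so the total movement is
inverted about a constant: `raw = cte - total`. The constant is chosen per
test as the smallest multiple of 50 strictly above the derivation cohort's
maximum total (`choose_cte()`), which keeps every raw score positive; the
published constants are 350 (SLB, cohort max 347.53) and 300 (TBT, max
288.80). For the YBT, reaches are normalized by leg length
(`ybt_composite()`: `(A + PM + PL) / (3 * leg_length) * 10`), more is
better, and the summed six attempt scores are log-transformed:
`raw = log(sum) - cte` with the published `cte = 80`.

Raw scores are then adjusted for demographics. An ordinary least squares
regression of raw scores on a male indicator, age, and foot size yields
each child's correction factor FC (its fitted value), and
`adjusted = raw - 0.5 * FC`; the 0.5 softens the correction. Finally the
adjusted score is min-max rescaled onto 1-10 using the cohort's
outward-rounded adjusted range and clamped, so children beyond the
derivation cohort's extremes still get a score:
`final = 1 + 9 * (adjusted - min) / (max - min)`, truncated to [1, 10].

Two notational wrinkles in the source material are resolved deliberately:

* the rescaling is sometimes printed with `* 9 - 1`, which maps the bounds
  to [-1, 8]; the package implements `* 9 + 1`, the only form consistent
  with the instrument's stated 1-10 range;
* the YBT composite appears both with and without the `x 3` divisor; the
  package uses the standard leg-length-times-three form, with the divisor
  configurable.

One published inconsistency is shipped as-is rather than silently repaired:
with `cte = 80` a natural-log YBT raw score sits near -75, which cannot
produce the published YBT adjusted range of (-175, 526) together with
correction coefficients of order 1. The published constants are stored
verbatim in the packaged YBT scale; users deriving their own YBT scale with
`build_scale()` get internally consistent constants for their cohort.

## Rebuilding a scale on a new cohort

`build_scale()` replays the whole construction: constant selection (for
YBT the constant is explicit config, default 80, since no arithmetic rule
reproduces the published value from the cohort maximum), raw scores, the
correction regression (which refuses rank-deficient designs, e.g.
single-sex cohorts), adjusted scores, and the outward-rounded adjusted
range. Rescoring the derivation cohort with its own scale spans [1, 10] up
to the rounding slack — with an adjusted range of width `W`, rounding costs
at most `9/W` score points at each end.

## The synthetic cohort generator

The generator exists so that every stage is testable with known ground
truth. It emulates:

* **Demographics** drawn from the derivation cohort's published summary:
  age 7.27 +/- 0.74 years (truncated to the 6-9 inclusion window by
  inverse-CDF sampling), foot size 32.95 +/- 2.14 EU, leg length
  67.45 +/- 4.62 cm, height 1.28 +/- 0.06 m, weight 27.25 +/- 7.37 kg,
  44/75 female, 68/75 right-footed.
* **Quiet-standing sway** as a two-dimensional Ornstein-Uhlenbeck process —
  the simplest stationary, mean-reverting process with bounded excursions —
  simulated exactly at the stationary law. The stationary COP SD per axis
  defaults to 0.5 cm, chosen so that simulated SLB movement totals match the
  derivation cohort's published range (typical totals around 200 cm, maxima
  near 350 cm). Amplitude is multiplied by 1.5 with eyes closed, by 1.2
  (TBT) or 1.5 (YBT) per test type, and by `1 + 0.1 * (age - 7.27)` per
  year of age (the study found balance tasks harder at older ages in this
  window; the direction of the effect is preserved, its size is a free
  parameter). The vertical force is weight under gravity plus noise, and
  plate moments are back-computed from the simulated COP, so `cop_path()`
  recovers the simulated trajectory to machine precision.
* **Marker excursions** proportional to the COP (gains 6, 4, 3 for
  acromion, umbilicus, trochanter — trunk landmarks swing several times the
  COP excursion — and 3.5 for L3) plus jitter proportional to sway
  amplitude, so a zero-amplitude configuration yields exactly zero
  movement.
* **YBT attempts** drawn per direction around the published cohort means
  (anterior 18.57, posteromedial 17.47, posterolateral 16.30 normalized
  score units). The published dispersions are standard errors of cohort
  means, not per-attempt SDs, so the per-attempt SD is a free parameter,
  default 2.0 score units; reaches are back-computed through each child's
  leg length.

Simulated plate trials run at 100 Hz by default — ample for sway, and it
keeps a full 14-trial protocol cheap to generate; the *reader's* fallback
for real exports remains 1000 Hz, typical of laboratory plates. With the
default 100 Hz the published 10-50 Hz band sits exactly at the Nyquist
limit, so pipelines over simulated trials compute the unfiltered stream
(`filter_channels = FALSE`) or raise the generator's `fs`.

For parameter-recovery studies, `fc_truth` replaces the sway model by a
known raw-score linear predictor under a reference constant `cte_ref`:
totals are `cte_ref - (Xb + noise)`, clamped at zero (the clamp is
essentially never active at sensible settings). Because the fitted
intercept is relative to whatever constant `build_scale()` selects, truth
recovery compares the intercept after shifting by the difference between
the chosen and reference constants; the slope coefficients are
constant-invariant.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* the instrument assumes — demographic mix, eyes and
age effects on sway amplitude, marker-COP coupling, direction-ordered YBT
scores — with Gaussian/OU noise. Real force-plate data have non-Gaussian
sway regimes, drift, tracker dropouts, and learning effects across trials,
none of which are emulated; pipeline correctness on synthetic data does not
certify those behaviors.

## Numerical choices and degenerate inputs

* Filtering requires `fs > 2 * high` (hard error) and more than `3 * order`
  samples.
* Trial lengths must agree with `nominal_duration * fs` within 5%; static
  trials shorter than 7 s leave an empty scored window and error.
* `cop_area_95()` returns 0 for degenerate (e.g. collinear or constant)
  clouds; it needs at least two points.
* `choose_cte()` is strict: a maximum exactly on a multiple of 50 moves up
  to the next one, keeping raw scores strictly positive.
* Final scores are clamped, never extrapolated, outside the adjusted range.
* All generation is reproducible from (config, seed); nested seeds are
  derived arithmetically and kept below 2^31.

## Problem sizes used in the checks

The packaged tests run the analytic ellipse check at 1e5 Gaussian points,
parameter recovery at n = 200 participants, cohort calibration at the
study's n = 75, and paired eyes-open/closed comparisons over 100 simulated
trial pairs at 100 Hz.

## Known limitations

* The published YBT constants are internally inconsistent (above); the
  packaged YBT scale reproduces the publication, not a repair.
* The correction regression is fit per test on raw scores, unstandardized,
  matching the magnitude of the published coefficients; pooling tests into
  one model is not supported.
* No frequency-domain posturography (spectral power, sway density), no
  convex-hull COP area, no mixed-effects inference: the package houses the
  covariates those analyses consume, not the analyses themselves.
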