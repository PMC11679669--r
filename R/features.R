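#' Zero-phase Butterworth bandpass filter
#'
#' Digital cleaning of plate channels with a 10-50 Hz passband, realized as
#' a forward-backward (zero-phase) Butterworth filter so that filtering
#' introduces no time shift of signal landmarks. The effective attenuation
#' is twice the single-pass order.
#'
#' @param series Numeric sample vector.
#' @param fs Sampling rate in Hz; must exceed twice the upper cutoff.
#' @param low,high Passband edges in Hz (defaults 10 and 50).
#' @param order Butterworth order per pass (default 4).
#' @return Filtered series, same length as the input.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 30 * seq(0, 1, by = 1 / fs)) # inside the passband
#' y <- bandpass(x, fs)
#' @export
bandpass <- function(series, fs, low = 10, high = 50, order = 4) {
  if (!is.numeric(fs) || fs <= 2 * high) {
    stop(sprintf("sampling rate %g Hz violates the Nyquist requirement fs > 2*high = %g Hz",
                 fs, 2 * high), call. = FALSE)
  }
  if (low <= 0 || high <= low) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (length(series) <= 3 * order) {
    stop(sprintf("series too short to filter (%d samples, need > %d)",
                 length(series), 3 * order), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series))
}

#' Scored-window sample indices for a trial
#'
#' Static trials (SLB, TBT) drop the first and last 3 s of the nominal 16 s
#' to avoid the settling peak at the start and fatigue at the end; YBT trials
#' keep the initial 4 s covering the reach movement.
#'
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @param nominal_duration Nominal trial length in s.
#' @param fs Sampling rate in Hz.
#' @param n_samples Number of samples actually recorded; must agree with
#'   `nominal_duration * fs` within 5%.
#' @return Integer vector of retained sample indices (1-based, contiguous).
#' @examples
#' w <- segment_window("SLB", 16, fs = 100, n_samples = 1600)
#' range(w) # samples 301..1300, i.e. seconds 3..13
#' @export
segment_window <- function(test_type, nominal_duration, fs, n_samples) {
  test_type <- match.arg(test_type, TEST_TYPES)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  expected <- nominal_duration * fs
  if (abs(n_samples - expected) > 0.05 * expected) {
    stop(sprintf("trial has %d samples but %g s at %g Hz implies %g (>5%% off)",
                 n_samples, nominal_duration, fs, expected), call. = FALSE)
  }
  if (test_type == "YBT") {
    start <- 0
    end <- min(round(4 * fs), n_samples)
  } else {
    start <- round(3 * fs)
    end <- n_samples - round(3 * fs)
  }
  if (end <= start) {
    stop(sprintf("window empty: %s trial of %g s leaves no samples after segmentation",
                 test_type, nominal_duration), call. = FALSE)
  }
  seq.int(start + 1L, end)
}

#' Root mean square of a series
#' @param series Non-empty numeric vector.
#' @return `sqrt(mean(series^2))`.
#' @export
rms <- function(series) {
  if (length(series) == 0) stop("rms of an empty series", call. = FALSE)
  sqrt(mean(series^2))
}

#' Center-of-pressure path from plate moments
#'
#' COP coordinates on the plate surface, from the unfiltered force/moment
#' channels: `cop_x = -My/Fz`, `cop_y = Mx/Fz`, converted from m to cm
#' (forces in N, moments in N m). Samples where the vertical load `Fz` does
#' not exceed `min_fz` are dropped (unloaded-plate guard) and counted.
#'
#' @param trial A [plate_trial()].
#' @param window Integer sample indices (e.g. from [segment_window()]);
#'   `NULL` uses the full trial.
#' @param min_fz Minimum vertical load in N for a sample to count (default 20).
#' @return List with `cop_x`, `cop_y` (cm) and `n_dropped`.
#' @export
cop_path <- function(trial, window = NULL, min_fz = 20) {
  stopifnot(inherits(trial, "plate_trial"))
  ch <- trial$channels
  if (is.null(window)) window <- seq_len(nrow(ch))
  if (length(window) == 0) stop("window is empty", call. = FALSE)
  fz <- ch$Fz[window]
  keep <- fz > min_fz
  if (!any(keep)) {
    stop(sprintf("no loaded samples: Fz never exceeds min_fz = %g N", min_fz),
         call. = FALSE)
  }
  idx <- window[keep]
  list(cop_x = -ch$My[idx] / ch$Fz[idx] * 100,
       cop_y = ch$Mx[idx] / ch$Fz[idx] * 100,
       n_dropped = sum(!keep))
}

#' 95% prediction-ellipse area of a COP point cloud
#'
#' The standard stabilometric sway-area summary: the area of the ellipse
#' expected to contain a given fraction of COP points under a bivariate
#' Gaussian model, `pi * chi2_2(q) * sqrt(det(S))` with `S` the sample
#' covariance of (x, y).
#'
#' @param cop_x,cop_y COP coordinate series in cm (equal length, >= 2 points).
#' @param quantile Coverage fraction (default 0.95).
#' @return Area in cm^2 (0 for a degenerate, e.g. collinear, cloud).
#' @export
cop_area_95 <- function(cop_x, cop_y, quantile = 0.95) {
  if (length(cop_x) != length(cop_y)) {
    stop("cop_x and cop_y must have the same length", call. = FALSE)
  }
  if (length(cop_x) < 2) {
    stop("need at least 2 COP points", call. = FALSE)
  }
  S <- cov(cbind(cop_x, cop_y))
  d <- det(S)
  if (!is.finite(d) || d < 0) d <- 0
  pi * qchisq(quantile, df = 2) * sqrt(d)
}

#' Total force and total moment over a window
#'
#' RMS of the resultant magnitude `sqrt(Fx^2 + Fy^2 + Fz^2)` (respectively
#' the moment channels) over the scored window, computed on the unfiltered
#' channels so that the static load is retained.
#'
#' @param trial A [plate_trial()].
#' @param window Integer sample indices; `NULL` uses the full trial.
#' @return Scalar TF in N (MT in N m).
#' @export
total_force <- function(trial, window = NULL) {
  resultant_rms(trial, window, c("Fx", "Fy", "Fz"))
}

#' @rdname total_force
#' @export
total_moment <- function(trial, window = NULL) {
  resultant_rms(trial, window, c("Mx", "My", "Mz"))
}

resultant_rms <- function(trial, window, cols) {
  stopifnot(inherits(trial, "plate_trial"))
  ch <- trial$channels
  if (is.null(window)) window <- seq_len(nrow(ch))
  if (length(window) == 0) stop("window is empty", call. = FALSE)
  mag <- sqrt(ch[[cols[1]]][window]^2 + ch[[cols[2]]][window]^2 +
                ch[[cols[3]]][window]^2)
  rms(mag)
}

#' Full feature set for one plate trial
#'
#' Runs the plate signal chain on a trial: segments the scored window,
#' computes total force and total moment and the COP path and 95% ellipse
#' area from the unfiltered channels, and the per-channel RMS of the
#' bandpass-filtered ("cleaned") signals. The two streams are reported side
#' by side; COP and TF/MT always come from the raw channels because the
#' 10-50 Hz passband removes the static load that carries them.
#'
#' @param trial A [plate_trial()].
#' @param low,high,order Bandpass settings; see [bandpass()].
#' @param min_fz Vertical-load guard for the COP path; see [cop_path()].
#' @param filter_channels If `FALSE`, skip the filtered-RMS stream (e.g. when
#'   `fs <= 2*high` makes the published band unusable).
#' @return An object of class `plate_features`: window bounds (s), `tf`,
#'   `mt`, `cop_x`/`cop_y` series, `cop_a`, dropped-sample count, and
#'   `rms_filtered` per channel (`NA` when skipped).
#' @export
plate_features <- function(trial, low = 10, high = 50, order = 4,
                           min_fz = 20, filter_channels = TRUE) {
  stopifnot(inherits(trial, "plate_trial"))
  n <- nrow(trial$channels)
  window <- segment_window(trial$test_type, trial$nominal_duration,
                           trial$sampling_rate, n)
  cop <- cop_path(trial, window, min_fz = min_fz)
  rms_filtered <- setNames(rep(NA_real_, 6),
                           c("Fx", "Fy", "Fz", "Mx", "My", "Mz"))
  if (isTRUE(filter_channels)) {
    for (nm in names(rms_filtered)) {
      filt <- bandpass(trial$channels[[nm]], trial$sampling_rate,
                       low = low, high = high, order = order)
      rms_filtered[nm] <- rms(filt[window])
    }
  }
  structure(
    list(participant = trial$participant, test_type = trial$test_type,
         eyes = trial$eyes, support_foot = trial$support_foot,
         ybt_direction = trial$ybt_direction,
         window_start_s = (window[1] - 1) / trial$sampling_rate,
         window_end_s = window[length(window)] / trial$sampling_rate,
         tf = total_force(trial, window), mt = total_moment(trial, window),
         cop_x = cop$cop_x, cop_y = cop$cop_y,
         cop_a = cop_area_95(cop$cop_x, cop$cop_y),
         n_dropped = cop$n_dropped, rms_filtered = rms_filtered),
    class = "plate_features")
}

#' @export
print.plate_features <- function(x, ...) {
  cat(sprintf("<plate_features> %s %s [%g, %g) s: TF = %.2f N, MT = %.3f N m, COP_A = %.3f cm^2\n",
              x$participant, x$test_type, x$window_start_s, x$window_end_s,
              x$tf, x$mt, x$cop_a))
  invisible(x)
}

#' Tabulate plate features for export
#'
#' One row per trial with the scalar features (tf, mt, cop_a, filtered RMS
#' per channel, window bounds, dropped-sample count), matching the feature
#' CSV contract.
#'
#' @param features A `plate_features` object or a list of them.
#' @return A `data.frame`.
#' @export
features_table <- function(features) {
  if (inherits(features, "plate_features")) features <- list(features)
  do.call(rbind, lapply(features, function(f) {
    data.frame(participant = f$participant, test_type = f$test_type,
               eyes = f$eyes, support_foot = f$support_foot,
               ybt_direction = f$ybt_direction,
               window_start_s = f$window_start_s, window_end_s = f$window_end_s,
               tf = f$tf, mt = f$mt, cop_a = f$cop_a, n_dropped = f$n_dropped,
               rms_Fx = f$rms_filtered[["Fx"]], rms_Fy = f$rms_filtered[["Fy"]],
               rms_Fz = f$rms_filtered[["Fz"]], rms_Mx = f$rms_filtered[["Mx"]],
               rms_My = f$rms_filtered[["My"]], rms_Mz = f$rms_filtered[["Mz"]],
               stringsAsFactors = FALSE)
  }))
}
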