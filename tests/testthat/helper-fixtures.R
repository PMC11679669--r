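# shared fixture builders: everything is generated in code, nothing on disk

make_profile <- function(nickname = "kid1", sex = "female", age = 7.23,
                         foot_size = 32.48, leg_length = 67.28, ...) {
  participant_profile(nickname, sex, age, foot_size, leg_length, ...)
}

# constant-load trial: Fz in N, moments in N m, duration s at fs Hz
make_trial <- function(fz = 267, mx = 0, my = 0, fx = 0, fy = 0, mz = 0,
                       duration = 16, fs = 100, test_type = "SLB", ...) {
  n <- round(duration * fs)
  plate_trial("kid1", test_type,
              channels = data.frame(Fx = rep(fx, n), Fy = rep(fy, n),
                                    Fz = rep(fz, n), Mx = rep(mx, n),
                                    My = rep(my, n), Mz = rep(mz, n)),
              sampling_rate = fs, ...)
}

# a track with prescribed per-axis excursions, in cm
make_track <- function(marker = "umbilicus", xrange = 0, yrange = 0, n = 50) {
  x <- seq(0, xrange, length.out = n)
  y <- seq(0, yrange, length.out = n)
  marker_track(marker, x, y)
}

# three scoring tracks with given total excursion split equally
make_scoring_tracks <- function(xrange = 1, yrange = 1, with_l3 = FALSE) {
  tracks <- lapply(c("acromion", "umbilicus", "trochanter"),
                   make_track, xrange = xrange, yrange = yrange)
  if (with_l3) tracks <- c(tracks, list(make_track("L3", xrange, yrange)))
  tracks
}
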