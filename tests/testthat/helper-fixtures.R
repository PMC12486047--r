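# Small fixtures shared across test files; everything is built in code.

# Short cued block: 4 move/rest repetitions of 5 s at a modest sampling
# rate, for tests where the full 200-s block would be wasteful.
tiny_schedule <- function(n_reps = 4, move_s = 5, rest_s = 5) {
  motor_test_schedule(n_reps = n_reps, move_s = move_s, rest_s = rest_s)
}

tiny_recording <- function(seed, move_rate = 3, rest_rate = 0.5,
                           n_channels = 4, n_active = n_channels,
                           fs = 500, schedule = tiny_schedule()) {
  generate_recording(schedule, n_channels = n_channels, n_active = n_active,
                     fs = fs, rest_burst_rate = rest_rate,
                     move_burst_rate = move_rate, seed = seed)
}

# Straight vessel along the rostro-caudal axis (x = z = 0).
straight_vessel <- function(y_from = 80, y_to = 0, step = 0.5, radius = 3.55) {
  ys <- seq(y_from, y_to, by = -step)
  vessel_model(cbind(x = 0, y = ys, z = 0), radius)
}

# A stent line object spanning exactly [y_lo, y_hi] on the axis.
straight_line <- function(y_lo, y_hi, spacing = 0.5, x = 0, z = 0) {
  ys <- seq(y_hi, y_lo, by = -spacing)
  pts <- cbind(x = x, y = ys, z = z)
  structure(list(points = pts, tip = pts[1, ], arc_length = y_hi - y_lo,
                 spacing = spacing), class = "stent_line")
}

# Hand-built surface from explicit vertex tables (one hemisphere each).
manual_surface <- function(pial_L, pial_R, labels_L = NULL, labels_R = NULL,
                           white_L = pial_L, white_R = pial_R) {
  mk <- function(p, w, lab) {
    if (is.null(lab)) lab <- rep("M1", nrow(p))
    list(pial = p, white = w,
         triangles = matrix(c(1L, 2L, 3L), 1), labels = lab)
  }
  structure(list(
    hemispheres = list(L = mk(pial_L, white_L, labels_L),
                       R = mk(pial_R, white_R, labels_R)),
    bands = default_bands(), spacing = NA, params = NULL
  ), class = "surface_model")
}

# Hand-built burst series (per-channel onset lists) for density tests.
manual_bursts <- function(onsets, duration, fs = 1000) {
  structure(list(
    onsets = onsets,
    durations = lapply(onsets, function(o) rep(0.05, length(o))),
    fs = fs, duration = duration,
    degenerate = rep(FALSE, length(onsets))
  ), class = "burst_series")
}
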