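#' Default cohort generator configuration
#'
#' Ranges emulate the printed cohort: years since diagnosis uniform on
#' 1-12, integer muscle strength score 0-50, active channels uniform
#' integer 9-16, lumen radius centred on 3.55 mm (7.1 mm sinus width),
#' stent rostral tip drawn across the band layout so M1 coverage spans a
#' wide range, and per-participant thickness / fold / clearance variation
#' so the geometric factors are not mutually redundant.
#'
#' @return named list of generator parameters.
#' @export
cohort_config <- function() {
  list(
    bands = default_bands(),
    # per-participant anatomical variability of the band layout: the M1
    # band centre and width, the width of S1, and the premotor gap
    # (labeled OTHER) separating M1 from SMA all vary across people
    m1_center_jitter = 4,           # mm around the base M1 band centre
    m1_width_range = c(20, 30),     # mm
    s1_width_range = c(15, 25),     # mm
    sma_gap_range = c(2, 12),       # premotor strip between M1 and SMA
    tip_range = c(22, 72),          # rostral tip station (mm): spans
                                    # near-zero to full M1 coverage on
                                    # both the rostral and caudal side
    stent_length = 25,
    thickness_range = c(2.0, 3.0),  # cortical thickness (mm)
    fold_amplitude_range = c(1, 3),
    clearance_range = c(2.5, 10),   # lumen centre above dorsal pial (mm):
                                    # sinus depth varies markedly across
                                    # people, decoupling the distance
                                    # factors from rostro-caudal placement
    lumen_radius_mean = 3.55, lumen_radius_sd = 0.45,
    years_range = c(1, 12),
    muscle_range = c(0L, 50L),
    active_range = c(9L, 16L),
    n_channels = 16, fs = 1000,
    rest_rate = 0.5, rate_gain = 1.0,  # move rate = rest + gain * strength
    activation = list(spread_range = c(5, 12), amplitude_range = c(2, 6),
                      noise_sd = 0.5, peak_sd = 8)
  )
}

# Analytic rostro-caudal overlap (%) of the stent extent with a band.
band_overlap_pct <- function(tip, stent_length, band) {
  100 * interval_intersection_length(c(tip - stent_length, tip), band) /
    stent_length
}

#' Generate a synthetic participant cohort with planted ground truth
#'
#' Every participant gets a folded two-hemisphere surface with an
#' individual band layout (M1 centre/width, S1 width and the premotor gap
#' between M1 and SMA all vary, as cortical anatomy does), a midline sinus
#' with a stent placement whose M1 coverage is drawn across
#' `factor_config$tip_range`, covariates from the configured
#' distributions, an activation map, and a cued-block recording whose
#' move/rest burst-rate contrast is set by the planted relation
#' `strength = intercept + slope * (M1 overlap %) + noise`. The planted
#' strength and the analytic overlap are stored as ground truth.
#'
#' @param n_participants cohort size (>= 3).
#' @param relation list with `intercept`, `slope`, `noise_sd` of the
#'   planted overlap-to-strength relation. The default places participants
#'   with minimal M1 coverage near the signal floor (negative planted
#'   strengths are clamped: move rate = rest rate) and strong coverage at a
#'   robust burst-rate contrast, so the measured overlap-strength rank
#'   correlation sits near 0.8, the association structure the cohort is
#'   meant to emulate.
#' @param factor_config generator parameters, see [cohort_config()].
#' @param schedule the cued block schedule shared by all participants.
#' @param seed master integer seed; all per-participant draws use child
#'   seeds derived from it.
#' @param light if `TRUE`, generate only planted truth and covariates
#'   (no meshes, recordings or maps) — used for large-sample checks of the
#'   generative model itself.
#' @return list with `cohort` (data.frame of ids, covariates and planted
#'   truth) and `participants` (list of per-participant objects, `NULL`
#'   when `light`).
#' @export
generate_cohort <- function(n_participants = 10,
                            relation = list(intercept = -0.5,
                                            slope = 0.035,
                                            noise_sd = 0.1),
                            factor_config = cohort_config(),
                            schedule = motor_test_schedule(),
                            seed = 1L, light = FALSE) {
  if (n_participants < 3) stop("need >= 3 participants")
  fc <- utils::modifyList(cohort_config(), factor_config)
  if (diff(fc$tip_range) <= 0) stop("degenerate overlap (tip) range")
  base_center <- mean(fc$bands$M1)

  rows <- list()
  participants <- if (light) NULL else vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    ps <- function(stage) child_seed(seed, i * 100L + stage)
    set.seed(ps(1L))
    tip <- runif(1, fc$tip_range[1], fc$tip_range[2])
    thickness <- runif(1, fc$thickness_range[1], fc$thickness_range[2])
    fold_amp <- runif(1, fc$fold_amplitude_range[1],
                      fc$fold_amplitude_range[2])
    clearance <- runif(1, fc$clearance_range[1], fc$clearance_range[2])
    radius <- max(2.2, rnorm(1, fc$lumen_radius_mean, fc$lumen_radius_sd))
    years <- runif(1, fc$years_range[1], fc$years_range[2])
    muscle <- sample(fc$muscle_range[1]:fc$muscle_range[2], 1L)
    n_active <- sample(fc$active_range[1]:fc$active_range[2], 1L)
    # participant-specific band layout (anatomical variability)
    m1_center <- base_center + runif(1, -fc$m1_center_jitter,
                                     fc$m1_center_jitter)
    m1_width <- runif(1, fc$m1_width_range[1], fc$m1_width_range[2])
    s1_width <- runif(1, fc$s1_width_range[1], fc$s1_width_range[2])
    sma_gap <- runif(1, fc$sma_gap_range[1], fc$sma_gap_range[2])
    m1 <- m1_center + c(-0.5, 0.5) * m1_width
    bands_i <- list(
      SMA = c(m1[2] + sma_gap, m1[2] + sma_gap + 30),
      M1 = m1,
      S1 = c(m1[1] - s1_width, m1[1]),
      CAUDAL = c(m1[1] - s1_width - 40, m1[1] - s1_width)
    )
    overlap <- band_overlap_pct(tip, fc$stent_length, m1)
    strength <- relation$intercept + relation$slope * overlap +
      rnorm(1, 0, relation$noise_sd)
    move_rate <- fc$rest_rate + fc$rate_gain * max(strength, 0)
    act <- fc$activation
    peak <- rnorm(1, m1_center, act$peak_sd)
    spread <- runif(1, act$spread_range[1], act$spread_range[2])
    amplitude <- runif(1, act$amplitude_range[1], act$amplitude_range[2])

    rows[[i]] <- data.frame(
      id = sprintf("P%02d", i),
      years_since_diagnosis = years,
      muscle_strength = muscle,
      active_channels = n_active,
      planted_overlap_pct = overlap,
      planted_strength = strength,
      move_rate = move_rate,
      rest_rate = fc$rest_rate,
      rostral_tip = tip
    )

    if (!light) {
      surface <- generate_surface(bands = bands_i,
                                  fold_amplitude = fold_amp,
                                  thickness = thickness, seed = ps(2L))
      vs <- generate_vessel_and_stent(surface, lumen_radius = radius,
                                      stent_length = fc$stent_length,
                                      rostral_tip = tip,
                                      clearance = clearance, seed = ps(3L))
      rec <- generate_recording(schedule, n_channels = fc$n_channels,
                                n_active = n_active, fs = fc$fs,
                                rest_burst_rate = fc$rest_rate,
                                move_burst_rate = move_rate,
                                seed = ps(4L))
      map <- generate_activation_map(surface, peak_station = peak,
                                     spread = spread,
                                     amplitude = amplitude,
                                     noise_sd = act$noise_sd,
                                     seed = ps(5L))
      participants[[i]] <- list(
        id = rows[[i]]$id, surface = surface, vessel = vs$vessel,
        stent = vs$stent, schedule = schedule, recording = rec,
        activation = map,
        truth = rows[[i]]
      )
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(cohort = cohort, participants = participants)
}
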