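#' Names of the default 16-factor predictor set
#'
#' Three clinical/device covariates, six fMRI activation summaries (mean
#' and suprathreshold spread in M1/S1/SMA), and seven geometric factors
#' (stent-to-cortex distances, sinus width, rostro-caudal ROI overlaps and
#' M1 thickness). The screened factor set of the original analysis is not
#' published item by item; this reconstruction is documented in the
#' methods vignette.
#'
#' @return character vector of 16 names.
#' @export
default_factor_names <- function() {
  c("years_since_diagnosis", "muscle_strength", "active_channels",
    "fmri_mean_m1", "fmri_mean_s1", "fmri_mean_sma",
    "fmri_spread_m1", "fmri_spread_s1", "fmri_spread_sma",
    "stent_cortex_mean_mm", "stent_m1_mean_mm", "sss_width_mm",
    "overlap_sma_pct", "overlap_m1_pct", "overlap_s1_pct",
    "m1_thickness_mm")
}

#' Extract all user-specific factors and signal strength for one participant
#'
#' Runs the geometric quantification (stent line fit, distances, overlap,
#' sinus width, thickness), the fMRI activation summaries, the slice-based
#' targeting analysis, and the motor signal strength computation for one
#' synthetic (or assembled) participant object.
#'
#' @param p participant list with `surface`, `vessel`, `stent`,
#'   `recording`, `schedule`, `activation` (as produced by
#'   [generate_cohort()]).
#' @param signal config for [block_signal_strength()].
#' @param halfwidth dorsal band half-width (mm).
#' @param threshold activation z threshold.
#' @return list with `factors` (named numeric, 16 entries), `strength`
#'   (d-prime), and `slices` (center-of-gravity targeting summary).
#' @export
compute_participant_factors <- function(p, signal = signal_config(),
                                        halfwidth = 15, threshold = 2.3) {
  line <- fit_stent_line(p$stent, p$vessel)
  dist_all <- stent_to_cortex(line, p$surface)
  dist_m1 <- stent_to_cortex(line, p$surface, roi = "M1")
  ov <- roi_overlap(line, p$surface, halfwidth = halfwidth)
  width <- sinus_width(p$vessel, line)
  thick <- cortical_thickness(p$surface, roi = "M1")

  tab <- surface_vertex_table(p$surface, p$activation)
  astats <- roi_activation_stats(tab$value, tab$label, threshold = threshold)
  amean <- setNames(astats$mean, astats$roi)
  aspread <- setNames(astats$n_suprathreshold, astats$roi)

  extent <- range(unlist(p$surface$bands))
  grid <- slice_grid(origin = extent[1], spacing = 1,
                     n = ceiling(diff(extent)))
  prof <- slice_profile_from_map(p$surface, p$activation, grid,
                                 halfwidth = halfwidth)
  cog <- center_of_gravity(prof)
  span <- stent_slice_span(line, grid)
  m1s <- roi_slices(p$surface, grid, "M1", halfwidth = halfwidth)
  slices <- list(
    cog_station = cog,
    stent_midpoint_station = span$midpoint_station,
    cog_distance = cog_to_stent_distance(cog, span$midpoint_station),
    slice_overlap_m1_pct = stent_m1_slice_overlap(span$slices, m1s)
  )

  res <- block_signal_strength(p$recording, p$schedule, signal)

  factors <- c(
    years_since_diagnosis = p$truth$years_since_diagnosis,
    muscle_strength = p$truth$muscle_strength,
    active_channels = p$truth$active_channels,
    fmri_mean_m1 = unname(amean["M1"]),
    fmri_mean_s1 = unname(amean["S1"]),
    fmri_mean_sma = unname(amean["SMA"]),
    fmri_spread_m1 = unname(aspread["M1"]),
    fmri_spread_s1 = unname(aspread["S1"]),
    fmri_spread_sma = unname(aspread["SMA"]),
    stent_cortex_mean_mm = dist_all$mean,
    stent_m1_mean_mm = dist_m1$mean,
    sss_width_mm = width,
    overlap_sma_pct = unname(ov["SMA"]),
    overlap_m1_pct = unname(ov["M1"]),
    overlap_s1_pct = unname(ov["S1"]),
    m1_thickness_mm = thick
  )
  list(factors = factors, strength = res$dprime, slices = slices,
       min_distance_mm = dist_all$min)
}

#' Assemble the cohort predictor matrix
#'
#' @param run output of [generate_cohort()] (with participants).
#' @param ... passed to [compute_participant_factors()].
#' @return list with `X` (data.frame, 16 factor columns), `y` (d-prime
#'   response), `table` (everything combined, one row per participant)
#'   and `slices` (targeting summaries).
#' @export
assemble_factor_table <- function(run, ...) {
  per <- lapply(run$participants, compute_participant_factors, ...)
  X <- as.data.frame(do.call(rbind, lapply(per, `[[`, "factors")))
  y <- vapply(per, `[[`, numeric(1), "strength")
  slices <- do.call(rbind, lapply(per, function(q)
    data.frame(cog_station = q$slices$cog_station,
               stent_midpoint_station = q$slices$stent_midpoint_station,
               cog_distance_signed = q$slices$cog_distance$signed,
               slice_overlap_m1_pct = q$slices$slice_overlap_m1_pct)))
  table <- cbind(id = run$cohort$id, X, strength = y, slices)
  list(X = X, y = y, table = table, slices = slices)
}

#' End-to-end run configuration
#' @param seed master seed.
#' @param n_participants cohort size.
#' @param relation planted overlap-to-strength relation.
#' @param factor_config generator parameters ([cohort_config()] overrides).
#' @param signal signal strength parameters ([signal_config()] overrides).
#' @param halfwidth dorsal band half-width (mm).
#' @param include_lasso run the Lasso selection stage.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_participants = 10,
                       relation = list(intercept = -0.5, slope = 0.035,
                                       noise_sd = 0.1),
                       factor_config = list(), signal = list(),
                       halfwidth = 15, include_lasso = TRUE) {
  structure(list(
    seed = as.integer(seed), n_participants = n_participants,
    relation = relation,
    factor_config = utils::modifyList(cohort_config(), factor_config),
    signal = utils::modifyList(signal_config(), signal),
    halfwidth = halfwidth, include_lasso = include_lasso
  ), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, computes every user-specific factor and the motor
#' signal strength per participant, screens the factors (Spearman), runs
#' the Lasso selection, and persists all outputs (CSV/JSON/YAML) plus a
#' checksum manifest to `out_dir`. Deterministic given the config seed.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with `cohort`, `factors` (assembled table), `screen`,
#'   `lasso`, and `manifest` (data.frame of files and md5 checksums,
#'   `NULL` when nothing was written).
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- generate_cohort(config$n_participants, config$relation,
                         config$factor_config, seed = config$seed)
  ft <- assemble_factor_table(run, signal = config$signal,
                              halfwidth = config$halfwidth)
  screen <- screen_factors(ft$X, ft$y)
  lasso <- if (isTRUE(config$include_lasso)) lasso_select(ft$X, ft$y)
           else NULL

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    yaml::write_yaml(unclass(config), fp("config.yaml"))
    write.csv(run$cohort, fp("cohort.csv"), row.names = FALSE)
    write.csv(ft$table, fp("factors.csv"), row.names = FALSE)
    write.csv(as.data.frame(screen), fp("screen.csv"), row.names = FALSE)
    if (!is.null(lasso))
      write.csv(as.data.frame(lasso), fp("lasso.csv"), row.names = FALSE)
    log_lines <- c(
      sprintf("seed: %d", config$seed),
      sprintf("n_participants: %d", config$n_participants),
      sprintf("relation: intercept=%g slope=%g noise_sd=%g",
              config$relation$intercept, config$relation$slope,
              config$relation$noise_sd),
      sprintf("signal.%s: %s", names(config$signal),
              vapply(config$signal, function(v)
                paste(format(v), collapse = ","), character(1))),
      sprintf("factor_config.%s: %s", names(config$factor_config),
              vapply(config$factor_config, function(v)
                paste(format(unlist(v)), collapse = ","), character(1))),
      sprintf("halfwidth: %g", config$halfwidth)
    )
    writeLines(log_lines, fp("run.log"))
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))
    )
    jsonlite::write_json(manifest, fp("manifest.json"), dataframe = "rows",
                         pretty = TRUE)
  }
  list(cohort = run$cohort, factors = ft, screen = screen, lasso = lasso,
       manifest = manifest)
}

#' Validate pipeline inputs against the type invariants
#'
#' Checks every supplied component against its structural invariants
#' (mesh pairing and label coverage, vessel ordering and positive radii,
#' schedule ordering/alternation, the 2 x 200 Hz sampling bound, active
#' channel count, stent containment) and reports violations without
#' raising.
#'
#' @param surface,vessel,stent,recording,schedule optional components.
#' @return data.frame with columns `component` and `message`; zero rows
#'   when everything is well formed.
#' @export
validate_inputs <- function(surface = NULL, vessel = NULL, stent = NULL,
                            recording = NULL, schedule = NULL) {
  bad <- list()
  note <- function(component, message)
    bad[[length(bad) + 1L]] <<- data.frame(component = component,
                                           message = message)
  if (!is.null(surface)) {
    for (hn in names(surface$hemispheres)) {
      h <- surface$hemispheres[[hn]]
      if (nrow(h$pial) != nrow(h$white))
        note("surface", sprintf("%s: pial/white vertex counts differ", hn))
      if (!all(is.finite(h$pial)) || !all(is.finite(h$white)))
        note("surface", sprintf("%s: non-finite coordinates", hn))
      if (!all(h$labels %in% c(roi_labels(), "OTHER")))
        note("surface", sprintf("%s: invalid vertex labels", hn))
      if (max(h$triangles) > nrow(h$pial) || min(h$triangles) < 1)
        note("surface", sprintf("%s: triangle indexes invalid vertex", hn))
    }
  }
  if (!is.null(vessel)) {
    if (nrow(vessel$centerline) < 2)
      note("vessel", "centerline has fewer than 2 points")
    if (any(vessel$radius <= 0))
      note("vessel", "non-positive lumen radius")
    if (any(diff(vessel$centerline[, 2]) >= 0))
      note("vessel", "centerline stations not strictly decreasing")
  }
  if (!is.null(stent)) {
    if (nrow(rbind(stent)) == 0) note("stent", "empty segmentation")
    else if (!is.null(vessel)) {
      d <- nearest_vertex_distance(rbind(stent), vessel$centerline)
      if (any(d > max(vessel$radius) + 0.5))
        note("stent", "points outside the lumen")
    }
  }
  if (!is.null(schedule)) {
    if (any(schedule$end <= schedule$start))
      note("schedule", "epoch with non-positive duration")
    n <- nrow(schedule)
    if (n > 1) {
      ov <- which(schedule$start[-1] < schedule$end[-n] - 1e-12)
      for (i in ov)
        note("schedule", sprintf("epochs %d and %d overlap", i, i + 1L))
      if (any(schedule$label[-1] == schedule$label[-n]))
        note("schedule", "labels do not alternate")
    }
    if (!is.null(recording) && max(schedule$end) > recording$duration + 1e-9)
      note("schedule", "extends beyond recording duration")
  }
  if (!is.null(recording)) {
    if (recording$fs <= 400)
      note("recording",
           sprintf("sampling rate %g Hz violates the 2 x 200 Hz bound",
                   recording$fs))
    if (sum(recording$active) > ncol(recording$signal))
      note("recording", "active count exceeds channel count")
  }
  if (length(bad) == 0)
    return(data.frame(component = character(0), message = character(0)))
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}
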