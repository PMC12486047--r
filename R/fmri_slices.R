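#' Define a rostro-caudal slice grid
#'
#' Slices are half-open mm bins along the rostro-caudal axis: slice `i`
#' (0-based) covers `[origin + i*spacing, origin + (i+1)*spacing)`.
#'
#' @param origin station of the caudal edge of slice 0 (mm).
#' @param spacing slice thickness (mm, > 0).
#' @param n number of slices.
#' @return a `slice_grid` list.
#' @export
slice_grid <- function(origin = 0, spacing = 1, n = 100) {
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(origin = origin, spacing = spacing, n = as.integer(n)),
            class = "slice_grid")
}

#' Per-ROI activation statistics
#'
#' Mean statistic value over each ROI's elements and the count of elements
#' strictly above the significance threshold (z > 2.3 by default; an
#' element exactly at the threshold is not counted).
#'
#' @param values numeric statistic values (per vertex or per voxel).
#' @param labels ROI label per element, aligned with `values`.
#' @param threshold z threshold (strict inequality).
#' @param rois which ROIs to report.
#' @return data.frame with columns `roi`, `mean`, `n_suprathreshold`,
#'   `threshold`.
#' @export
roi_activation_stats <- function(values, labels, threshold = 2.3,
                                 rois = c("SMA", "M1", "S1")) {
  stopifnot(length(values) == length(labels))
  rows <- lapply(rois, function(r) {
    v <- values[labels == r]
    if (length(v) == 0) stop(sprintf("empty ROI '%s'", r))
    data.frame(roi = r, mean = mean(v),
               n_suprathreshold = sum(v > threshold),
               threshold = threshold)
  })
  do.call(rbind, rows)
}

#' Center of gravity of a slice activity profile
#'
#' Activity-weighted mean station. Negative activity values carry no mass
#' and are clamped to zero before weighting.
#'
#' @param profile a `slice_profile` data.frame (columns `slice` or
#'   `station`, and `activity`).
#' @return the center-of-gravity station (same units as the profile's
#'   station column).
#' @export
center_of_gravity <- function(profile) {
  station <- if ("station" %in% names(profile)) profile$station
             else profile$slice
  w <- pmax(profile$activity, 0)
  if (sum(w) <= 0) stop("zero total mass after clamping negatives")
  sum(w * station) / sum(w)
}

#' Slice span of the stent line
#'
#' Slices whose half-open mm bins intersect the line's rostro-caudal
#' interval with positive measure, and the slice at the interval midpoint
#' (the slice whose centre is nearest the midpoint station; a midpoint
#' exactly on a bin edge is equidistant between two slice centres and goes
#' to the even index, R's default rounding).
#'
#' @param line a `stent_line`.
#' @param grid a `slice_grid` covering the line.
#' @return list with `first`, `last` (0-based slice indices), `slices`
#'   (integer vector), `midpoint` (slice index) and `midpoint_station`
#'   (mm).
#' @export
stent_slice_span <- function(line, grid) {
  span <- range(line$points[, "y"])
  edges_lo <- grid$origin + (0:(grid$n - 1L)) * grid$spacing
  edges_hi <- edges_lo + grid$spacing
  hit <- which(span[1] < edges_hi & span[2] > edges_lo) - 1L
  if (length(hit) == 0) stop("line outside slice grid")
  if (span[1] < grid$origin - 1e-9 ||
      span[2] > grid$origin + grid$n * grid$spacing + 1e-9)
    stop("line outside slice grid")
  mid_idx <- as.integer(round((mean(span) - grid$origin) / grid$spacing -
                                0.5))
  list(first = min(hit), last = max(hit), slices = hit,
       midpoint = mid_idx,
       midpoint_station = grid$origin + mid_idx * grid$spacing)
}

#' Signed distance from activation center of gravity to stent midpoint
#'
#' Positive values mean the center of gravity lies rostral (anterior) of
#' the stent midpoint.
#'
#' @param cog center-of-gravity station or slice index.
#' @param midpoint stent midpoint on the same grid.
#' @return list with `signed` and `absolute` distance.
#' @export
cog_to_stent_distance <- function(cog, midpoint) {
  list(signed = cog - midpoint, absolute = abs(cog - midpoint))
}

#' Percent of stent slices overlapping M1 slices
#'
#' @param stent_slices integer slice indices covered by the stent.
#' @param m1_slices integer slice indices covered by M1.
#' @return overlap percentage of the stent slice set.
#' @export
stent_m1_slice_overlap <- function(stent_slices, m1_slices) {
  if (length(stent_slices) == 0) stop("empty stent slice set")
  100 * length(intersect(stent_slices, m1_slices)) / length(stent_slices)
}

#' Slices covered by an ROI band
#'
#' Maps an ROI's dorsal-band rostro-caudal interval (see [roi_overlap()])
#' onto a slice grid: all slices whose bins intersect the interval with
#' positive measure.
#'
#' @param surface a `surface_model`.
#' @param grid a `slice_grid`.
#' @param roi ROI label.
#' @param halfwidth dorsal band half-width (mm).
#' @return integer vector of 0-based slice indices.
#' @export
roi_slices <- function(surface, grid, roi = "M1", halfwidth = 15) {
  iv <- roi_intervals(surface, halfwidth)[[roi]]
  if (is.null(iv)) return(integer(0))
  edges_lo <- grid$origin + (0:(grid$n - 1L)) * grid$spacing
  edges_hi <- edges_lo + grid$spacing
  which(iv[1] < edges_hi & iv[2] > edges_lo) - 1L
}

#' Dorsal-strip slice profile from a surface activation map
#'
#' Averages the activation values of dorsal-band vertices (within
#' `halfwidth` of the midline, both hemispheres) falling in each slice bin.
#' Slices without vertices get zero activity.
#'
#' @param surface a `surface_model`.
#' @param map an `activation_map` aligned with the surface.
#' @param grid a `slice_grid`.
#' @param halfwidth dorsal band half-width (mm).
#' @return a `slice_profile` data.frame with columns `slice`, `station`
#'   (bin centre, mm) and `activity`.
#' @export
slice_profile_from_map <- function(surface, map, grid, halfwidth = 15) {
  tab <- surface_vertex_table(surface, map)
  band <- tab[abs(tab$x) <= halfwidth, ]
  idx <- floor((band$y - grid$origin) / grid$spacing)
  keep <- idx >= 0 & idx < grid$n
  agg <- tapply(band$value[keep], idx[keep], mean)
  act <- numeric(grid$n)
  act[as.integer(names(agg)) + 1L] <- agg
  structure(data.frame(
    slice = 0:(grid$n - 1L),
    station = grid$origin + (0:(grid$n - 1L) + 0.5) * grid$spacing,
    activity = act
  ), class = c("slice_profile", "data.frame"))
}
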