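#' Fit the stent centerline approximation
#'
#' Models the device as a fixed-length line centred in the sinus: starting
#' from the centerline point nearest (by rostro-caudal station) to the most
#' rostral point of the device segmentation, the line follows the vessel
#' centerline caudally until its arc length reaches `length`, and is
#' resampled at `spacing`-mm arc-length steps.
#'
#' @param seg a `stent_segmentation` (point matrix) or any n-by-3 matrix.
#' @param vessel a `vessel_model`.
#' @param length target arc length (mm); the device is 25 mm.
#' @param spacing resampling step along the line (mm).
#' @return a `stent_line`: list with `points` (matrix, rostral first),
#'   `tip` (first point), `arc_length`, `spacing`.
#' @export
fit_stent_line <- function(seg, vessel, length = 25, spacing = 0.5) {
  seg <- rbind(seg)
  if (nrow(seg) == 0) stop("segmentation is empty")
  cl <- vessel$centerline
  tip_station <- max(seg[, 2])
  i0 <- which.min(abs(cl[, 2] - tip_station))
  sub <- cl[i0:nrow(cl), , drop = FALSE]
  if (nrow(sub) < 2) stop("centerline exhausted before reaching length")
  s <- c(0, cumsum(sqrt(rowSums(diff(sub)^2))))
  if (max(s) < length - 1e-9)
    stop("centerline exhausted before reaching length")
  ss <- seq(0, length, by = spacing)
  pts <- sapply(1:3, function(cc) approx(s, sub[, cc], xout = ss)$y)
  colnames(pts) <- c("x", "y", "z")
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  structure(list(points = pts, tip = pts[1, ], arc_length = arc,
                 spacing = spacing), class = "stent_line")
}

#' Stent-to-cortex distance summary
#'
#' For every line sample point the nearest pial-vertex distance is found in
#' each hemisphere separately (to account for folding hiding one hemisphere
#' locally); the summary mean is the average over line points of the
#' two-hemisphere mean, and the minimum is the global minimum over points
#' and hemispheres. `roi` restricts candidate vertices to one ROI label.
#'
#' @param line a `stent_line`.
#' @param surface a `surface_model`.
#' @param roi `"ALL"` or one of `"SMA"`, `"M1"`, `"S1"`, `"CAUDAL"`.
#' @return a `distance_summary`: list with `mean`, `min`,
#'   `per_hemisphere` (named means), `roi`.
#' @export
stent_to_cortex <- function(line, surface, roi = "ALL") {
  per_hemi <- lapply(surface$hemispheres, function(h) {
    keep <- if (identical(roi, "ALL")) rep(TRUE, nrow(h$pial))
            else h$labels == roi
    if (!any(keep)) stop(sprintf("label '%s' absent from surface", roi))
    nearest_vertex_distance(line$points, h$pial[keep, , drop = FALSE])
  })
  dmat <- do.call(cbind, per_hemi)
  structure(list(
    mean = mean(rowMeans(dmat)),
    min = min(dmat),
    per_hemisphere = colMeans(dmat),
    roi = roi
  ), class = "distance_summary")
}

# Rostro-caudal interval of each ROI within the dorsal band (vertices within
# `halfwidth` of the midline). Vertex stations are treated as centres of
# axial cells, so each interval is extended by half the local station
# spacing on both sides; a band generated on an h-mm cell-centre grid is
# recovered exactly.
roi_intervals <- function(surface, halfwidth = 15) {
  tab <- surface_vertex_table(surface)
  band <- tab[abs(tab$x) <= halfwidth, ]
  if (nrow(band) == 0) stop("dorsal band contains no vertices")
  stations <- sort(unique(band$y))
  h <- if (length(stations) > 1) median(diff(stations)) else 0
  out <- lapply(roi_labels(), function(r) {
    y <- band$y[band$label == r]
    if (length(y) == 0) return(NULL)
    c(min(y) - h / 2, max(y) + h / 2)
  })
  names(out) <- roi_labels()
  out
}

#' Rostro-caudal ROI overlap of the stent line
#'
#' Projects the line onto the rostro-caudal axis and intersects its extent
#' with each ROI's rostro-caudal interval, taken from labeled vertices
#' within `halfwidth` mm of the midline (the dorsal band). Overlap is
#' reported as percent of the stent extent; over exhaustive disjoint bands
#' the four percentages sum to 100.
#'
#' @param line a `stent_line`.
#' @param surface a `surface_model`.
#' @param halfwidth dorsal band half-width (mm from midline).
#' @return named numeric vector (`SMA`, `M1`, `S1`, `CAUDAL`) of overlap
#'   percentages, with the ROI intervals attached as attribute
#'   `"intervals"`.
#' @export
roi_overlap <- function(line, surface, halfwidth = 15) {
  span <- range(line$points[, "y"])
  ivs <- roi_intervals(surface, halfwidth)
  pct <- vapply(roi_labels(), function(r) {
    iv <- ivs[[r]]
    if (is.null(iv)) return(0)
    100 * interval_intersection_length(span, iv) / diff(span)
  }, numeric(1))
  attr(pct, "intervals") <- ivs
  pct
}

#' Mean sinus width around the implant
#'
#' The lumen diameter (2x radius) sampled at every stent-line point and
#' averaged.
#'
#' @param vessel a `vessel_model`.
#' @param line a `stent_line` within the centerline extent.
#' @return mean width (mm).
#' @export
sinus_width <- function(vessel, line) {
  r <- approx(vessel$centerline[, 2], vessel$radius,
              xout = line$points[, "y"])$y
  if (anyNA(r)) stop("stent line outside the vessel radius samples")
  mean(2 * r)
}

#' Mean cortical thickness within an ROI
#'
#' Per-vertex Euclidean pial-to-white distance averaged over the ROI's
#' vertices of both hemispheres.
#'
#' @param surface a `surface_model` with paired pial/white sheets.
#' @param roi ROI label, or `"ALL"`.
#' @return mean thickness (mm).
#' @export
cortical_thickness <- function(surface, roi = "M1") {
  d <- unlist(lapply(surface$hemispheres, function(h) {
    if (nrow(h$pial) != nrow(h$white)) stop("unpaired pial/white surfaces")
    keep <- if (identical(roi, "ALL")) rep(TRUE, nrow(h$pial))
            else h$labels == roi
    if (!any(keep)) stop(sprintf("label '%s' absent from surface", roi))
    sqrt(rowSums((h$pial[keep, , drop = FALSE] -
                    h$white[keep, , drop = FALSE])^2))
  }))
  mean(d)
}
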