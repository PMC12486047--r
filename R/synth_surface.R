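#' Default rostro-caudal ROI band layout
#'
#' Bands are half-open intervals `[lo, hi)` in mm along the rostro-caudal
#' (y, anterior-positive) axis, ordered rostral to caudal: the supplementary
#' motor area (SMA) most rostral, then primary motor (M1), primary
#' somatosensory (S1), and everything caudal of S1 (CAUDAL).
#'
#' @return named list of length-2 numeric vectors.
#' @export
default_bands <- function() {
  list(
    SMA    = c(45, 70),
    M1     = c(20, 45),
    S1     = c(0, 20),
    CAUDAL = c(-40, 0)
  )
}

roi_labels <- function() c("SMA", "M1", "S1", "CAUDAL")

#' Generate a synthetic two-hemisphere cortical surface model
#'
#' Builds paired pial/white sheets for each hemisphere, mirrored about the
#' midline plane (x = 0). Coordinates are RAS millimetres: x lateral
#' (right-positive), y rostro-caudal (anterior-positive), z dorsal. Each
#' sheet is a height field `z = f(x, y)` with a linear lateral fall-off and
#' a sinusoidal fold along y emulating gyral folding; vertices are placed at
#' the centres of half-open `spacing`-mm axial cells, so ROI bands are
#' recovered exactly by cell-extended interval extraction downstream. The
#' white surface is the pial surface offset inward by `thickness` along the
#' analytic vertex normal, so every pial-to-white vertex distance equals
#' `thickness` exactly.
#'
#' @param bands named list of half-open `[lo, hi)` rostro-caudal intervals
#'   for SMA, M1, S1, CAUDAL (rostral to caudal, non-overlapping).
#' @param spacing vertex grid spacing (mm).
#' @param x_inner,x_outer lateral extent of each hemisphere sheet (mm from
#'   the midline).
#' @param z_base dorsal height of the sheet at the inner edge (mm).
#' @param lateral_slope linear fall-off of z with lateral distance
#'   (mm per mm).
#' @param fold_amplitude,fold_wavelength sinusoidal fold along y (mm).
#' @param thickness cortical thickness: pial-to-white offset (mm, > 0).
#' @param seed integer seed (reserved for jittered variants; the default
#'   construction is deterministic in its parameters).
#' @return a `surface_model`: list with `$hemispheres$L/$R` (each holding
#'   `pial`, `white` n-by-3 matrices, integer `triangles`, character
#'   `labels`), `$bands`, `$spacing`, `$params`.
#' @export
generate_surface <- function(bands = default_bands(), spacing = 1,
                             x_inner = 2, x_outer = 30, z_base = 40,
                             lateral_slope = 0.15, fold_amplitude = 2,
                             fold_wavelength = 12, thickness = 2.5,
                             seed = 1L) {
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0")
  stopifnot(all(roi_labels() %in% names(bands)))
  b <- do.call(rbind, bands[roi_labels()])
  ord <- order(-b[, 1])
  if (!identical(rownames(b)[ord], roi_labels()))
    stop("bands must be ordered rostro-caudally: SMA > M1 > S1 > CAUDAL")
  bs <- b[order(b[, 1]), , drop = FALSE]
  if (any(bs[-1, 1] < bs[-nrow(bs), 2] - 1e-9))
    stop("band extents overlap")

  y_min <- min(b[, 1]); y_max <- max(b[, 2])
  ys <- seq(y_min + spacing / 2, y_max - spacing / 2, by = spacing)
  xs <- seq(x_inner, x_outer, by = spacing)

  params <- list(
    z_base = z_base, lateral_slope = lateral_slope,
    fold_amplitude = fold_amplitude, fold_wavelength = fold_wavelength,
    x_inner = x_inner, thickness = thickness
  )

  sheet <- function(sign_x) {
    g <- expand.grid(x = xs * sign_x, y = ys)
    fold <- fold_amplitude * sin(2 * pi * g$y / fold_wavelength)
    z <- z_base - lateral_slope * (abs(g$x) - x_inner) - fold
    pial <- cbind(x = g$x, y = g$y, z = z)
    # analytic normal of the height field z = f(x, y)
    fx <- -lateral_slope * sign_x
    fy <- -fold_amplitude * (2 * pi / fold_wavelength) *
      cos(2 * pi * g$y / fold_wavelength)
    nrm <- cbind(-fx, -fy, 1)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    white <- pial - thickness * nrm
    labels <- rep("OTHER", nrow(g))
    for (r in roi_labels()) {
      lo <- bands[[r]][1]; hi <- bands[[r]][2]
      labels[g$y >= lo & g$y < hi] <- r
    }
    nx <- length(xs); ny <- length(ys)
    # two triangles per grid quad
    i <- rep(seq_len(nx - 1), ny - 1)
    j <- rep(seq_len(ny - 1), each = nx - 1)
    v00 <- (j - 1) * nx + i
    tri <- rbind(
      cbind(v00, v00 + 1, v00 + nx),
      cbind(v00 + 1, v00 + nx + 1, v00 + nx)
    )
    list(pial = pial, white = white, triangles = tri, labels = labels)
  }

  out <- list(
    hemispheres = list(L = sheet(-1), R = sheet(1)),
    bands = bands[roi_labels()], spacing = spacing, params = params
  )
  class(out) <- "surface_model"
  out
}

#' Construct a vessel model from a centerline and lumen radii
#'
#' @param centerline n-by-3 matrix of points (mm), ordered rostral to caudal
#'   (strictly decreasing y).
#' @param radius per-point lumen radius (mm, > 0); recycled if length 1.
#' @return a `vessel_model`.
#' @export
vessel_model <- function(centerline, radius) {
  centerline <- rbind(centerline)
  if (nrow(centerline) < 2) stop("centerline needs >= 2 points")
  radius <- rep_len(radius, nrow(centerline))
  if (any(radius <= 0)) stop("lumen radii must be > 0")
  if (any(diff(centerline[, 2]) >= 0))
    stop("centerline must be ordered rostral to caudal (y strictly decreasing)")
  structure(list(centerline = centerline, radius = radius),
            class = "vessel_model")
}

# Dorsal midline profile of a generated surface at stations y: the pial
# height at the inner sheet edge.
dorsal_profile <- function(surface, y) {
  p <- surface$params
  p$z_base - p$fold_amplitude * sin(2 * pi * y / p$fold_wavelength)
}

#' Generate a midline venous sinus and a stent segmentation inside it
#'
#' The sinus centerline runs along the midline above the cortical sheets,
#' matching the dorsal fold profile of the surface, at a configurable
#' clearance. The stent segmentation is a point cloud scattered on the lumen
#' wall spanning `[rostral_tip - stent_length, rostral_tip]` along the
#' rostro-caudal axis, emulating a CT segmentation of the device.
#'
#' @param surface a `surface_model`.
#' @param lumen_radius lumen radius (mm); scalar or one value per
#'   centerline point.
#' @param stent_length device length along the vessel (mm).
#' @param rostral_tip rostro-caudal station (mm) of the device's rostral
#'   end; must lie within the surface extent.
#' @param clearance height of the lumen centre above the dorsal pial
#'   profile (mm).
#' @param follow_fraction fraction of the cortical fold amplitude the
#'   sinus follows: the vessel rides the dorsal envelope, attenuating the
#'   gyral folds rather than tracing them.
#' @param n_stent_points number of wall points in the segmentation.
#' @param step centerline sampling step (mm).
#' @param seed integer seed.
#' @return list with `$vessel` (a `vessel_model`) and `$stent`
#'   (a `stent_segmentation` point matrix). Wall points sit on axial
#'   lumen cross-sections, so the segmentation's rostro-caudal span is
#'   exactly `[rostral_tip - stent_length, rostral_tip]`.
#' @export
generate_vessel_and_stent <- function(surface, lumen_radius = 3.55,
                                      stent_length = 25, rostral_tip = 55,
                                      clearance = 5, follow_fraction = 0.3,
                                      n_stent_points = 200,
                                      step = 0.5, seed = 1L) {
  b <- range(unlist(surface$bands))
  if (rostral_tip < b[1] || rostral_tip > b[2])
    stop("rostral_tip outside surface rostro-caudal extent")
  ys <- seq(b[2], b[1], by = -step)
  p <- surface$params
  zc <- p$z_base + clearance -
    follow_fraction * p$fold_amplitude * sin(2 * pi * ys / p$fold_wavelength)
  cl <- cbind(x = 0, y = ys, z = zc)
  vessel <- vessel_model(cl, lumen_radius)
  caudal_end <- rostral_tip - stent_length
  if (caudal_end < min(ys) - 1e-9 || rostral_tip > max(ys) + 1e-9)
    stop("stent extent outside centerline extent")

  set.seed(child_seed(seed, 7L))
  stations <- c(rostral_tip, caudal_end,
                runif(max(n_stent_points - 2L, 0L), caudal_end, rostral_tip))
  theta <- runif(length(stations), 0, 2 * pi)
  ctr <- sapply(c("x", "y", "z"), function(cc)
    approx(cl[, "y"], cl[, cc], xout = stations)$y)
  rad <- approx(cl[, "y"], vessel$radius, xout = stations)$y
  # wall points on axial cross-sections: radial offset in the x-z plane
  pts <- ctr + rad * cbind(cos(theta), 0, sin(theta))
  colnames(pts) <- c("x", "y", "z")
  stent <- structure(pts, class = c("stent_segmentation", class(pts)))
  list(vessel = vessel, stent = stent)
}

#' Generate a per-vertex activation statistic map on a surface
#'
#' A Gaussian activation bump along the rostro-caudal axis plus Gaussian
#' noise, standing in for a movement-versus-rest z-statistic map projected
#' onto the cortical surface.
#'
#' @param surface a `surface_model`.
#' @param peak_station rostro-caudal centre of the bump (mm).
#' @param spread bump standard deviation (mm, > 0).
#' @param amplitude peak z value.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return an `activation_map`: list with per-hemisphere numeric vectors
#'   `L`, `R` aligned with the surface vertices.
#' @export
generate_activation_map <- function(surface, peak_station, spread = 8,
                                    amplitude = 4, noise_sd = 0.5,
                                    seed = 1L) {
  if (spread <= 0) stop("spread must be > 0")
  set.seed(child_seed(seed, 11L))
  out <- lapply(surface$hemispheres, function(h) {
    y <- h$pial[, "y"]
    amplitude * exp(-(y - peak_station)^2 / (2 * spread^2)) +
      rnorm(length(y), 0, noise_sd)
  })
  structure(out, class = "activation_map")
}

#' All vertex labels and map values of a surface, hemispheres concatenated
#' @param surface a `surface_model`
#' @param map optional `activation_map` aligned with `surface`
#' @return data.frame with `hemi`, `label`, coordinates and optional `value`
#' @export
surface_vertex_table <- function(surface, map = NULL) {
  rows <- lapply(names(surface$hemispheres), function(hn) {
    h <- surface$hemispheres[[hn]]
    d <- data.frame(
      hemi = hn, label = h$labels,
      x = h$pial[, "x"], y = h$pial[, "y"], z = h$pial[, "z"]
    )
    if (!is.null(map)) d$value <- map[[hn]]
    d
  })
  do.call(rbind, rows)
}
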