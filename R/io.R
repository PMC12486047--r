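#' Read and write pipeline objects as plain-text files
#'
#' All interchange formats are plain text: cue schedules as JSON, surfaces
#' as a pair of CSV tables (vertices with paired pial/white coordinates
#' and labels; triangles), vessel centerlines and stent segmentations as
#' CSV point lists, recordings as a samples-by-channels CSV with a JSON
#' sidecar carrying the sampling rate and active mask, and run
#' configurations as YAML.
#'
#' @param schedule an `epoch_schedule`.
#' @param path file path.
#' @name vascbci-io
NULL

#' @rdname vascbci-io
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname vascbci-io
#' @export
read_schedule_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  epoch_schedule(d$start, d$end, d$label)
}

#' @rdname vascbci-io
#' @param surface a `surface_model`.
#' @param prefix path prefix; `<prefix>_vertices.csv` and
#'   `<prefix>_triangles.csv` are written.
#' @export
write_surface_csv <- function(surface, prefix) {
  verts <- do.call(rbind, lapply(names(surface$hemispheres), function(hn) {
    h <- surface$hemispheres[[hn]]
    data.frame(hemi = hn, label = h$labels,
               px = h$pial[, 1], py = h$pial[, 2], pz = h$pial[, 3],
               wx = h$white[, 1], wy = h$white[, 2], wz = h$white[, 3])
  }))
  tris <- do.call(rbind, lapply(names(surface$hemispheres), function(hn) {
    t <- surface$hemispheres[[hn]]$triangles
    data.frame(hemi = hn, v1 = t[, 1], v2 = t[, 2], v3 = t[, 3])
  }))
  write.csv(verts, paste0(prefix, "_vertices.csv"), row.names = FALSE)
  write.csv(tris, paste0(prefix, "_triangles.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname vascbci-io
#' @export
read_surface_csv <- function(prefix) {
  verts <- read.csv(paste0(prefix, "_vertices.csv"))
  tris <- read.csv(paste0(prefix, "_triangles.csv"))
  hemis <- lapply(split(verts, verts$hemi), function(v) {
    t <- tris[tris$hemi == v$hemi[1], ]
    list(pial = cbind(x = v$px, y = v$py, z = v$pz),
         white = cbind(x = v$wx, y = v$wy, z = v$wz),
         triangles = cbind(t$v1, t$v2, t$v3),
         labels = v$label)
  })
  structure(list(hemispheres = hemis, bands = NULL, spacing = NA,
                 params = NULL), class = "surface_model")
}

#' @rdname vascbci-io
#' @param vessel a `vessel_model`.
#' @export
write_vessel_csv <- function(vessel, path) {
  d <- data.frame(x = vessel$centerline[, 1], y = vessel$centerline[, 2],
                  z = vessel$centerline[, 3], radius = vessel$radius)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname vascbci-io
#' @export
read_vessel_csv <- function(path) {
  d <- read.csv(path)
  vessel_model(cbind(x = d$x, y = d$y, z = d$z), d$radius)
}

#' @rdname vascbci-io
#' @param stent a `stent_segmentation` point matrix.
#' @export
write_stent_csv <- function(stent, path) {
  write.csv(as.data.frame(unclass(stent)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname vascbci-io
#' @export
read_stent_csv <- function(path) {
  d <- read.csv(path)
  pts <- cbind(x = d$x, y = d$y, z = d$z)
  structure(pts, class = c("stent_segmentation", class(pts)))
}

#' @rdname vascbci-io
#' @param rec a `recording`.
#' @param prefix path prefix; `<prefix>_signal.csv` and
#'   `<prefix>_meta.json` are written.
#' @export
write_recording_csv <- function(rec, prefix) {
  write.csv(as.data.frame(rec$signal), paste0(prefix, "_signal.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, active = rec$active),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname vascbci-io
#' @export
read_recording_csv <- function(prefix) {
  sig <- as.matrix(read.csv(paste0(prefix, "_signal.csv")))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  recording(unname(sig), meta$fs, active = meta$active)
}
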