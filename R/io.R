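# On-disk recording bundles and the cohort manifest. One directory per
# breast-run: metadata.yaml, points.csv (point_id,x_mm,y_mm,z_mm) and
# displacements.csv (point_id,t_index,dx_mm,dy_mm,dz_mm). All plain text.

required_metadata <- c("breast_id", "side", "label", "input_frequency_hz",
                       "sampling_rate_hz", "n_points", "n_samples", "seed")

#' Write a recording bundle
#'
#' @param recording A `surface_motion_recording`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_bundle <- function(recording, dir) {
  stopifnot(inherits(recording, "surface_motion_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_smp <- nrow(recording$disp$dx)
  n_pts <- ncol(recording$disp$dx)
  meta <- list(breast_id = recording$breast_id, side = recording$side,
               label = recording$label,
               input_frequency_hz = recording$input_frequency,
               sampling_rate_hz = recording$sampling_rate,
               n_points = n_pts, n_samples = n_smp,
               seed = recording$seed)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  write.csv(recording$points, file.path(dir, "points.csv"),
            row.names = FALSE, quote = FALSE)
  long <- data.frame(
    point_id = rep(recording$points$point_id, each = n_smp),
    t_index = rep(seq_len(n_smp) - 1L, times = n_pts),
    dx_mm = as.vector(recording$disp$dx),
    dy_mm = as.vector(recording$disp$dy),
    dz_mm = as.vector(recording$disp$dz))
  write.csv(long, file.path(dir, "displacements.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read and validate a recording bundle
#'
#' Hard-errors on missing metadata keys, non-positive sampling rates,
#' point-id mismatches between the two CSV files, ragged time series and
#' non-numeric cells, naming the offending points.
#'
#' @param dir Bundle directory written by [write_recording_bundle()].
#' @return A `surface_motion_recording`.
#' @export
read_recording_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path))
    stop_dietdx(paste0("missing metadata.yaml in ", dir), "dietdx_bad_bundle")
  meta <- yaml::read_yaml(meta_path)
  missing <- setdiff(required_metadata, names(meta))
  if (length(missing))
    stop_dietdx(paste0("metadata missing keys: ",
                       paste(missing, collapse = ", ")), "dietdx_bad_bundle")
  if (!is.numeric(meta$sampling_rate_hz) || meta$sampling_rate_hz <= 0)
    stop_dietdx("metadata sampling_rate_hz must be a positive number",
                "dietdx_bad_bundle")
  pts <- read.csv(file.path(dir, "points.csv"),
                  colClasses = c(point_id = "character"))
  if (!all(vapply(pts[c("x_mm", "y_mm", "z_mm")], is.numeric, TRUE)))
    stop_dietdx("non-numeric coordinates in points.csv", "dietdx_bad_bundle")
  long <- read.csv(file.path(dir, "displacements.csv"),
                   colClasses = c(point_id = "character"))
  if (!all(vapply(long[c("dx_mm", "dy_mm", "dz_mm")], is.numeric, TRUE)))
    stop_dietdx("non-numeric cells in displacements.csv", "dietdx_bad_bundle")

  cnt <- table(long$point_id)
  absent <- setdiff(pts$point_id, names(cnt))
  extra <- setdiff(names(cnt), pts$point_id)
  if (length(absent) || length(extra))
    stop_dietdx(paste0(
      "point ids inconsistent between points.csv and displacements.csv",
      if (length(absent)) paste0("; missing displacements for: ",
                                 paste(utils::head(absent, 5), collapse = ", ")),
      if (length(extra)) paste0("; unknown points: ",
                                paste(utils::head(extra, 5), collapse = ", "))),
      "dietdx_bad_bundle")
  if (length(unique(cnt)) != 1L)
    stop_dietdx(paste0(
      "ragged time series; offending points: ",
      paste(utils::head(names(cnt)[cnt != stats::median(cnt)], 5),
            collapse = ", ")), "dietdx_bad_bundle")
  n_smp <- unname(cnt[1])
  if (n_smp != meta$n_samples)
    stop_dietdx(sprintf("metadata n_samples (%d) disagrees with data (%d)",
                        meta$n_samples, n_smp), "dietdx_bad_bundle")

  ord <- order(match(long$point_id, pts$point_id), long$t_index)
  long <- long[ord, ]
  shape <- c(n_smp, nrow(pts))
  disp <- list(dx = matrix(long$dx_mm, shape[1], shape[2]),
               dy = matrix(long$dy_mm, shape[1], shape[2]),
               dz = matrix(long$dz_mm, shape[1], shape[2]))
  attr(pts, "height_mm") <- max(pts$z_mm)
  attr(pts, "radius_mm") <- max(sqrt(pts$x_mm^2 + pts$y_mm^2))
  structure(
    list(breast_id = meta$breast_id, side = meta$side, label = meta$label,
         input_frequency = meta$input_frequency_hz,
         sampling_rate = meta$sampling_rate_hz,
         points = pts, disp = disp, seed = meta$seed),
    class = "surface_motion_recording"
  )
}

#' Write / read the cohort manifest
#'
#' @param manifest Manifest data frame from [synth_cohort()].
#' @param path CSV path.
#' @return `path` invisibly; `read_manifest()` returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, colClasses = c(breast_id = "character"))
}

#' Export a per-point frequency map
#'
#' Joins the FoI results with the rest positions for external 3-D viewers
#' (columns `point_id`, `x_mm`, `y_mm`, `z_mm`, `foi_hz`; excluded points
#' have empty `foi_hz`).
#'
#' @param foi FoI data frame from [extract_foi()].
#' @param points Rest point cloud of the same recording.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_map <- function(foi, points, path) {
  m <- merge(points[c("point_id", "x_mm", "y_mm", "z_mm")],
             foi[c("point_id", "foi_hz")], by = "point_id")
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
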