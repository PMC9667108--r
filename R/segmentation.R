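# Surface segmentation: trim the noisy chest-wall and apex fringes, assign
# each retained point to one of 4 radial quadrants x 4 vertical (z) bands,
# and reduce per-point frequencies of interest to per-segment means.

#' Trim the top and bottom height fringes
#'
#' Removes the lowest and highest `fraction` of points by z (nearest-rank
#' convention: exactly `floor(fraction * N)` points are dropped at each end),
#' discarding the noisy zones near the chest wall and the actuator.
#'
#' @param points Point cloud data frame with `point_id` and `z_mm`.
#' @param fraction Fraction in `[0, 0.5)` to drop at each end (default 0.05).
#' @return Character vector of retained `point_id`s.
#' @export
trim_by_height <- function(points, fraction = 0.05) {
  check_number(fraction, "fraction", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  n <- nrow(points)
  k <- floor(fraction * n)
  if (k == 0L) return(points$point_id)
  ord <- order(points$z_mm)
  keep <- ord[(k + 1):(n - k)]
  points$point_id[sort(keep)]
}

#' Assign radial quadrant and z-band segments
#'
#' The radial index comes from the clock angle about the z-axis through the
#' cloud centroid, with quadrant boundaries at the half-hour positions
#' 1:30 / 4:30 / 7:30 / 10:30 (quadrant 0 contains 12 o'clock). Right-breast
#' angles are mirrored so quadrant labels compare anatomically consistent
#' (outer/inner) tissue across sides. The z-band index (0 nearest the chest
#' wall) splits the retained points into four equal-count bands.
#'
#' @param points Trimmed point cloud (`point_id`, `x_mm`, `y_mm`, `z_mm`).
#' @param side `"left"` or `"right"`.
#' @return Data frame `point_id`, `radial` (0--3), `zband` (0--3).
#' @export
assign_segments <- function(points, side) {
  check_side(side)
  if (length(unique(points$z_mm)) < 4L)
    stop_dietdx("fewer than 4 distinct z values: cannot form z-bands",
                "dietdx_degenerate_geometry")
  cx <- mean(points$x_mm); cy <- mean(points$y_mm)
  hrs <- hours_from_xy(points$x_mm - cx, points$y_mm - cy, side)
  radial <- as.integer(floor(((hrs + 1.5) %% 12) / 3))
  zr <- rank(points$z_mm, ties.method = "first")
  zband <- as.integer(floor(4 * (zr - 1) / nrow(points)))
  data.frame(point_id = points$point_id, radial = radial, zband = zband)
}

# Cell-wise means of a per-point value over the 4 x 4 grid.
cell_means <- function(values, assignments) {
  ok <- !is.na(values)
  key <- assignments$zband[ok] * 4L + assignments$radial[ok]  # column-major
  cnts <- matrix(tabulate(key + 1L, nbins = 16L), 4, 4)
  sums <- as.numeric(tapply(values[ok], factor(key, levels = 0:15), sum))
  means <- matrix(ifelse(cnts > 0L, sums / cnts, NA_real_), 4, 4)
  dimnames(means) <- dimnames(cnts) <-
    list(radial = paste0("r", 0:3), zband = paste0("z", 0:3))
  list(mean = means, count = cnts)
}

#' Per-segment mean frequencies of interest for one run
#'
#' Averages the retained frequencies of interest over each of the 16
#' segments. Segments in which every point was excluded are missing
#' (`NA` with count 0).
#'
#' @param foi FoI data frame from [extract_foi()].
#' @param assignments Segment assignments from [assign_segments()]; points
#'   absent from `assignments` (trimmed) are ignored.
#' @param breast_id Identifier stored on the table.
#' @param run_hz Actuation frequency of the run, Hz.
#' @return An object of class `segment_table`: `mean_foi` and `counts`
#'   (4 x 4, radial x zband), `breast_id`, `runs_used`.
#' @export
segment_table <- function(foi, assignments, breast_id = "", run_hz = NA_real_) {
  m <- merge(assignments, foi, by = "point_id")
  vals <- ifelse(m$status == "retained", m$foi_hz, NA_real_)
  cm <- cell_means(vals, m)
  structure(
    list(breast_id = breast_id, mean_foi = cm$mean, counts = cm$count,
         runs_used = run_hz),
    class = "segment_table"
  )
}

#' Per-segment mean dominant frequencies (for run selection)
#'
#' Same reduction as [segment_table()] but over the dominant frequency of
#' every non-degenerate point (retained or not), the quantity whose deviation
#' from the actuation frequency defines an irregular segment.
#'
#' @inheritParams segment_table
#' @return A 4 x 4 matrix of mean dominant frequencies (Hz, `NA` when empty).
#' @export
dominant_segment_means <- function(foi, assignments) {
  m <- merge(assignments, foi, by = "point_id")
  cell_means(m$dominant_hz, m)$mean
}

#' Average segment tables across usable runs
#'
#' Cell-wise unweighted mean over the runs in which the cell is present; a
#' cell is missing only when missing in every run. Counts accumulate across
#' runs.
#'
#' @param tables Non-empty list of `segment_table`s for one breast.
#' @return A `segment_table` with `runs_used` the vector of run frequencies.
#' @export
average_tables <- function(tables) {
  if (length(tables) == 0L)
    stop_dietdx("no usable runs to average", "dietdx_empty_selection")
  stopifnot(all(vapply(tables, inherits, TRUE, "segment_table")))
  sums <- matrix(0, 4, 4); npres <- matrix(0L, 4, 4); cnts <- matrix(0L, 4, 4)
  for (tb in tables) {
    pres <- !is.na(tb$mean_foi)
    sums[pres] <- sums[pres] + tb$mean_foi[pres]
    npres <- npres + pres
    cnts <- cnts + tb$counts
  }
  means <- ifelse(npres > 0L, sums / npres, NA_real_)
  dimnames(means) <- dimnames(cnts) <-
    list(radial = paste0("r", 0:3), zband = paste0("z", 0:3))
  structure(
    list(breast_id = tables[[1]]$breast_id, mean_foi = means, counts = cnts,
         runs_used = unlist(lapply(tables, `[[`, "runs_used"))),
    class = "segment_table"
  )
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %s (runs: %s)\n", x$breast_id,
              paste(x$runs_used, collapse = ", ")))
  print(round(x$mean_foi, 2))
  invisible(x)
}
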