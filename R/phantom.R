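# Synthetic DIET-style surface-vibration phantom.
#
# The phantom stands in for clinical recordings that are access-restricted.
# Each breast is a pendant half-ellipsoid of revolution sampled quasi-uniformly
# on its surface; every reference point vibrates with a primary tone at the
# actuation frequency plus a weaker secondary tone whose frequency over a
# lesion is elevated by sqrt(k_tumor / k_healthy), the square-root stiffness
# scaling of natural frequency.

# Half-ellipsoid of revolution: equatorial radius R, height h = 1.2 R,
# enclosed volume (2/3) pi R^2 h = 0.8 pi R^3.
breast_geometry <- function(volume_cm3) {
  v_mm3 <- volume_cm3 * 1000
  radius <- (v_mm3 / (0.8 * pi))^(1 / 3)
  list(radius_mm = radius, height_mm = 1.2 * radius)
}

# Clock convention: 12 o'clock is +y (superior); the clock runs clockwise
# when facing the patient's left breast, mirrored for the right.
clock_direction <- function(hours, side) {
  alpha <- 2 * pi * hours / 12
  sx <- if (side == "left") sin(alpha) else -sin(alpha)
  cbind(x = sx, y = cos(alpha))
}

hours_from_xy <- function(x, y, side) {
  a <- if (side == "left") atan2(x, y) else atan2(-x, y)
  (a %% (2 * pi)) * 12 / (2 * pi)
}

#' Sample a surface point cloud for one breast
#'
#' Quasi-uniform sampling of a pendant half-ellipsoid of revolution whose
#' enclosed volume equals the breast volume (aspect ratio fixed at
#' height = 1.2 x equatorial radius). `z = 0` is the chest-wall rim and
#' `z = max` the apex.
#'
#' @param breast A [breast_spec()].
#' @param seed Integer seed; identical seeds give bit-identical clouds.
#' @return A data frame with columns `point_id`, `x_mm`, `y_mm`, `z_mm` and
#'   attributes `radius_mm`, `height_mm`.
#' @export
surface_point_cloud <- function(breast, seed = 1L) {
  stopifnot(inherits(breast, "breast_spec"))
  geom <- breast_geometry(breast$volume_cm3)
  n <- breast$n_points
  pts <- with_seed_(seed, {
    # uniform on the unit upper hemisphere (z uniform gives uniform area),
    # then anisotropic scaling -> quasi-uniform on the spheroid
    u <- runif(n)                 # z / h
    lam <- runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - u^2))
    data.frame(
      point_id = sprintf("p%05d", seq_len(n)),
      x_mm = geom$radius_mm * s * cos(lam),
      y_mm = geom$radius_mm * s * sin(lam),
      z_mm = geom$height_mm * u
    )
  })
  attr(pts, "radius_mm") <- geom$radius_mm
  attr(pts, "height_mm") <- geom$height_mm
  pts
}

#' Surface footprint weight of a tumor
#'
#' Weight 1 for surface points within `diameter/2` of the lesion's surface
#' projection (at its clock position and depth-determined height), cosine
#' falloff to 0 at one diameter, 0 beyond; all zeros when no tumor is present.
#' Distance is the 3-D chord distance to the projection centre, a monotone
#' proxy for the surface geodesic on this convex shape.
#'
#' @param points Point cloud from [surface_point_cloud()].
#' @param tumor A [tumor_spec()].
#' @param side `"left"` or `"right"` (fixes the clock handedness).
#' @return Numeric weights in `[0, 1]`, one per point.
#' @export
tumor_weight <- function(points, tumor, side = "left") {
  stopifnot(inherits(tumor, "tumor_spec"))
  check_side(side)
  if (!tumor$present) return(rep(0, nrow(points)))
  ctr <- tumor_surface_centre(points, tumor, side)
  d <- sqrt((points$x_mm - ctr[1])^2 + (points$y_mm - ctr[2])^2 +
              (points$z_mm - ctr[3])^2)
  r <- tumor$diameter_mm / 2
  w <- ifelse(d <= r, 1,
              ifelse(d >= 2 * r, 0, 0.5 * (1 + cos(pi * (d - r) / r))))
  w
}

# Surface projection centre of the lesion: clock angle + height h - depth
# (clamped to the surface), radial offset on the ellipsoid at that height.
tumor_surface_centre <- function(points, tumor, side) {
  h <- attr(points, "height_mm") %||% max(points$z_mm)
  R <- attr(points, "radius_mm") %||%
    max(sqrt(points$x_mm^2 + points$y_mm^2))
  zc <- min(max(h - tumor$depth_mm, 0), h)
  sc <- R * sqrt(max(0, 1 - (zc / h)^2))
  dir <- clock_direction(tumor$clock_position, side)
  c(sc * dir[1, "x"], sc * dir[1, "y"], zc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize one surface-motion recording
#'
#' Per point `p` the displacement is a primary sinusoid at the actuation
#' frequency (amplitude tapering with height) plus a secondary sinusoid at
#' `r(p)` times the actuation frequency with relative amplitude
#' `secondary_mag_fraction`, where
#' `r(p) = healthy_secondary_ratio * sqrt(1 + w(p) * (stiffness_ratio - 1))`
#' and `w(p)` is the tumor footprint weight. Motion is carried by a per-point
#' unit vector along the actuation (z) axis with at most 10% off-axis jitter.
#' Gaussian noise of sd `noise_sd` is added to every component, multiplied by
#' `boundary_noise_gain` within the outer 5% z-ranges (chest wall and apex).
#'
#' @param breast A [breast_spec()].
#' @param params A [recording_params()].
#' @param material A [material_spec()].
#' @param tumor A [tumor_spec()]; defaults to no tumor.
#' @param cloud Optional precomputed point cloud (so several runs can share
#'   one rest geometry); defaults to a cloud seeded from `params$seed`.
#' @return An object of class `surface_motion_recording`: breast metadata,
#'   the rest point cloud, and displacement component matrices
#'   (`n_samples x n_points`) in `disp$dx`, `disp$dy`, `disp$dz`.
#' @export
synth_recording <- function(breast, params, material,
                            tumor = tumor_spec(present = FALSE),
                            cloud = NULL) {
  stopifnot(inherits(breast, "breast_spec"),
            inherits(params, "recording_params"),
            inherits(material, "material_spec"))
  check_recording_feasible(params, material)
  if (is.null(cloud))
    cloud <- surface_point_cloud(breast, seed = child_seed(params$seed, 1L))
  n_pts <- nrow(cloud)
  n_smp <- round(params$duration * params$sampling_rate)
  h <- attr(cloud, "height_mm") %||% max(cloud$z_mm)

  w <- tumor_weight(cloud, tumor, breast$side)
  ratio <- material$healthy_secondary_ratio *
    sqrt(1 + w * (material$stiffness_ratio - 1))
  f1 <- params$input_frequency
  f2 <- ratio * f1

  amp <- 1 - 0.5 * cloud$z_mm / h          # primary amplitude taper, mm
  zfrac <- cloud$z_mm / h
  gain <- ifelse(zfrac < 0.05 | zfrac > 0.95, params$boundary_noise_gain, 1)
  tt <- (seq_len(n_smp) - 1) / params$sampling_rate

  disp <- with_seed_(child_seed(params$seed, 2L), {
    phi <- runif(n_pts, 0, 2 * pi)
    psi <- runif(n_pts, 0, 2 * pi)
    jx <- runif(n_pts, -0.1, 0.1)
    jy <- runif(n_pts, -0.1, 0.1)
    nrm <- sqrt(jx^2 + jy^2 + 1)
    ux <- jx / nrm; uy <- jy / nrm; uz <- 1 / nrm

    # n_smp x n_pts phase matrices (column-major: rep(..., each = n_smp))
    p1 <- outer(2 * pi * f1 * tt, rep(1, n_pts)) +
      rep(phi, each = n_smp)
    p2 <- outer(tt, 2 * pi * f2) + rep(psi, each = n_smp)
    s <- (sin(p1) + material$secondary_mag_fraction * sin(p2)) *
      rep(amp, each = n_smp)
    gsd <- rep(gain * params$noise_sd, each = n_smp)
    list(
      dx = s * rep(ux, each = n_smp) + rnorm(n_smp * n_pts) * gsd,
      dy = s * rep(uy, each = n_smp) + rnorm(n_smp * n_pts) * gsd,
      dz = s * rep(uz, each = n_smp) + rnorm(n_smp * n_pts) * gsd
    )
  })
  for (k in seq_along(disp)) dim(disp[[k]]) <- c(n_smp, n_pts)

  structure(
    list(breast_id = breast$breast_id, side = breast$side,
         label = breast$label,
         input_frequency = params$input_frequency,
         sampling_rate = params$sampling_rate,
         points = cloud, disp = disp, seed = params$seed),
    class = "surface_motion_recording"
  )
}

#' @export
print.surface_motion_recording <- function(x, ...) {
  cat(sprintf(
    "<surface_motion_recording> %s (%s, %s)\n  %d points, %d samples at %g Hz, actuation %g Hz\n",
    x$breast_id, x$side, x$label, nrow(x$points), nrow(x$disp$dx),
    x$sampling_rate, x$input_frequency))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' One recording per breast per actuation frequency, with a manifest of
#' breast-level ground truth. Cancerous breasts carry exactly one tumor with
#' stiffness ratio drawn uniformly from `stiffness_range`. Breast volumes are
#' drawn from the clinical volume spread (239.5--1057 cm^3) and, under
#' `tumor_extent = "table1"`, tumor diameters from the clinical 7--48 mm
#' range. `tumor_extent = "segment"` instead sizes each lesion's footprint to
#' cover the surface segment containing its centre, guaranteeing at least one
#' of the 16 segments sees the full sqrt(stiffness-ratio) secondary-frequency
#' elevation (a factor of at least 2 for stiffness ratios of 4 and above).
#'
#' @param n_healthy,n_cancerous Cohort sizes (non-negative).
#' @param input_frequencies Actuation frequencies, Hz (non-empty).
#' @param seed Integer master seed; all randomness derives from it.
#' @param material Base [material_spec()]; per-breast stiffness ratios are
#'   drawn from `stiffness_range` for cancerous breasts (1 for healthy).
#' @param stiffness_range Range of the tumor stiffness ratio, default 4--10.
#' @param tumor_extent `"table1"` (clinical diameter range) or `"segment"`.
#' @param n_points,sampling_rate,duration,noise_sd,boundary_noise_gain
#'   Recording parameters shared across the cohort.
#' @param volume_range_cm3 Breast-volume draw range, cm^3.
#' @return A list with `recordings` (list of `surface_motion_recording`) and
#'   `manifest` (one row per breast: id, side, label, tumor ground truth).
#' @export
synth_cohort <- function(n_healthy = 13, n_cancerous = 13,
                         input_frequencies = 20:23, seed = 1L,
                         material = material_spec(),
                         stiffness_range = c(4, 10),
                         tumor_extent = c("table1", "segment"),
                         n_points = 1000, sampling_rate = 500, duration = 1,
                         noise_sd = 0.02, boundary_noise_gain = 3,
                         volume_range_cm3 = c(239.5, 1057)) {
  check_number(n_healthy, "n_healthy", lower = 0)
  check_number(n_cancerous, "n_cancerous", lower = 0)
  if (length(input_frequencies) < 1L)
    stop_invalid("`input_frequencies` must be non-empty")
  tumor_extent <- match.arg(tumor_extent)
  n_total <- n_healthy + n_cancerous

  draws <- with_seed_(child_seed(seed, 0L), {
    list(volumes = runif(n_total, volume_range_cm3[1], volume_range_cm3[2]),
         sides = sample(c("left", "right"), n_total, replace = TRUE),
         sr = runif(n_total, stiffness_range[1], stiffness_range[2]),
         clock = runif(n_total, 0, 12),
         diam = runif(n_total, 7, 48),
         zband_target = sample(1:2, n_total, replace = TRUE),
         quadrant = sample(0:3, n_total, replace = TRUE),
         clock_jitter = runif(n_total, -0.75, 0.75))
  })

  labels <- c(rep("healthy", n_healthy), rep("cancerous", n_cancerous))
  ids <- c(sprintf("H%02d", seq_len(n_healthy)),
           sprintf("C%02d", seq_len(n_cancerous)))

  recordings <- list()
  manifest <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    br <- breast_spec(ids[i], side = draws$sides[i],
                      volume_cm3 = draws$volumes[i], n_points = n_points,
                      label = labels[i])
    cloud <- surface_point_cloud(br, seed = child_seed(seed, 100L + i))
    geom <- list(radius_mm = attr(cloud, "radius_mm"),
                 height_mm = attr(cloud, "height_mm"))

    if (labels[i] == "cancerous") {
      if (tumor_extent == "table1") {
        depth <- geom$height_mm * (1 - (draws$zband_target[i] + 0.5) / 4)
        tm <- tumor_spec(TRUE, clock_position = draws$clock[i],
                         depth_mm = depth, diameter_mm = draws$diam[i])
      } else {
        # centre the lesion inside one quadrant so its covering footprint
        # stays segment-scale instead of straddling a quadrant boundary
        clock_c <- (3 * draws$quadrant[i] + draws$clock_jitter[i]) %% 12
        tm <- segment_scale_tumor(cloud, br$side, clock_c,
                                  draws$zband_target[i])
      }
      mat <- material_spec(stiffness_ratio = draws$sr[i],
                           healthy_secondary_ratio = material$healthy_secondary_ratio,
                           secondary_mag_fraction = material$secondary_mag_fraction)
    } else {
      tm <- tumor_spec(present = FALSE)
      mat <- material_spec(stiffness_ratio = 1,
                           healthy_secondary_ratio = material$healthy_secondary_ratio,
                           secondary_mag_fraction = material$secondary_mag_fraction)
    }

    for (f in input_frequencies) {
      rp <- recording_params(input_frequency = f,
                             sampling_rate = sampling_rate,
                             duration = duration, noise_sd = noise_sd,
                             boundary_noise_gain = boundary_noise_gain,
                             seed = child_seed(seed, 1000L * i + round(f)))
      key <- sprintf("%s_%gHz", ids[i], f)
      recordings[[key]] <- synth_recording(br, rp, mat, tm, cloud = cloud)
    }
    manifest[[i]] <- data.frame(
      breast_id = ids[i], side = br$side, label = labels[i],
      tumor_clock = if (tm$present) tm$clock_position else NA_real_,
      tumor_diameter_mm = if (tm$present) tm$diameter_mm else NA_real_,
      tumor_depth_mm = if (tm$present) tm$depth_mm else NA_real_,
      volume_cm3 = br$volume_cm3,
      stiffness_ratio = if (tm$present) draws$sr[i] else 1
    )
  }
  list(recordings = recordings, manifest = do.call(rbind, manifest))
}

# A tumor whose weight-1 footprint covers the whole radial x z segment that
# contains its surface centre, placed at the centre height of `zband_target`
# (bands counted from the chest wall, 0-based).
segment_scale_tumor <- function(cloud, side, clock_position, zband_target) {
  h <- attr(cloud, "height_mm")
  zc_frac <- (zband_target + 0.5) / 4
  depth <- h * (1 - zc_frac)
  tm0 <- tumor_spec(TRUE, clock_position = clock_position,
                    depth_mm = depth, diameter_mm = 1)
  ctr <- tumor_surface_centre(cloud, tm0, side)

  hrs <- hours_from_xy(cloud$x_mm, cloud$y_mm, side)
  radial <- floor(((hrs + 1.5) %% 12) / 3)
  zr <- rank(cloud$z_mm, ties.method = "first")
  zband <- floor(4 * (zr - 1) / nrow(cloud))
  ctr_radial <- floor(((clock_position %% 12 + 1.5) %% 12) / 3)
  in_seg <- radial == ctr_radial & zband == zband_target
  d <- sqrt((cloud$x_mm - ctr[1])^2 + (cloud$y_mm - ctr[2])^2 +
              (cloud$z_mm - ctr[3])^2)
  diam <- 2 * max(d[in_seg])
  tumor_spec(TRUE, clock_position = clock_position, depth_mm = depth,
             diameter_mm = diam)
}
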