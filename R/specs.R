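#' Material specification for the surface-vibration phantom
#'
#' Describes the mechanical contrast the phantom synthesizes. Tumor tissue is
#' 4--10 times stiffer than healthy tissue, and natural frequency scales with
#' the square root of stiffness, so the secondary spectral component over a
#' lesion sits at `sqrt(stiffness_ratio)` times its healthy-tissue frequency
#' (a factor of 2--3.16 across the physiological stiffness range).
#'
#' @param stiffness_ratio Tumor-to-healthy stiffness ratio, dimensionless,
#'   `>= 1`. 1 means no mechanical contrast (a healthy-tissue phantom).
#' @param healthy_secondary_ratio Ratio of the healthy-tissue secondary
#'   frequency to the actuation frequency, `> 1`. Default 1.5.
#' @param secondary_mag_fraction Amplitude of the secondary tone relative to
#'   the primary actuation response, in `(0, 1]`. The default 0.3 sits
#'   comfortably above the 0.15 retention threshold of the frequency-of-
#'   interest rule; values below 0.15 produce the "filtered out" regime.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(stiffness_ratio = 4,
                          healthy_secondary_ratio = 1.5,
                          secondary_mag_fraction = 0.3) {
  check_number(stiffness_ratio, "stiffness_ratio", lower = 1)
  check_number(healthy_secondary_ratio, "healthy_secondary_ratio",
               lower = 1, strict_lower = TRUE)
  check_number(secondary_mag_fraction, "secondary_mag_fraction",
               lower = 0, upper = 1, strict_lower = TRUE)
  structure(
    list(stiffness_ratio = stiffness_ratio,
         healthy_secondary_ratio = healthy_secondary_ratio,
         secondary_mag_fraction = secondary_mag_fraction),
    class = "material_spec"
  )
}

#' Tumor specification
#'
#' Lesion position uses the clinical clock convention: hours in `[0, 12)`
#' with 12 o'clock superior, plus a depth below the apex along the
#' apex-to-chest axis and a diameter. Hours wrap modulo 12.
#'
#' @param present Logical; `FALSE` gives a tumor-free breast.
#' @param clock_position Hours in `[0, 12)` (wrapped modulo 12).
#' @param depth_mm Depth of the lesion centre below the apex, mm.
#' @param diameter_mm Lesion diameter, mm, `> 0` when present.
#' @return An object of class `tumor_spec`.
#' @export
tumor_spec <- function(present = TRUE, clock_position = 0,
                       depth_mm = 30, diameter_mm = 20) {
  if (!is.logical(present) || length(present) != 1L || is.na(present))
    stop_invalid("`present` must be TRUE or FALSE")
  if (present) {
    check_number(clock_position, "clock_position")
    check_number(depth_mm, "depth_mm", lower = 0)
    check_number(diameter_mm, "diameter_mm", lower = 0, strict_lower = TRUE)
    clock_position <- clock_position %% 12
  }
  structure(
    list(present = present,
         clock_position = if (present) clock_position else NA_real_,
         depth_mm = if (present) depth_mm else NA_real_,
         diameter_mm = if (present) diameter_mm else NA_real_),
    class = "tumor_spec"
  )
}

#' Breast specification
#'
#' @param breast_id Identifier string.
#' @param side `"left"` or `"right"`.
#' @param volume_cm3 Breast volume in cm^3. The default plausible range
#'   200--1100 cm^3 covers the clinical spread of pendant breast volumes.
#' @param n_points Number of surface reference points, `>= 16` so every one
#'   of the 16 segments is reachable.
#' @param label `"healthy"` or `"cancerous"`.
#' @param volume_range Permitted `volume_cm3` range (override to relax).
#' @return An object of class `breast_spec`.
#' @export
breast_spec <- function(breast_id, side = "left", volume_cm3 = 500,
                        n_points = 1000, label = "healthy",
                        volume_range = c(200, 1100)) {
  if (!is.character(breast_id) || length(breast_id) != 1L || !nzchar(breast_id))
    stop_invalid("`breast_id` must be a non-empty string")
  check_side(side)
  check_number(volume_cm3, "volume_cm3",
               lower = volume_range[1], upper = volume_range[2])
  check_number(n_points, "n_points", lower = 16)
  if (n_points != round(n_points)) stop_invalid("`n_points` must be an integer")
  if (!label %in% c("healthy", "cancerous"))
    stop_invalid("`label` must be \"healthy\" or \"cancerous\"")
  structure(
    list(breast_id = breast_id, side = side, volume_cm3 = volume_cm3,
         n_points = as.integer(n_points), label = label),
    class = "breast_spec"
  )
}

#' Recording parameters
#'
#' Sampling must satisfy Nyquist for the highest tone the phantom can place:
#' `sampling_rate > 2 * healthy_secondary_ratio * sqrt(stiffness_ratio) *
#' input_frequency`, and the run must be long enough that the primary and
#' secondary tones are at least two spectral bins apart. Both are enforced
#' when a recording is synthesized.
#'
#' @param input_frequency Actuation frequency, Hz.
#' @param sampling_rate Samples per second, Hz.
#' @param duration Run length, seconds.
#' @param noise_sd Gaussian displacement-noise standard deviation (mm).
#' @param boundary_noise_gain Multiplier (`>= 1`) applied to the noise inside
#'   the outer 5% z-ranges, emulating the noisy chest-wall and actuator zones.
#' @param seed Integer seed for the recording's randomness.
#' @return An object of class `recording_params`.
#' @export
recording_params <- function(input_frequency = 23, sampling_rate = 500,
                             duration = 1, noise_sd = 0.02,
                             boundary_noise_gain = 3, seed = 1L) {
  check_number(input_frequency, "input_frequency", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(boundary_noise_gain, "boundary_noise_gain", lower = 1)
  check_number(seed, "seed")
  structure(
    list(input_frequency = input_frequency, sampling_rate = sampling_rate,
         duration = duration, noise_sd = noise_sd,
         boundary_noise_gain = boundary_noise_gain, seed = as.integer(seed)),
    class = "recording_params"
  )
}

# Nyquist + bin-separation preconditions for one recording.
check_recording_feasible <- function(params, material) {
  f_max <- material$healthy_secondary_ratio * sqrt(material$stiffness_ratio) *
    params$input_frequency
  if (params$sampling_rate <= 2 * f_max)
    stop_invalid(sprintf(
      "sampling_rate %g Hz violates Nyquist for the highest synthesized tone %g Hz",
      params$sampling_rate, f_max))
  df <- 1 / params$duration  # spectral resolution, Hz
  sep <- (material$healthy_secondary_ratio - 1) * params$input_frequency
  if (sep < 2 * df)
    stop_invalid(sprintf(
      "duration %g s gives %g Hz resolution; primary and secondary tones only %g Hz apart (need >= 2 bins)",
      params$duration, df, sep))
  invisible(TRUE)
}
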