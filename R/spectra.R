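# Per-point spectral analysis: reduce each reference point's 3-D displacement
# trajectory to a scalar series, Fourier-transform it, and select the
# "frequency of interest" (FoI):
#   * if the dominant peak differs from the actuation frequency, the point is
#     irregular and the dominant frequency itself is the FoI;
#   * otherwise the second-dominant peak is the FoI, provided its magnitude is
#     at least 15% of the dominant's — weaker second peaks are discarded.

#' Project a 3-D trajectory onto its principal axis
#'
#' Mean-removes the trajectory and projects it onto its first principal
#' axis, giving the signed scalar motion that carries most variance. The
#' output has zero mean. Constant (zero-variance) trajectories yield a zero
#' series with attribute `degenerate = TRUE`; such points are later excluded.
#'
#' @param trajectory Numeric matrix, `n_samples x 3`, with `n_samples >= 8`.
#' @return Numeric vector of length `n_samples` with attribute `degenerate`.
#' @export
project_scalar <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) < 8L || ncol(trajectory) != 3L)
    stop_invalid("`trajectory` must be an n x 3 matrix with n >= 8")
  x <- sweep(trajectory, 2, colMeans(trajectory))
  cv <- crossprod(x) / nrow(x)
  tot <- sum(diag(cv))
  if (!is.finite(tot) || tot < 1e-24) {
    out <- numeric(nrow(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  v <- principal_axis(cv[1, 1], cv[2, 2], cv[3, 3],
                      cv[1, 2], cv[1, 3], cv[2, 3])
  out <- drop(x %*% v)
  out <- out - mean(out)
  attr(out, "degenerate") <- FALSE
  out
}

# Leading eigenvector of one or many 3x3 covariance matrices by power
# iteration (vectorised over points; entries are equal-length vectors).
# Sign fixed so the largest-magnitude component is positive.
principal_axis <- function(cxx, cyy, czz, cxy, cxz, cyz) {
  n <- length(cxx)
  vx <- rep(1 / sqrt(3), n); vy <- vx; vz <- vx
  for (it in 1:60) {
    wx <- cxx * vx + cxy * vy + cxz * vz
    wy <- cxy * vx + cyy * vy + cyz * vz
    wz <- cxz * vx + cyz * vy + czz * vz
    nrm <- sqrt(wx^2 + wy^2 + wz^2)
    nrm[nrm < 1e-300] <- 1
    vx <- wx / nrm; vy <- wy / nrm; vz <- wz / nrm
  }
  sgn <- ifelse(abs(vx) >= abs(vy) & abs(vx) >= abs(vz), sign(vx),
                ifelse(abs(vy) >= abs(vz), sign(vy), sign(vz)))
  sgn[sgn == 0] <- 1
  if (n == 1L) c(vx, vy, vz) * sgn
  else list(vx = vx * sgn, vy = vy * sgn, vz = vz * sgn)
}

#' One-sided magnitude spectrum of a scalar series
#'
#' Discrete Fourier transform with the DC bin removed and, for even lengths,
#' the Nyquist bin excluded (rigid-body drift and aliasing guards).
#' Frequency resolution is `sampling_rate / length(series)`.
#'
#' @param series Numeric vector, length `>= 8`.
#' @param sampling_rate Samples per second, `> 0`.
#' @return A data frame of class `point_spectrum` with strictly increasing
#'   `frequency` (Hz, first bin `> 0`) and non-negative `magnitude`, plus a
#'   `bin_width` attribute.
#' @export
compute_spectrum <- function(series, sampling_rate) {
  if (length(series) < 8L) stop_invalid("`series` must have length >= 8")
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  n <- length(series)
  kmax <- floor((n - 1) / 2)          # excludes DC and (even n) Nyquist
  mags <- 2 * Mod(fft(series))[2:(kmax + 1)] / n
  out <- data.frame(frequency = (1:kmax) * sampling_rate / n,
                    magnitude = mags)
  class(out) <- c("point_spectrum", "data.frame")
  attr(out, "bin_width") <- sampling_rate / n
  out
}

#' Rank the local spectral peaks by magnitude
#'
#' Local maxima sorted by descending magnitude; once a peak is selected, bins
#' within `exclusion_halfwidth` of it become ineligible (so leakage shoulders
#' of a strong peak are not reported as independent peaks). Ties are broken
#' toward lower frequency. A flat spectrum has no peaks.
#'
#' @param spectrum A `point_spectrum` from [compute_spectrum()].
#' @param exclusion_halfwidth Exclusion half-width around a selected peak, in
#'   bins (default 2).
#' @return Data frame with columns `frequency`, `magnitude`, `bin`, ordered
#'   by rank; zero rows when no local maximum exists.
#' @export
rank_peaks <- function(spectrum, exclusion_halfwidth = 2) {
  m <- spectrum$magnitude
  if (length(m) == 0L) stop_invalid("`spectrum` must be non-empty")
  cand <- which(local_peak_mask(m))
  cand <- cand[order(-m[cand], cand)]
  chosen <- integer(0)
  for (i in cand) {
    if (!length(chosen) || all(abs(chosen - i) > exclusion_halfwidth))
      chosen <- c(chosen, i)
  }
  out <- data.frame(frequency = spectrum$frequency[chosen],
                    magnitude = m[chosen], bin = chosen)
  attr(out, "bin_width") <- attr(spectrum, "bin_width")
  out
}

# Local maxima of a magnitude vector: interior bins strictly above the left
# neighbour and at least the right neighbour (plateaus collapse to their
# low-frequency edge); endpoints count when above their single neighbour.
local_peak_mask <- function(m) {
  n <- length(m)
  if (n == 1L) return(m > 0)
  up <- c(TRUE, m[-1] > m[-n])
  dn <- c(m[-n] >= m[-1], TRUE)
  mask <- up & dn
  mask[1] <- m[1] > m[2]
  mask[n] <- m[n] > m[n - 1]
  mask & (m > 0)
}

#' Select the frequency of interest from ranked peaks
#'
#' Implements the FoI decision rule. When the dominant peak differs from the
#' actuation frequency by more than `match_tolerance` the point is irregular
#' and the dominant frequency is used directly. Otherwise the second-dominant
#' peak is used, provided its magnitude is at least
#' `magnitude_threshold` (default 15%) of the dominant magnitude; points
#' failing that are excluded as having no sufficiently dominant second peak.
#'
#' @param peaks Ranked peaks from [rank_peaks()].
#' @param input_frequency Actuation frequency of the run, Hz.
#' @param magnitude_threshold Retention threshold for the second peak's
#'   relative magnitude, default 0.15.
#' @param match_tolerance Hz within which the dominant peak counts as equal
#'   to the actuation frequency; default `max(0.5, one bin)`.
#' @return A list of class `foi_result`: `status` ("retained"/"excluded"),
#'   `branch` ("irregular_dominant"/"second_dominant" or `NA`), `foi_hz`,
#'   `dominant_hz`, `dominant_mag`, `second_hz`, `second_mag`, `reason`.
#' @export
frequency_of_interest <- function(peaks, input_frequency,
                                  magnitude_threshold = 0.15,
                                  match_tolerance = NULL) {
  check_number(input_frequency, "input_frequency", lower = 0,
               strict_lower = TRUE)
  bw <- attr(peaks, "bin_width") %||% 0
  if (is.null(match_tolerance)) match_tolerance <- max(0.5, bw)
  res <- list(status = "excluded", branch = NA_character_,
              foi_hz = NA_real_, dominant_hz = NA_real_,
              dominant_mag = NA_real_, second_hz = NA_real_,
              second_mag = NA_real_, reason = NA_character_)
  if (nrow(peaks) == 0L) {
    res$reason <- "degenerate"
    class(res) <- "foi_result"
    return(res)
  }
  res$dominant_hz <- peaks$frequency[1]
  res$dominant_mag <- peaks$magnitude[1]
  if (nrow(peaks) >= 2L) {
    res$second_hz <- peaks$frequency[2]
    res$second_mag <- peaks$magnitude[2]
  }
  if (abs(res$dominant_hz - input_frequency) > match_tolerance) {
    res$status <- "retained"
    res$branch <- "irregular_dominant"
    res$foi_hz <- res$dominant_hz
  } else if (!is.na(res$second_mag) &&
             res$second_mag >= magnitude_threshold * res$dominant_mag) {
    res$status <- "retained"
    res$branch <- "second_dominant"
    res$foi_hz <- res$second_hz
  } else {
    res$reason <- "low_second"
  }
  class(res) <- "foi_result"
  res
}

#' Extract frequencies of interest for every point of a recording
#'
#' Vectorised pipeline equivalent of [project_scalar()] +
#' [compute_spectrum()] + [rank_peaks()] + [frequency_of_interest()] applied
#' to each reference point.
#'
#' @param recording A `surface_motion_recording`.
#' @param magnitude_threshold,match_tolerance,exclusion_halfwidth As in the
#'   per-point functions.
#' @return Data frame with one row per point: `point_id`, `status`, `branch`,
#'   `foi_hz`, `dominant_hz`, `dominant_mag`, `second_hz`, `second_mag`,
#'   `reason`.
#' @export
extract_foi <- function(recording, magnitude_threshold = 0.15,
                        match_tolerance = NULL, exclusion_halfwidth = 2) {
  stopifnot(inherits(recording, "surface_motion_recording"))
  dx <- recording$disp$dx; dy <- recording$disp$dy; dz <- recording$disp$dz
  n <- nrow(dx); p <- ncol(dx)
  fs <- recording$sampling_rate
  bw <- fs / n
  if (is.null(match_tolerance)) match_tolerance <- max(0.5, bw)

  dx <- sweep(dx, 2, colMeans(dx)); dy <- sweep(dy, 2, colMeans(dy))
  dz <- sweep(dz, 2, colMeans(dz))
  cxx <- colSums(dx^2) / n; cyy <- colSums(dy^2) / n; czz <- colSums(dz^2) / n
  cxy <- colSums(dx * dy) / n; cxz <- colSums(dx * dz) / n
  cyz <- colSums(dy * dz) / n
  degen <- (cxx + cyy + czz) < 1e-24
  v <- principal_axis(cxx, cyy, czz, cxy, cxz, cyz)
  s <- dx * rep(v$vx, each = n) + dy * rep(v$vy, each = n) +
    dz * rep(v$vz, each = n)
  s <- sweep(s, 2, colMeans(s))

  kmax <- floor((n - 1) / 2)
  mag <- 2 * Mod(mvfft(s))[2:(kmax + 1), , drop = FALSE] / n
  freqs <- (1:kmax) * bw

  # vectorised dominant / second-dominant peak search
  pk <- apply_peak_mask(mag)
  has_peak <- colSums(pk) > 0L
  mneg <- ifelse(pk, mag, -Inf)
  dom <- max.col(t(mneg), ties.method = "first")
  # bins within the exclusion half-width of the dominant become ineligible
  for (off in -exclusion_halfwidth:exclusion_halfwidth) {
    rows <- pmin(pmax(dom + off, 1L), kmax)
    mneg[cbind(rows, seq_len(p))] <- -Inf
  }
  sec <- max.col(t(mneg), ties.method = "first")
  sec_ok <- is.finite(mneg[cbind(sec, seq_len(p))])

  dom_f <- freqs[dom]; dom_m <- mag[cbind(dom, seq_len(p))]
  sec_f <- ifelse(sec_ok, freqs[sec], NA_real_)
  sec_m <- ifelse(sec_ok, mag[cbind(sec, seq_len(p))], NA_real_)

  irregular <- abs(dom_f - recording$input_frequency) > match_tolerance
  second_good <- sec_ok & sec_m >= magnitude_threshold * dom_m
  usable <- has_peak & !degen

  status <- ifelse(usable & (irregular | second_good), "retained", "excluded")
  branch <- ifelse(status == "retained",
                   ifelse(irregular, "irregular_dominant", "second_dominant"),
                   NA_character_)
  foi <- ifelse(status == "retained",
                ifelse(irregular, dom_f, sec_f), NA_real_)
  reason <- ifelse(status == "retained", NA_character_,
                   ifelse(!usable, "degenerate", "low_second"))

  data.frame(
    point_id = recording$points$point_id,
    status = status, branch = branch, foi_hz = foi,
    dominant_hz = ifelse(usable, dom_f, NA_real_),
    dominant_mag = ifelse(usable, dom_m, NA_real_),
    second_hz = ifelse(usable, sec_f, NA_real_),
    second_mag = ifelse(usable, sec_m, NA_real_),
    reason = reason
  )
}

# Column-wise local-peak mask for a magnitude matrix (bins x points),
# matching local_peak_mask() on each column.
apply_peak_mask <- function(mag) {
  k <- nrow(mag)
  up <- rbind(TRUE, mag[-1, , drop = FALSE] > mag[-k, , drop = FALSE])
  dn <- rbind(mag[-k, , drop = FALSE] >= mag[-1, , drop = FALSE], TRUE)
  mask <- up & dn
  mask[1, ] <- mag[1, ] > mag[2, ]
  mask[k, ] <- mag[k, ] > mag[k - 1, ]
  mask & (mag > 0)
}

#' Select usable actuation-frequency runs
#'
#' A segment is irregular when its mean dominant frequency differs from the
#' run's actuation frequency by more than `irregular_hz` (default 2 Hz); a
#' run is usable when fewer than `max_irregular_fraction` (default 10%) of
#' its segments are irregular.
#'
#' @param segment_dominant_means Named list (one element per run) of 4 x 4
#'   matrices of segment-mean dominant frequencies (Hz, `NA` when empty).
#' @param input_frequencies Actuation frequency of each run, Hz.
#' @param irregular_hz Segment irregularity threshold, Hz.
#' @param max_irregular_fraction Run rejection threshold (strict `<` retains).
#' @return Data frame with one row per run: `input_frequency`, `n_segments`,
#'   `n_irregular`, `irregular_fraction`, `retained`.
#' @export
select_usable_runs <- function(segment_dominant_means, input_frequencies,
                               irregular_hz = 2,
                               max_irregular_fraction = 0.10) {
  if (length(segment_dominant_means) != length(input_frequencies))
    stop_invalid("one segment-mean table is required per run")
  rows <- lapply(seq_along(input_frequencies), function(i) {
    m <- segment_dominant_means[[i]]
    ok <- !is.na(m)
    irr <- abs(m[ok] - input_frequencies[i]) > irregular_hz
    frac <- if (any(ok)) mean(irr) else NA_real_
    data.frame(input_frequency = input_frequencies[i],
               n_segments = sum(ok), n_irregular = sum(irr),
               irregular_fraction = frac,
               retained = !is.na(frac) && frac < max_irregular_fraction)
  })
  out <- do.call(rbind, rows)
  if (!any(out$retained))
    stop_dietdx(paste0(
      "no usable runs: irregular-segment fractions ",
      paste(sprintf("%g Hz: %.3f", out$input_frequency,
                    out$irregular_fraction), collapse = ", ")),
      "dietdx_empty_selection")
  out
}
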