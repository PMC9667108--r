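# Shared fixtures, built in code. Cohorts are cached per session because the
# acceptance checks reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full-size conditioned cohort: 13 + 13, runs 20-23 Hz, segment-scale lesions.
acceptance_cohort <- function() {
  cached("acceptance_cohort", {
    co <- synth_cohort(n_healthy = 13, n_cancerous = 13,
                       input_frequencies = 20:23, seed = 42,
                       tumor_extent = "segment")
    seg <- cohort_segment_tables(co$recordings)
    list(manifest = co$manifest, tables = seg$tables,
         labels = co$manifest[c("breast_id", "label")])
  })
}

# Null cohort: no mechanical contrast anywhere (stiffness ratio 1).
null_cohort <- function() {
  cached("null_cohort", {
    co <- synth_cohort(n_healthy = 13, n_cancerous = 13,
                       input_frequencies = 20:23, seed = 42,
                       stiffness_range = c(1, 1))
    seg <- cohort_segment_tables(co$recordings)
    list(manifest = co$manifest, tables = seg$tables,
         labels = co$manifest[c("breast_id", "label")])
  })
}

# Small noise-free cancerous recording with a lesion confined near one
# quadrant/band centre.
small_recording <- function(noise_sd = 0, stiffness_ratio = 9,
                            diameter_mm = 60, clock = 0, n_points = 600,
                            seed = 5, input_frequency = 23) {
  br <- breast_spec("B1", side = "left", volume_cm3 = 500,
                    n_points = n_points, label = "cancerous")
  mat <- material_spec(stiffness_ratio = stiffness_ratio)
  tm <- tumor_spec(TRUE, clock_position = clock, depth_mm = 30,
                   diameter_mm = diameter_mm)
  rp <- recording_params(input_frequency = input_frequency,
                         sampling_rate = 500, duration = 1,
                         noise_sd = noise_sd, seed = seed)
  synth_recording(br, rp, mat, tm)
}

# A synthetic segment table with given 4x4 mean matrix.
table_from_matrix <- function(m, breast_id = "T", runs = 23) {
  counts <- matrix(ifelse(is.na(m), 0L, 10L), 4, 4)
  dimnames(m) <- dimnames(counts) <-
    list(radial = paste0("r", 0:3), zband = paste0("z", 0:3))
  structure(list(breast_id = breast_id, mean_foi = m, counts = counts,
                 runs_used = runs), class = "segment_table")
}

# Independent DFT oracle: direct O(n^2) sum, one-sided, DC and Nyquist
# excluded, same scaling convention as the package.
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  kmax <- floor((n - 1) / 2)
  j <- 0:(n - 1)
  mags <- vapply(1:kmax, function(k)
    2 * Mod(sum(x * exp(-2i * pi * j * k / n))) / n, numeric(1))
  data.frame(frequency = (1:kmax) * fs / n, magnitude = mags)
}

# Exhaustive local-maximum search oracle: returns bins of the dominant and
# second-dominant peaks (exclusion half-width around the dominant).
oracle_top_two <- function(mags, halfwidth = 2) {
  n <- length(mags)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || mags[i] > mags[i - 1]
    right_ok <- i == n || mags[i] >= mags[i + 1]
    edge <- (i == 1 && mags[i] > mags[i + 1]) ||
      (i == n && mags[i] > mags[i - 1])
    is_peak[i] <- if (i == 1 || i == n) edge else (left_ok && right_ok)
  }
  is_peak <- is_peak & mags > 0
  if (!any(is_peak)) return(list(dominant = NA, second = NA))
  peaks <- which(is_peak)
  dom <- peaks[order(-mags[peaks], peaks)][1]
  rest <- peaks[abs(peaks - dom) > halfwidth]
  sec <- if (length(rest)) rest[order(-mags[rest], rest)][1] else NA
  list(dominant = dom, second = sec)
}
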