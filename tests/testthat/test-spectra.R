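test_that("principal-axis projection recovers single-axis motion", {
  t <- seq(0, 1, length.out = 200)
  s <- sin(2 * pi * 11 * t)
  traj <- cbind(0.8 * s, 0, 0)
  out <- project_scalar(traj)
  expect_false(attr(out, "degenerate"))
  # recovered up to sign
  expect_lt(min(sum((out - 0.8 * (s - mean(s)))^2),
                sum((out + 0.8 * (s - mean(s)))^2)), 1e-18)
  expect_equal(mean(out), 0, tolerance = 1e-12)

  zero <- project_scalar(matrix(0, 50, 3))
  expect_true(attr(zero, "degenerate"))
  expect_identical(as.numeric(zero), rep(0, 50))
  expect_error(project_scalar(matrix(0, 4, 3)), class = "dietdx_invalid_spec")
})

test_that("projection of a two-tone 3-D signal keeps both tones", {
  fs <- 256; t <- (0:511) / fs
  s <- sin(2 * pi * 20 * t) + 0.4 * sin(2 * pi * 52 * t + 1)
  u <- c(0.1, -0.05, 1); u <- u / sqrt(sum(u^2))
  traj <- outer(s, u)
  proj <- project_scalar(traj)
  sp <- compute_spectrum(proj, fs)
  # oracle: the DFT of each Cartesian component shows the tone bins
  oz <- oracle_spectrum(traj[, 3], fs)
  for (f in c(20, 52)) {
    k <- which.min(abs(sp$frequency - f))
    expect_gt(sp$magnitude[k], 0.5 * max(sp$magnitude) * (f == 20) +
                0.1 * max(sp$magnitude) * (f == 52))
    expect_gt(oz$magnitude[k], 0.1 * max(oz$magnitude))
  }
})

test_that("spectra match the direct-DFT oracle and drop DC/Nyquist", {
  fs <- 500; t <- (0:999) / fs
  sp <- compute_spectrum(sin(2 * pi * 23 * t), fs)
  expect_equal(sp$frequency[which.max(sp$magnitude)], 23)
  expect_gt(min(sp$frequency), 0)
  expect_lt(max(sp$frequency), fs / 2)
  expect_equal(attr(sp, "bin_width"), 0.5)

  two <- 7 * sin(2 * pi * 23 * t) + 2.1 * sin(2 * pi * 50 * t + 0.3)
  sp2 <- compute_spectrum(two, fs)
  o <- oracle_spectrum(two[1:250], fs)  # oracle at smaller n for speed
  sp2_small <- compute_spectrum(two[1:250], fs)
  expect_equal(sp2_small$magnitude, o$magnitude, tolerance = 1e-9)
  k23 <- which.min(abs(sp2$frequency - 23))
  k50 <- which.min(abs(sp2$frequency - 50))
  expect_equal(sp2$magnitude[k50] / sp2$magnitude[k23], 0.3,
               tolerance = 0.02)

  spz <- compute_spectrum(rep(0, 64), fs)
  expect_true(all(spz$magnitude == 0))
  expect_error(compute_spectrum(1:4, fs), class = "dietdx_invalid_spec")
})

test_that("peak ranking orders by magnitude with low-frequency tie-break", {
  fs <- 240; t <- (0:239) / fs
  sp <- compute_spectrum(sin(2 * pi * 23 * t) + 0.4 * sin(2 * pi * 50 * t), fs)
  pk <- rank_peaks(sp)
  expect_equal(pk$frequency[1], 23)
  expect_equal(pk$frequency[2], 50)

  flat <- structure(data.frame(frequency = 1:20, magnitude = rep(1, 20)),
                    class = c("point_spectrum", "data.frame"))
  expect_equal(nrow(rank_peaks(flat)), 0)

  # exact tie between separated peaks: lower frequency first
  m <- rep(0.1, 60); m[20] <- 1; m[40] <- 1
  tie <- structure(data.frame(frequency = 1:60, magnitude = m),
                   class = c("point_spectrum", "data.frame"))
  expect_equal(rank_peaks(tie)$frequency[1], 20)
  expect_equal(rank_peaks(tie)$frequency[2], 40)
})

test_that("dominant and second peaks agree with the exhaustive oracle", {
  set.seed(202)
  for (trial in 1:25) {
    n <- sample(c(128, 256, 512, 1024), 1)
    fs <- 200
    t <- (0:(n - 1)) / fs
    f1 <- runif(1, 10, 60); f2 <- runif(1, 10, 90)
    x <- runif(1, 0.5, 2) * sin(2 * pi * f1 * t + runif(1, 0, 6)) +
      runif(1, 0.1, 0.9) * sin(2 * pi * f2 * t + runif(1, 0, 6)) +
      rnorm(n, sd = 0.05)
    sp <- compute_spectrum(x, fs)
    pk <- rank_peaks(sp, exclusion_halfwidth = 2)
    o <- oracle_top_two(sp$magnitude, halfwidth = 2)
    expect_equal(pk$bin[1], o$dominant)
    if (!is.na(o$second)) expect_equal(pk$bin[2], o$second)
  }
})

test_that("the frequency-of-interest rule follows its three branches", {
  mk <- function(f, m, bw = 0.5) {
    structure(data.frame(frequency = f, magnitude = m,
                         bin = as.integer(f / bw)), bin_width = bw)
  }
  # dominant at input, second strong -> second is the FoI
  r <- frequency_of_interest(mk(c(23, 50), c(1, 0.3)), 23)
  expect_equal(r$status, "retained")
  expect_equal(r$branch, "second_dominant")
  expect_equal(r$foi_hz, 50)
  # dominant at input, second below 15% -> discarded
  r <- frequency_of_interest(mk(c(23, 50), c(1, 0.10)), 23)
  expect_equal(r$status, "excluded")
  expect_equal(r$reason, "low_second")
  # second exactly at 15% is retained (threshold is "less than 15%")
  r <- frequency_of_interest(mk(c(23, 50), c(1, 0.15)), 23)
  expect_equal(r$status, "retained")
  # irregular dominant -> dominant itself is the FoI
  r <- frequency_of_interest(mk(c(37, 23), c(1, 0.9)), 23)
  expect_equal(r$branch, "irregular_dominant")
  expect_equal(r$foi_hz, 37)
  # no peaks at all
  r <- frequency_of_interest(mk(numeric(0), numeric(0)), 23)
  expect_equal(r$status, "excluded")
  expect_equal(r$reason, "degenerate")
})

test_that("a pure tone at the input frequency is always excluded", {
  fs <- 500
  for (n in c(250, 500, 1000)) {
    t <- (0:(n - 1)) / fs
    sp <- compute_spectrum(3 * sin(2 * pi * 23 * t + 0.7), fs)
    r <- frequency_of_interest(rank_peaks(sp), 23)
    expect_equal(r$status, "excluded")
  }
})

test_that("the FoI is invariant to uniform amplitude scaling", {
  rec <- small_recording(noise_sd = 0.01, n_points = 30, seed = 11)
  foi1 <- extract_foi(rec)
  rec$disp <- lapply(rec$disp, function(m) 7.3 * m)
  foi2 <- extract_foi(rec)
  expect_equal(foi1$foi_hz, foi2$foi_hz)
  expect_equal(foi1$status, foi2$status)
})

test_that("vectorised extraction matches the per-point path", {
  rec <- small_recording(noise_sd = 0.02, n_points = 25, seed = 13)
  foi <- extract_foi(rec)
  for (p in c(1, 7, 25)) {
    traj <- cbind(rec$disp$dx[, p], rec$disp$dy[, p], rec$disp$dz[, p])
    sp <- compute_spectrum(project_scalar(traj), rec$sampling_rate)
    r <- frequency_of_interest(rank_peaks(sp), rec$input_frequency)
    expect_equal(foi$status[p], r$status)
    expect_equal(foi$foi_hz[p], r$foi_hz)
    expect_equal(foi$dominant_hz[p], r$dominant_hz)
    expect_equal(foi$dominant_mag[p], r$dominant_mag, tolerance = 1e-9)
  }
})

test_that("runs are kept or dropped by the segment-irregularity rule", {
  reg <- matrix(23.1, 4, 4)
  irr1 <- reg; irr1[1, 1] <- 26    # 1 of 16 irregular (6.25%)
  irr2 <- reg; irr2[1, 1:2] <- 26  # 2 of 16 irregular (12.5%)
  out <- select_usable_runs(list(reg, irr1, irr2), c(23, 23, 23))
  expect_equal(out$irregular_fraction, c(0, 1 / 16, 2 / 16))
  expect_equal(out$retained, c(TRUE, TRUE, FALSE))
  expect_error(select_usable_runs(list(irr2), 23),
               class = "dietdx_empty_selection")
})
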