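test_that("surface clouds sample the half-ellipsoid surface deterministically", {
  br <- breast_spec("B1", volume_cm3 = 500, n_points = 2000)
  pts <- surface_point_cloud(br, seed = 3)
  expect_equal(nrow(pts), 2000)
  R <- attr(pts, "radius_mm"); h <- attr(pts, "height_mm")
  # enclosed volume of the half-ellipsoid equals the requested volume
  expect_equal((2 / 3) * pi * R^2 * h / 1000, 500, tolerance = 1e-10)
  expect_equal(h, 1.2 * R, tolerance = 1e-12)
  # every point satisfies the surface equation
  resid <- (pts$x_mm^2 + pts$y_mm^2) / R^2 + (pts$z_mm / h)^2 - 1
  expect_lt(max(abs(resid)), 1e-10)
  expect_true(all(pts$z_mm >= 0 & pts$z_mm <= h))
  expect_identical(pts, surface_point_cloud(br, seed = 3))
  expect_false(identical(pts$x_mm, surface_point_cloud(br, seed = 4)$x_mm))
})

test_that("larger breasts extend further from the chest wall", {
  big <- surface_point_cloud(breast_spec("B", volume_cm3 = 1057, n_points = 500), seed = 1)
  small <- surface_point_cloud(breast_spec("S", volume_cm3 = 239.5, n_points = 500), seed = 1)
  expect_gt(max(big$z_mm), max(small$z_mm))
  expect_gt(attr(big, "height_mm"), attr(small, "height_mm"))
})

test_that("invalid breast specifications are rejected", {
  expect_error(breast_spec("B", volume_cm3 = -10), class = "dietdx_invalid_spec")
  expect_error(breast_spec("B", n_points = 8), class = "dietdx_invalid_spec")
  expect_error(breast_spec("B", volume_cm3 = 5000), class = "dietdx_invalid_spec")
})

test_that("tumor weights follow the radial falloff profile", {
  br <- breast_spec("B1", volume_cm3 = 500, n_points = 3000)
  pts <- surface_point_cloud(br, seed = 7)
  expect_identical(tumor_weight(pts, tumor_spec(present = FALSE)),
                   rep(0, 3000))
  tm <- tumor_spec(TRUE, clock_position = 3, depth_mm = 30, diameter_mm = 40)
  w <- tumor_weight(pts, tm, side = "left")
  expect_true(all(w >= 0 & w <= 1))

  # independent closed-form oracle for the projection centre and profile
  R <- attr(pts, "radius_mm"); h <- attr(pts, "height_mm")
  zc <- h - 30
  sc <- R * sqrt(1 - (zc / h)^2)
  ctr <- c(sc * sin(2 * pi * 3 / 12), sc * cos(2 * pi * 3 / 12), zc)
  d <- sqrt((pts$x_mm - ctr[1])^2 + (pts$y_mm - ctr[2])^2 +
              (pts$z_mm - ctr[3])^2)
  r <- 20
  w_expected <- ifelse(d <= r, 1,
                       ifelse(d >= 2 * r, 0, 0.5 * (1 + cos(pi * (d - r) / r))))
  expect_equal(w, w_expected, tolerance = 1e-12)
  # non-increasing in distance from the centre
  ord <- order(d)
  expect_true(all(diff(w[ord]) <= 1e-12))
  expect_equal(max(w), 1)  # dense cloud reaches the full-weight core
})

test_that("noise-free recordings contain exactly the two synthesized tones", {
  rec <- small_recording(noise_sd = 0, stiffness_ratio = 10, diameter_mm = 80,
                         n_points = 40)
  w <- tumor_weight(rec$points, tumor_spec(TRUE, 0, 30, 80), "left")
  ratio <- 1.5 * sqrt(1 + w * (10 - 1))
  for (p in c(which.max(w), which.min(w))) {
    for (comp in c("dx", "dz")) {
      sp <- oracle_spectrum(rec$disp[[comp]][, p], rec$sampling_rate)
      big <- sp$magnitude > 0.1 * max(sp$magnitude)
      f_big <- sp$frequency[big]
      targets <- c(23, ratio[p] * 23)
      # every substantial component lies within the leakage width of a tone
      expect_true(all(vapply(f_big, function(f)
        min(abs(f - targets)) <= 2.0, logical(1))))
      # and both tones are present
      expect_true(all(vapply(targets, function(f)
        any(abs(f_big - f) <= 1.0), logical(1))))
    }
  }
})

test_that("tumor-centre secondary frequency scales as sqrt of the stiffness ratio", {
  for (sr in c(4, 10)) {
    rec <- small_recording(noise_sd = 0, stiffness_ratio = sr,
                           diameter_mm = 80, n_points = 200)
    foi <- extract_foi(rec)
    w <- tumor_weight(rec$points, tumor_spec(TRUE, 0, 30, 80), "left")
    f_tumor <- foi$foi_hz[which.max(w)]
    f_healthy <- foi$foi_hz[which.min(w)]
    bin <- rec$sampling_rate / nrow(rec$disp$dx)
    expect_equal(f_tumor / f_healthy, sqrt(sr),
                 tolerance = 2 * bin / (1.5 * 23))
  }
})

test_that("a unit stiffness ratio leaves the tumor region spectrally healthy", {
  br <- breast_spec("B1", volume_cm3 = 500, n_points = 150, label = "cancerous")
  tm <- tumor_spec(TRUE, 0, 30, 60)
  rp <- recording_params(seed = 9, noise_sd = 0)
  rec <- synth_recording(br, rp, material_spec(stiffness_ratio = 1), tm)
  foi <- extract_foi(rec)
  expect_true(all(foi$branch == "second_dominant"))
  expect_true(all(abs(foi$foi_hz - 1.5 * 23) <= 1))
})

test_that("infeasible sampling setups are rejected", {
  br <- breast_spec("B1", n_points = 20)
  mat <- material_spec(stiffness_ratio = 10)
  expect_error(
    synth_recording(br, recording_params(input_frequency = 23,
                                         sampling_rate = 100, seed = 1), mat),
    class = "dietdx_invalid_spec")  # Nyquist
  expect_error(
    synth_recording(br, recording_params(duration = 0.1, seed = 1), mat),
    class = "dietdx_invalid_spec")  # tones closer than two bins
})

test_that("cohort generation produces the requested runs and manifest", {
  co <- synth_cohort(3, 2, input_frequencies = c(21, 23), seed = 5,
                     n_points = 40, noise_sd = 0)
  expect_length(co$recordings, 10)  # 5 breasts x 2 runs
  expect_equal(nrow(co$manifest), 5)
  expect_equal(sum(co$manifest$label == "cancerous"), 2)
  expect_true(all(!is.na(co$manifest$tumor_diameter_mm[
    co$manifest$label == "cancerous"])))
  expect_true(all(is.na(co$manifest$tumor_diameter_mm[
    co$manifest$label == "healthy"])))

  single <- synth_cohort(1, 0, input_frequencies = 23, seed = 5, n_points = 40)
  expect_length(single$recordings, 1)
  expect_identical(single$manifest$label, "healthy")

  co2 <- synth_cohort(3, 2, input_frequencies = c(21, 23), seed = 5,
                      n_points = 40, noise_sd = 0)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$recordings[[1]]$disp, co2$recordings[[1]]$disp)
  expect_error(synth_cohort(1, 1, input_frequencies = numeric(0)),
               class = "dietdx_invalid_spec")
})
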