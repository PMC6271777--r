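# Surface pressure, compressibility, detectors, potential and dipole readouts.

test_that("surface pressure is the tension deficit", {
  expect_equal(surface_pressure_from_tension(72.8, 72.8), 0)
  expect_equal(surface_pressure_from_tension(72.8, 42.8), 30)
  expect_equal(surface_pressure_from_tension(72.8, 14.8), 58)
})

test_that("pipeline modulus matches the Volmer closed form on a noiseless LE branch", {
  # a film whose LE branch passes through A = 60 with omega = 40
  spec <- isotherm_spec(
    area_max = 150, area_min = 40, n_points = 2000L,
    liftoff_area = 100, volmer_coarea = 40,
    plateau_onset_pressure = 20,
    lc_elasticity = 240, collapse_pressure = 58
  )
  iso <- smooth_isotherm(generate_isotherm(spec), 50)
  curve <- compute_compressibility(iso)
  kT <- kT_monolayer(23)
  at60 <- approx(curve$area_A2, curve$modulus_mN_m, xout = 60)$y
  expect_equal(at60, 60 * kT / (60 - 40)^2, tolerance = 0.01)
  expect_equal(60 * kT / (60 - 40)^2, 61.3, tolerance = 1e-3)
})

test_that("pipeline modulus is K on a constant-elasticity branch and ~0 on a plateau", {
  spec <- transition_spec(noise = 0)
  iso <- smooth_isotherm(generate_isotherm(spec), 50)
  curve <- compute_compressibility(iso)
  # plateau interior: pressures strictly inside (15, 22)
  plateau <- curve$pressure_mN_m > 16.5 & curve$pressure_mN_m < 20.5
  expect_true(any(plateau))
  geom <- monolayr:::backbone_geometry(spec)
  expect_true(all(abs(curve$modulus_mN_m[plateau] -
    curve$area_A2[plateau] * spec$plateau_slope) < 2))
  lc <- curve$area_A2 < geom$a_pe - 2 & curve$area_A2 > 31
  expect_true(all(abs(curve$modulus_mN_m[lc] / 200 - 1) < 0.005))
})

test_that("compressibility needs at least three samples above lift-off", {
  iso <- new_test_isotherm(seq(100, 50, length.out = 50), rep(0, 50))
  expect_error(compute_compressibility(iso), class = "monolayr_error_insufficient_data")
})

test_that("lift-off recovers the injected area on noiseless curves", {
  p <- preset_spec("DPPE", "carvacrol",
    noise_sd_pressure = 0, noise_sd_potential = 0
  )
  iso <- smooth_isotherm(generate_isotherm(p$spec, p$psi_spec), 50)
  got <- detect_liftoff(iso)
  expect_equal(got$liftoff_area_A2, 120, tolerance = 1 / 120) # within 1 A^2
})

test_that("lift-off is absent on an all-zero trace", {
  iso <- new_test_isotherm(seq(120, 20, length.out = 1000), rep(0, 1000))
  got <- detect_liftoff(iso)
  expect_true(is.na(got$liftoff_area_A2))
  expect_equal(got$baseline_mN_m, 0)
})

test_that("lift-off warns when the baseline has fewer than 20 samples", {
  iso <- new_test_isotherm(seq(120, 20, length.out = 150), rep(0, 150))
  expect_warning(detect_liftoff(iso), "baseline")
})

test_that("noisy DPPG/water recovers the published ~90 A^2 lift-off", {
  p <- preset_spec("DPPG", "water", seed = 101)
  iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
  got <- detect_liftoff(smooth_isotherm(iso, 50))
  expect_equal(got$liftoff_area_A2, 90, tolerance = 2 / 90)
})

test_that("collapse of a flat clipped backbone is read exactly", {
  spec <- isotherm_spec(
    area_max = 80, area_min = 20, liftoff_area = 70, volmer_coarea = 20,
    plateau_onset_pressure = 12, lc_elasticity = 240, collapse_pressure = 50,
    post_collapse_slope = 0
  )
  iso <- generate_isotherm(spec)
  sm <- smooth_isotherm(iso, 50)
  curve <- compute_compressibility(sm)
  got <- detect_collapse(iso, curve)
  expect_equal(got$collapse_pressure_mN_m, 50, tolerance = 1e-3)
  geom <- monolayr:::backbone_geometry(spec)
  grid_step <- abs(diff(iso$area_A2[1:2]))
  expect_lt(abs(got$collapse_area_A2 - geom$a_coll), 3 * grid_step)
})

test_that("noisy DPPE/water collapse lands within 1 mN/m of the published 58", {
  p <- preset_spec("DPPE", "water", seed = 202)
  iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
  sm <- smooth_isotherm(iso, 50)
  curve <- compute_compressibility(sm)
  got <- detect_collapse(iso, curve)
  expect_equal(got$collapse_pressure_mN_m, 58, tolerance = 1 / 58)
})

test_that("a run truncated before collapse reports the feature absent", {
  # monotone curve ending at ~30 mN/m with no kink
  spec <- isotherm_spec(
    area_max = 120, area_min = 42, liftoff_area = 90, volmer_coarea = 20,
    plateau_onset_pressure = 12, lc_elasticity = 240, collapse_pressure = 55
  )
  iso <- generate_isotherm(spec)
  expect_lt(max(iso$pressure_mN_m), 35)
  sm <- smooth_isotherm(iso, 50)
  curve <- compute_compressibility(sm)
  got <- detect_collapse(iso, curve)
  expect_true(is.na(got$collapse_pressure_mN_m))
  # and without any condensed region at all (shallow LE only), absent as well
  a2 <- seq(200, 100, length.out = 800)
  kT <- kT_monolayer(23)
  p2 <- pmax(0, kT / (a2 - 20) - (kT / 130 - 0.5))
  iso2 <- new_test_isotherm(a2, p2)
  sm2 <- smooth_isotherm(iso2, 50)
  curve2 <- compute_compressibility(sm2)
  expect_lt(max(curve2$modulus_mN_m), 30)
  got2 <- detect_collapse(iso2, curve2)
  expect_true(is.na(got2$collapse_pressure_mN_m))
})

test_that("LE-LC plateau bounds are recovered within 1 mN/m", {
  spec <- transition_spec(noise = 0.05, seed = 33)
  iso <- smooth_isotherm(generate_isotherm(spec), 50)
  curve <- compute_compressibility(iso)
  got <- detect_transition(curve)
  expect_equal(got$transition_onset_mN_m, 15, tolerance = 1 / 15)
  expect_equal(got$transition_end_mN_m, 22, tolerance = 1 / 22)
})

test_that("transition is absent when the plateau is disabled", {
  iso <- smooth_isotherm(generate_isotherm(basic_spec(noise = 0.2, seed = 12)), 50)
  got <- detect_transition(compute_compressibility(iso))
  expect_true(is.na(got$transition_onset_mN_m))
})

test_that("a constant-pressure stretch between steep branches is detected", {
  # hand-built curve: steep rise, flat stretch, steep rise
  a <- seq(100, 25, length.out = 1200)
  p <- numeric(1200)
  seg1 <- a >= 70
  p[seg1] <- 18 - 2 * (a[seg1] - 70)
  seg2 <- a < 70 & a >= 50
  p[seg2] <- 18
  seg3 <- a < 50
  p[seg3] <- 18 + 2.5 * (50 - a[seg3])
  p <- pmax(p, 0)
  iso <- smooth_isotherm(new_test_isotherm(a, p), 50)
  got <- detect_transition(compute_compressibility(iso))
  expect_false(is.na(got$transition_onset_mN_m))
  # the detected low-elasticity interval covers the constant stretch
  expect_lte(got$transition_onset_mN_m, 18.2)
  expect_gte(got$transition_end_mN_m, 17.8)
  expect_equal(got$transition_onset_mN_m, 18, tolerance = 0.05)
})

test_that("modulus summary of a constant-elasticity curve is the constant", {
  spec <- basic_spec(k = 100, coll = 45)
  iso <- smooth_isotherm(generate_isotherm(spec), 50)
  curve <- compute_compressibility(iso)
  got <- modulus_summary(curve, collapse_pressure = 45)
  expect_equal(got$max_modulus_mN_m, 100, tolerance = 0.01)
  expect_equal(got$modulus_at_reference_mN_m, 100, tolerance = 0.01)
  expect_equal(got$phase_at_reference, "liquid-condensed")
})

test_that("modulus at the reference is absent for runs ending below it", {
  spec <- isotherm_spec(
    area_max = 120, area_min = 54, liftoff_area = 90, volmer_coarea = 20,
    plateau_onset_pressure = 5, lc_elasticity = 240, collapse_pressure = 55
  )
  iso <- smooth_isotherm(generate_isotherm(spec), 50)
  expect_lt(max(iso$pressure_mN_m), 30)
  curve <- compute_compressibility(iso)
  expect_message(got <- modulus_summary(curve), "reference")
  expect_true(is.na(got$modulus_at_reference_mN_m))
  expect_true(is.na(got$phase_at_reference))
})

test_that("increasing LC elasticity strictly increases the detected maximum", {
  maxima <- vapply(c(80, 140, 200, 260), function(k) {
    iso <- smooth_isotherm(generate_isotherm(basic_spec(k = k, coll = 55)), 50)
    modulus_summary(compute_compressibility(iso))$max_modulus_mN_m
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))
})

test_that("condensed-state potential extrema are recovered with sign", {
  p <- preset_spec("DPPE", "water", seed = 77)
  iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
  got <- max_surface_potential(smooth_isotherm(iso, 50))
  expect_equal(got$max_potential_mV, 600, tolerance = 10 / 600)
  expect_true(got$area_at_max_potential_A2 >= 30 && got$area_at_max_potential_A2 <= 40)

  n <- preset_spec("cardiolipin", "geraniol", seed = 78)
  iso_n <- generate_isotherm(n$spec, n$psi_spec, metadata = n$metadata)
  got_n <- max_surface_potential(smooth_isotherm(iso_n, 50))
  expect_equal(got_n$max_potential_mV, -100, tolerance = 10 / 100)

  zero <- new_test_isotherm(
    seq(120, 20, length.out = 500), rep(1, 500),
    potential = rep(0, 500)
  )
  expect_equal(max_surface_potential(zero)$max_potential_mV, 0)

  no_pot <- new_test_isotherm(seq(120, 20, length.out = 500), rep(1, 500))
  expect_true(is.na(max_surface_potential(no_pot)$max_potential_mV))
})

test_that("Helmholtz conversion reproduces the unit constant and scales exactly", {
  iso <- new_test_isotherm(
    c(12 * pi, 40), c(10, 20),
    potential = c(1, 600)
  )
  prof <- dipole_moment_profile(iso)
  expect_equal(prof$dipole_mD[1], 1, tolerance = 1e-7)
  expect_equal(prof$dipole_mD[2], 40 * 600 / (12 * pi), tolerance = 1e-12)
  expect_equal(prof$dipole_mD[2], 636.6, tolerance = 1e-4)

  iso_scaled <- iso
  iso_scaled$potential_mV <- iso$potential_mV * 3.5
  expect_equal(dipole_moment_profile(iso_scaled)$dipole_mD, prof$dipole_mD * 3.5)

  iso0 <- iso
  iso0$potential_mV <- c(0, 0)
  expect_equal(dipole_moment_profile(iso0)$dipole_mD, c(0, 0))

  expect_error(
    dipole_moment_profile(new_test_isotherm(c(40, 30), c(1, 2))),
    class = "monolayr_error_no_potential"
  )
})

test_that("extract_features recovers the published DPPE/carvacrol row", {
  p <- preset_spec("DPPE", "carvacrol", seed = 55)
  iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
  f <- extract_features(iso)
  expect_equal(f$lipid, "DPPE")
  expect_equal(f$subphase, "carvacrol")
  expect_equal(f$liftoff_area_A2, 120, tolerance = 3 / 120)
  expect_equal(f$collapse_pressure_mN_m, 38, tolerance = 1 / 38)
  expect_equal(f$max_modulus_mN_m, 50, tolerance = 0.05)
})

test_that("a noiseless preset yields a complete feature row", {
  p <- preset_spec("DPPG", "water", noise_sd_pressure = 0, noise_sd_potential = 0)
  iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
  f <- extract_features(iso)
  cols <- c(
    "liftoff_area_A2", "collapse_pressure_mN_m", "collapse_area_A2",
    "max_modulus_mN_m", "pressure_at_max_modulus_mN_m",
    "modulus_at_reference_mN_m", "max_potential_mV", "area_at_max_potential_A2"
  )
  for (col in cols) expect_false(is.na(f[[col]]))
})

test_that("a gas-only trace yields lift-off absent and downstream features absent", {
  iso <- new_test_isotherm(
    seq(200, 150, length.out = 300), rep(0, 300),
    potential = rep(5, 300)
  )
  f <- extract_features(iso)
  expect_true(is.na(f$liftoff_area_A2))
  expect_true(is.na(f$collapse_pressure_mN_m))
  expect_true(is.na(f$max_modulus_mN_m))
})

test_that("feature ordering holds: lift-off area exceeds collapse area", {
  for (cb in list(c("DPPE", "water"), c("DPPG", "carvacrol"), c("cardiolipin", "geraniol"))) {
    p <- preset_spec(cb[1], cb[2], seed = 91)
    iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
    f <- extract_features(iso)
    expect_gt(f$liftoff_area_A2, f$collapse_area_A2)
    if (!is.na(f$transition_onset_mN_m)) {
      expect_lte(f$transition_onset_mN_m, f$transition_end_mN_m)
    }
  }
})

test_that("feature_config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "smoothing:", "  window: 30", "  apply_to: pressure",
    "reference_pressure: 35"
  ), path)
  cfg <- read_feature_config(path)
  expect_equal(cfg$window, 30)
  expect_equal(cfg$apply_to, "pressure")
  expect_equal(cfg$reference_pressure, 35)
})
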