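# Shared fixture builders. All synthetic; nothing read from disk.

# a well-behaved condensed-type film: sharp lift-off, no plateau
basic_spec <- function(noise = 0, seed = NULL, n = 1000L, k = 240, coll = 55) {
  isotherm_spec(
    area_max = 120, area_min = 20, n_points = n,
    liftoff_area = 90, volmer_coarea = 20,
    plateau_onset_pressure = 12,
    lc_elasticity = k, collapse_pressure = coll,
    noise_sd_pressure = noise, noise_sd_potential = noise * 25,
    seed = seed
  )
}

# an expanded film with an LE-LC coexistence plateau from 15 to 22 mN/m;
# the run ends before collapse (truncated at area_min)
transition_spec <- function(noise = 0.05, seed = NULL) {
  isotherm_spec(
    area_max = 100, area_min = 30, n_points = 2000L,
    liftoff_area = 80, volmer_coarea = 30,
    plateau_enabled = TRUE,
    plateau_onset_pressure = 15, plateau_end_pressure = 22,
    plateau_slope = 0.5,
    lc_elasticity = 200, collapse_pressure = 60,
    noise_sd_pressure = noise,
    seed = seed
  )
}

basic_psi <- function(psi_max = 400) {
  potential_spec(psi_max = psi_max, midpoint_area = 85, width = 6)
}

# independent brute-force modulus oracle: centered finite differences on the
# raw (area, pressure) samples, no smoothing, no package derivative code
brute_force_modulus <- function(area, pressure) {
  n <- length(area)
  i <- 2:(n - 1)
  d <- (pressure[i + 1] - pressure[i - 1]) / (area[i + 1] - area[i - 1])
  tibble::tibble(area_A2 = area[i], modulus_mN_m = -area[i] * d)
}

new_test_isotherm <- function(area, pressure, potential = NULL, metadata = list()) {
  monolayr:::new_isotherm(area, pressure, potential, metadata)
}
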