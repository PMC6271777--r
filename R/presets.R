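# Presets reproducing the published summary table of thermodynamic
# parameters for three phospholipid monolayers (DPPE, DPPG, cardiolipin) on
# water and on subphases containing five natural antimicrobial compounds.

.preset_lipids <- c("DPPE", "DPPG", "cardiolipin")
.preset_subphases <- c(
  "water", "carvacrol", "cinnamaldehyde", "geraniol",
  "2,5-dihydroxybenzaldehyde", "2-hydroxy-5-methoxybenzaldehyde"
)

# lift-off (A^2/molecule), collapse pressure (mN/m), maximal Cs^-1 (mN/m),
# condensed-state surface potential (mV), reported dipole-moment area
# (A^2/molecule; an experimental readout carried along but not computed here)
.preset_values <- tibble::tribble(
  ~lipid, ~subphase, ~liftoff_A2, ~collapse_mN_m, ~max_modulus_mN_m, ~potential_mV, ~dipole_area_A2,
  "DPPE", "water", 43, 58, 240, 600, NA,
  "DPPE", "carvacrol", 120, 38, 50, 520, 185,
  "DPPE", "cinnamaldehyde", 117, 51, 95, 300, 75,
  "DPPE", "geraniol", 120, 43, 88, 300, 100,
  "DPPE", "2,5-dihydroxybenzaldehyde", 33, 50, 108, 300, 90,
  "DPPE", "2-hydroxy-5-methoxybenzaldehyde", 43, 47, 100, 600, 75,
  "DPPG", "water", 90, 49, 255, 450, 125,
  "DPPG", "carvacrol", 200, 42, 60, 180, 400,
  "DPPG", "cinnamaldehyde", 200, 44, 175, 75, 250,
  "DPPG", "geraniol", 200, 38, 80, 25, 180,
  "DPPG", "2,5-dihydroxybenzaldehyde", 90, 52, 170, 230, 270,
  "DPPG", "2-hydroxy-5-methoxybenzaldehyde", 125, 42, 72, 460, 250,
  "cardiolipin", "water", 110, 52, 145, 270, 260,
  "cardiolipin", "carvacrol", 180, 39, 85, 280, 400,
  "cardiolipin", "cinnamaldehyde", 180, 43, 120, 80, 400,
  "cardiolipin", "geraniol", 180, 32, 90, -100, 250,
  "cardiolipin", "2,5-dihydroxybenzaldehyde", 140, 52, 130, 430, 320,
  "cardiolipin", "2-hydroxy-5-methoxybenzaldehyde", 180, 44, 115, 210, 210
)

# per-lipid grid floor and the area window used for condensed-state
# surface-potential comparison
.lipid_params <- tibble::tribble(
  ~lipid, ~area_min, ~window_lo, ~window_hi,
  "DPPE", 12, 30, 40,
  "DPPG", 28, 40, 80,
  "cardiolipin", 40, 50, 100
)

#' Published monolayer parameters used by the presets
#'
#' The per-curve summary parameters (lift-off area, collapse pressure, maximal
#' compressibility modulus, condensed-state surface potential, and the
#' reported dipole-moment area) for the three phospholipids on water and on
#' five antimicrobial subphases. These values parameterize [preset_spec()].
#'
#' @return A tibble with one row per (lipid, subphase) combination.
#' @export
preset_table <- function() {
  .preset_values
}

#' Per-lipid area window for condensed-state potential comparison
#'
#' @param lipid Lipid name.
#' @return Numeric length-2 vector (lo, hi) in Å²/molecule, or `NULL` for
#'   unknown lipids.
#' @export
potential_window <- function(lipid) {
  row <- .lipid_params[.lipid_params$lipid == lipid, ]
  if (nrow(row) == 0) {
    return(NULL)
  }
  c(row$window_lo, row$window_hi)
}

#' Generator preset for a published lipid/subphase combination
#'
#' Builds an ([isotherm_spec()], [potential_spec()]) pair whose generated
#' isotherm, when analysed with [extract_features()], recovers the published
#' lift-off area, collapse pressure, maximal \eqn{C_s^{-1}} and
#' condensed-state surface potential within detector tolerance. The published
#' values fix the landmarks; the remaining geometry (co-area, LC onset
#' pressure, grid, noise) follows a fixed recipe documented in the package
#' vignette.
#'
#' @param lipid One of `"DPPE"`, `"DPPG"`, `"cardiolipin"`.
#' @param subphase One of `"water"`, `"carvacrol"`, `"cinnamaldehyde"`,
#'   `"geraniol"`, `"2,5-dihydroxybenzaldehyde"`,
#'   `"2-hydroxy-5-methoxybenzaldehyde"`.
#' @param n_points Grid size (default 1000).
#' @param noise_sd_pressure,noise_sd_potential Measurement noise SDs; the
#'   defaults (0.2 mN/m, 5 mV) emulate instrument noise.
#' @param seed Optional RNG seed stored in the spec.
#' @return A list with elements `spec`, `psi_spec`, `metadata` and `truth`
#'   (the published values being injected).
#' @examples
#' p <- preset_spec("DPPE", "water", seed = 1)
#' iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
#' @export
preset_spec <- function(lipid, subphase,
                        n_points = 1000L,
                        noise_sd_pressure = 0.2,
                        noise_sd_potential = 5,
                        seed = NULL) {
  row <- .preset_values[
    .preset_values$lipid == lipid & .preset_values$subphase == subphase,
  ]
  if (nrow(row) != 1L) {
    abort_mono(
      paste0(
        "Unknown (lipid, subphase) combination: (", lipid, ", ", subphase, "). ",
        "Valid lipids: ", paste(.preset_lipids, collapse = ", "), ". ",
        "Valid subphases: ", paste(.preset_subphases, collapse = ", "), "."
      ),
      "unknown_preset"
    )
  }
  lp <- .lipid_params[.lipid_params$lipid == lipid, ]
  kT <- kT_monolayer(23)
  thr <- 0.5
  a_lift <- row$liftoff_A2
  area_min <- lp$area_min
  omega <- min(0.45 * a_lift, area_min)
  pi_coh <- kT / (a_lift - omega) - thr
  k_lc <- row$max_modulus_mN_m
  area_max <- 1.35 * a_lift
  # LC onset: low enough that (a) the LE branch's modulus stays well below K
  # (joint modulus m(u) = u + omega*u^2/kT with u = pi + pi_coh) and (b) the
  # constant-elasticity segment spans enough grid points that its modulus
  # plateau survives the smoothing applied before differentiation
  c2 <- omega / kT
  u_star <- if (c2 > 0) {
    (-1 + sqrt(1 + 4 * c2 * 0.6 * k_lc)) / (2 * c2)
  } else {
    0.6 * k_lc
  }
  pi_cap <- min(12, max(5, u_star - pi_coh))
  d_area <- (area_max - area_min) / (n_points - 1)
  lc_points <- function(pi_t) {
    a_t <- omega + kT / (pi_t + pi_coh)
    a_coll <- a_t * exp(-(row$collapse_mN_m - pi_t) / k_lc)
    (a_t - a_coll) / d_area
  }
  # keep the LC onset at or above 5 mN/m so the liquid-expanded branch spans
  # the whole lift-off detection band even on the most expanded films
  pi_t <- pi_cap
  for (cand in seq(pi_cap, 5, by = -0.5)) {
    pi_t <- cand
    if (lc_points(cand) >= 110) break
  }

  spec <- isotherm_spec(
    area_max = area_max,
    area_min = area_min,
    n_points = n_points,
    liftoff_area = a_lift,
    volmer_coarea = omega,
    temperature = 23,
    plateau_enabled = FALSE,
    plateau_onset_pressure = pi_t,
    plateau_end_pressure = pi_t,
    lc_elasticity = k_lc,
    collapse_pressure = row$collapse_mN_m,
    post_collapse_slope = 0.2,
    noise_sd_pressure = noise_sd_pressure,
    noise_sd_potential = noise_sd_potential,
    liftoff_pressure = thr,
    seed = seed
  )
  a_psi <- max(a_lift, lp$window_hi)
  psi_spec <- potential_spec(
    psi_max = row$potential_mV,
    midpoint_area = a_psi,
    width = (a_psi - lp$window_lo) / 7
  )
  list(
    spec = spec,
    psi_spec = psi_spec,
    metadata = list(
      lipid = lipid, subphase_additive = subphase,
      additive_concentration = if (subphase == "water") {
        NA_real_
      } else if (subphase == "2,5-dihydroxybenzaldehyde") {
        74 # ug/mL, the MIC-level dose
      } else {
        500 # ug/mL
      },
      temperature = 23
    ),
    truth = as.list(row)
  )
}
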