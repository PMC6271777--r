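# Synthetic isotherm generation.

new_isotherm <- function(area, pressure, potential = NULL, metadata = list()) {
  iso <- tibble(area_A2 = area, pressure_mN_m = pressure)
  if (!is.null(potential)) iso$potential_mV <- potential
  attr(iso, "metadata") <- metadata
  class(iso) <- c("isotherm", class(iso))
  iso
}

#' Isotherm metadata
#'
#' Accessor for the metadata attached to an isotherm tibble (lipid, subphase
#' additive, concentration, temperature, provenance of processing steps).
#'
#' @param iso An isotherm tibble.
#' @return A named list.
#' @export
iso_metadata <- function(iso) {
  attr(iso, "metadata") %||% list()
}

`iso_metadata<-` <- function(iso, value) {
  attr(iso, "metadata") <- value
  iso
}

# noiseless backbone segment geometry for a spec; shared by the generator and
# by tests that need ground-truth joints
backbone_geometry <- function(spec) {
  kT <- kT_monolayer(spec$temperature)
  thr <- spec$liftoff_pressure
  pi_coh <- kT / (spec$liftoff_area - spec$volmer_coarea) - thr
  if (pi_coh <= 0) {
    abort_mono(
      "Volmer cohesion pressure is not positive; lift-off area too close to the co-area for this lift-off pressure.",
      "infeasible"
    )
  }
  a_zero <- spec$volmer_coarea + kT / pi_coh
  pi_t <- spec$plateau_onset_pressure
  if (pi_t < thr) {
    abort_mono(
      "plateau_onset_pressure (LC onset) must be at or above the lift-off pressure.",
      "infeasible"
    )
  }
  a_t <- spec$volmer_coarea + kT / (pi_t + pi_coh)
  if (a_t <= spec$area_min) {
    abort_mono(
      "Volmer branch cannot reach the LE end pressure before area_min.",
      "infeasible"
    )
  }
  if (spec$plateau_enabled && spec$plateau_end_pressure > pi_t) {
    a_pe <- a_t - (spec$plateau_end_pressure - pi_t) / spec$plateau_slope
    pi_pe <- spec$plateau_end_pressure
    if (a_pe <= spec$area_min) {
      abort_mono(
        "Plateau cannot reach its end pressure before area_min.",
        "infeasible"
      )
    }
  } else {
    a_pe <- a_t
    pi_pe <- pi_t
  }
  a_coll <- a_pe * exp(-(spec$collapse_pressure - pi_pe) / spec$lc_elasticity)
  list(
    kT = kT, pi_coh = pi_coh, a_zero = a_zero,
    a_t = a_t, pi_t = pi_t, a_pe = a_pe, pi_pe = pi_pe,
    a_coll = a_coll, collapse_reached = a_coll > spec$area_min
  )
}

# evaluate the noiseless pressure backbone on an area vector
backbone_pressure <- function(spec, area, geom = backbone_geometry(spec)) {
  p <- numeric(length(area))
  volmer <- geom$kT / (area - spec$volmer_coarea) - geom$pi_coh
  in_gas <- area >= geom$a_zero
  in_le <- area < geom$a_zero & area >= geom$a_t
  p[in_gas] <- 0
  p[in_le] <- volmer[in_le]
  if (spec$plateau_enabled && geom$a_pe < geom$a_t) {
    in_pl <- area < geom$a_t & area >= geom$a_pe
    p[in_pl] <- geom$pi_t + spec$plateau_slope * (geom$a_t - area[in_pl])
  }
  in_lc <- area < geom$a_pe & area >= geom$a_coll
  p[in_lc] <- geom$pi_pe + spec$lc_elasticity * log(geom$a_pe / area[in_lc])
  in_post <- area < geom$a_coll
  p[in_post] <- spec$collapse_pressure -
    spec$post_collapse_slope * (geom$a_coll - area[in_post])
  pmin(p, spec$collapse_pressure)
}

backbone_potential <- function(psi_spec, area) {
  psi_spec$psi_max / (1 + exp((area - psi_spec$midpoint_area) / psi_spec$width))
}

#' Generate a synthetic compression isotherm
#'
#' Evaluates the piecewise noiseless backbone described in [isotherm_spec()]
#' on a uniform decreasing area grid, adds i.i.d. Gaussian measurement noise,
#' and (when `psi_spec` is given) a sigmoidal surface-potential trace. The
#' same seed always reproduces the same samples.
#'
#' @param spec An [isotherm_spec()].
#' @param psi_spec An optional [potential_spec()]; omit for a
#'   pressure-only isotherm.
#' @param seed Overrides `spec$seed` when given.
#' @param metadata Optional named list merged into the isotherm metadata
#'   (e.g. `lipid`, `subphase_additive`).
#' @return An isotherm tibble with columns `area_A2`, `pressure_mN_m` and
#'   (optionally) `potential_mV`, in compression order (decreasing area).
#'   The generating parameters are recorded in `attr(, "metadata")$truth`.
#' @examples
#' spec <- isotherm_spec(
#'   area_max = 120, area_min = 20, liftoff_area = 90, volmer_coarea = 20,
#'   lc_elasticity = 240, collapse_pressure = 55, seed = 1
#' )
#' iso <- generate_isotherm(spec)
#' head(iso)
#' @export
generate_isotherm <- function(spec, psi_spec = NULL, seed = NULL, metadata = list()) {
  validate_isotherm_spec(spec)
  geom <- backbone_geometry(spec)
  area <- seq(spec$area_max, spec$area_min, length.out = spec$n_points)
  pressure <- backbone_pressure(spec, area, geom)
  potential <- if (!is.null(psi_spec)) backbone_potential(psi_spec, area) else NULL

  seed <- seed %||% spec$seed
  add_noise <- function() {
    if (spec$noise_sd_pressure > 0) {
      pressure <<- pressure + rnorm(length(area), sd = spec$noise_sd_pressure)
    }
    if (!is.null(potential) && spec$noise_sd_potential > 0) {
      potential <<- potential + rnorm(length(area), sd = spec$noise_sd_potential)
    }
  }
  if (!is.null(seed)) with_seed_restore(seed, add_noise()) else add_noise()

  md <- utils::modifyList(
    list(
      lipid = "synthetic", subphase_additive = "water",
      temperature = spec$temperature, source = "monolayr generator",
      truth = list(
        liftoff_area = spec$liftoff_area,
        collapse_pressure = spec$collapse_pressure,
        collapse_area = if (geom$collapse_reached) geom$a_coll else NA_real_,
        lc_elasticity = spec$lc_elasticity,
        psi_max = if (is.null(psi_spec)) NA_real_ else psi_spec$psi_max,
        transition = if (spec$plateau_enabled) {
          c(spec$plateau_onset_pressure, spec$plateau_end_pressure)
        } else {
          NULL
        }
      )
    ),
    metadata
  )
  new_isotherm(area, pressure, potential, md)
}
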