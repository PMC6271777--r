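#' Specification of a synthetic compression isotherm
#'
#' Builds the parameter set for [generate_isotherm()]. The noiseless backbone
#' is piecewise in compression order: a gas region at (near) zero pressure, a
#' liquid-expanded (LE) branch following the Volmer equation of state
#' \eqn{\pi = kT/(A-\omega) - \Pi_{coh}}, an optional LE–LC coexistence
#' plateau, a liquid-condensed (LC) branch of constant elasticity
#' \eqn{\pi = \pi_0 + K\,\ln(A_0/A)} (so that \eqn{C_s^{-1} \equiv K}), and a
#' post-collapse plateau after the pressure is clipped at the collapse
#' pressure. The cohesion pressure is fixed by continuity so that the backbone
#' crosses `liftoff_pressure` exactly at `liftoff_area`.
#'
#' @param area_max,area_min Bounds of the uniform area grid, Å²/molecule.
#' @param n_points Number of samples on the grid (>= 100).
#' @param liftoff_area Area at which the backbone crosses the lift-off
#'   pressure, Å²/molecule.
#' @param volmer_coarea Volmer co-area \eqn{\omega}, Å²/molecule. Must not
#'   exceed `area_min`.
#' @param temperature Temperature, °C.
#' @param plateau_enabled Insert an LE–LC coexistence plateau?
#' @param plateau_onset_pressure Pressure at which the LE branch ends, mN/m.
#'   Also the LC onset pressure when the plateau is disabled.
#' @param plateau_end_pressure Pressure at which the plateau ends, mN/m.
#' @param plateau_slope Plateau steepness, mN/m per Å² (> 0 when enabled).
#' @param lc_elasticity Constant compressibility modulus K of the LC branch,
#'   mN/m.
#' @param collapse_pressure Pressure at which the backbone is clipped, mN/m.
#' @param post_collapse_slope Gentle decline beyond collapse, mN/m per Å².
#' @param noise_sd_pressure,noise_sd_potential Gaussian measurement noise
#'   standard deviations (mN/m, mV).
#' @param liftoff_pressure Pressure level defining lift-off, mN/m.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `isotherm_spec` (a named list).
#' @seealso [potential_spec()], [generate_isotherm()], [preset_spec()]
#' @examples
#' spec <- isotherm_spec(
#'   area_max = 120, area_min = 20, liftoff_area = 90,
#'   volmer_coarea = 20, lc_elasticity = 240, collapse_pressure = 55
#' )
#' @export
isotherm_spec <- function(area_max,
                          area_min,
                          n_points = 1000L,
                          liftoff_area,
                          volmer_coarea,
                          temperature = 23,
                          plateau_enabled = FALSE,
                          plateau_onset_pressure = 12,
                          plateau_end_pressure = plateau_onset_pressure,
                          plateau_slope = 0.5,
                          lc_elasticity,
                          collapse_pressure,
                          post_collapse_slope = 0.12,
                          noise_sd_pressure = 0,
                          noise_sd_potential = 0,
                          liftoff_pressure = 0.5,
                          seed = NULL) {
  spec <- list(
    area_max = as.numeric(area_max),
    area_min = as.numeric(area_min),
    n_points = as.integer(n_points),
    liftoff_area = as.numeric(liftoff_area),
    volmer_coarea = as.numeric(volmer_coarea),
    temperature = as.numeric(temperature),
    plateau_enabled = isTRUE(plateau_enabled),
    plateau_onset_pressure = as.numeric(plateau_onset_pressure),
    plateau_end_pressure = as.numeric(plateau_end_pressure),
    plateau_slope = as.numeric(plateau_slope),
    lc_elasticity = as.numeric(lc_elasticity),
    collapse_pressure = as.numeric(collapse_pressure),
    post_collapse_slope = as.numeric(post_collapse_slope),
    noise_sd_pressure = as.numeric(noise_sd_pressure),
    noise_sd_potential = as.numeric(noise_sd_potential),
    liftoff_pressure = as.numeric(liftoff_pressure),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(spec) <- "isotherm_spec"
  validate_isotherm_spec(spec)
  spec
}

validate_isotherm_spec <- function(spec) {
  with(spec, {
    if (!(area_max > liftoff_area && liftoff_area > area_min)) {
      abort_mono(
        "Require area_max > liftoff_area > area_min.",
        "invalid_spec"
      )
    }
    if (!(area_min >= volmer_coarea && volmer_coarea >= 0)) {
      abort_mono(
        "Require area_min >= volmer_coarea >= 0.",
        "invalid_spec"
      )
    }
    if (n_points < 100L) {
      abort_mono("n_points must be at least 100.", "invalid_spec")
    }
    if (!(collapse_pressure > plateau_end_pressure &&
      plateau_end_pressure >= plateau_onset_pressure &&
      plateau_onset_pressure >= 0)) {
      abort_mono(
        "Require collapse_pressure > plateau_end_pressure >= plateau_onset_pressure >= 0.",
        "invalid_spec"
      )
    }
    if (lc_elasticity <= 0) {
      abort_mono("lc_elasticity must be positive.", "invalid_spec")
    }
    if (noise_sd_pressure < 0 || noise_sd_potential < 0) {
      abort_mono("Noise standard deviations must be >= 0.", "invalid_spec")
    }
    if (plateau_enabled && plateau_slope <= 0 &&
      plateau_end_pressure > plateau_onset_pressure) {
      abort_mono(
        "An enabled plateau with plateau_end_pressure > plateau_onset_pressure needs plateau_slope > 0.",
        "invalid_spec"
      )
    }
    if (liftoff_pressure <= 0) {
      abort_mono("liftoff_pressure must be positive.", "invalid_spec")
    }
  })
  invisible(spec)
}

#' Specification of a synthetic surface-potential curve
#'
#' The surface potential backbone is the sigmoid
#' \eqn{\Delta\psi(A) = \psi_{max} / (1 + \exp((A - A_\psi)/w_\psi))},
#' rising (or falling, for negative \eqn{\psi_{max}}) towards its asymptote as
#' the film is compressed. A negative `psi_max` models monolayers whose
#' condensed-state potential runs negative.
#'
#' @param psi_max Asymptotic surface potential, mV (may be negative).
#' @param midpoint_area Sigmoid midpoint \eqn{A_\psi}, Å²/molecule.
#' @param width Sigmoid width \eqn{w_\psi}, Å²/molecule (> 0).
#' @return An object of class `potential_spec`.
#' @examples
#' potential_spec(psi_max = 600, midpoint_area = 43, width = 2)
#' @export
potential_spec <- function(psi_max, midpoint_area, width) {
  if (!is.numeric(width) || width <= 0) {
    abort_mono("width must be positive.", "invalid_spec")
  }
  structure(
    list(
      psi_max = as.numeric(psi_max),
      midpoint_area = as.numeric(midpoint_area),
      width = as.numeric(width)
    ),
    class = "potential_spec"
  )
}

#' Read generator specifications from a YAML file
#'
#' Reads a YAML file whose top-level keys mirror the field names of
#' [isotherm_spec()] (under `isotherm:`) and [potential_spec()] (under
#' `potential:`, optional).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `spec` (`isotherm_spec`) and `psi_spec`
#'   (`potential_spec` or `NULL`).
#' @export
read_isotherm_spec <- function(path) {
  if (!file.exists(path)) {
    abort_mono(paste0("No such file: ", path), "io")
  }
  y <- yaml::read_yaml(path)
  fields <- y$isotherm %||% y
  spec <- do.call(isotherm_spec, fields)
  psi <- if (!is.null(y$potential)) do.call(potential_spec, y$potential) else NULL
  list(spec = spec, psi_spec = psi)
}
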