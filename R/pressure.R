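# Surface pressure and the compressibility (elasticity) modulus.

#' Surface pressure from surface tension
#'
#' Surface pressure is the reduction of surface tension by the film,
#' \eqn{\pi = \gamma_0 - \gamma}.
#'
#' @param gamma0 Surface tension of the clean subphase, mN/m.
#' @param gamma Surface tension with the monolayer present, mN/m.
#' @return Surface pressure, mN/m.
#' @examples
#' surface_pressure_from_tension(72.8, 42.8) # 30
#' @export
surface_pressure_from_tension <- function(gamma0, gamma) {
  stopifnot(is.numeric(gamma0), is.numeric(gamma))
  gamma0 - gamma
}

#' Compressibility modulus curve from a smoothed isotherm
#'
#' Computes the in-plane elasticity \eqn{C_s^{-1} = -A\,(\partial\pi /
#' \partial A)} by central differences on the area grid (one-sided at the
#' ends). The curve is restricted to points with \eqn{\pi \ge}
#' `liftoff_pressure` — below lift-off the derivative of a near-zero signal
#' only amplifies noise.
#'
#' @param iso A smoothed, compression-ordered isotherm tibble.
#' @param liftoff_pressure Gas-phase cutoff, mN/m.
#' @return A tibble of class `compressibility_curve` with columns `area_A2`,
#'   `pressure_mN_m`, `modulus_mN_m`, aligned and ordered by compression.
#' @examples
#' spec <- isotherm_spec(
#'   area_max = 120, area_min = 20, liftoff_area = 90, volmer_coarea = 20,
#'   lc_elasticity = 240, collapse_pressure = 55
#' )
#' curve <- compute_compressibility(generate_isotherm(spec))
#' @export
compute_compressibility <- function(iso, liftoff_pressure = 0.5) {
  a <- iso$area_A2
  p <- iso$pressure_mN_m
  n <- length(a)
  keep <- which(p >= liftoff_pressure & a > 0)
  if (length(keep) < 3L) {
    abort_mono(
      "Fewer than 3 samples above the lift-off pressure; cannot differentiate.",
      "insufficient_data"
    )
  }
  dpda <- numeric(n)
  dpda[1] <- (p[2] - p[1]) / (a[2] - a[1])
  dpda[n] <- (p[n] - p[n - 1]) / (a[n] - a[n - 1])
  idx <- 2:(n - 1)
  dpda[idx] <- (p[idx + 1] - p[idx - 1]) / (a[idx + 1] - a[idx - 1])
  modulus <- -a * dpda
  out <- tibble(
    area_A2 = a[keep],
    pressure_mN_m = p[keep],
    modulus_mN_m = modulus[keep]
  )
  attr(out, "metadata") <- iso_metadata(iso)
  class(out) <- c("compressibility_curve", class(out))
  out
}
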