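# Physical constants used throughout the package.
#
# Pressures are mN/m, areas A^2/molecule, potentials mV, dipole moments mD.
# In these units k_B*T at 23 degC (296.15 K) is 408.9 mN*A^2/m:
#   k_B * 296.15 K = 4.089e-21 J = 408.9e-23 (mN/m)*A^2.

# k_B*T at the reference temperature, mN*A^2/m
.kt_ref <- 408.9
.t_ref_K <- 296.15

#' Thermal energy in monolayer units
#'
#' Returns \eqn{k_B T} expressed in mN·Å²/m, the natural unit for surface
#' pressure–area work per molecule, scaled linearly with absolute temperature
#' from the fixed point 408.9 mN·Å²/m at 23 °C.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @return Thermal energy in mN·Å²/m.
#' @examples
#' kT_monolayer(23) # 408.9
#' @export
kT_monolayer <- function(temperature_C = 23) {
  stopifnot(is.numeric(temperature_C), is.finite(temperature_C))
  .kt_ref * (temperature_C + 273.15) / .t_ref_K
}

# Helmholtz conversion constant: mu[mD] = A[A^2] * psi[mV] / (12*pi)
.helmholtz_denom <- 12 * pi
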