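# Physical constants. Internal EOS units are Angstrom, Kelvin, molecule.
.const <- list(
  kB_J      = 1.380649e-23,     # J/K
  kB_PaA3   = 1.380649e7,       # Pa * Angstrom^3 / K  (1.380649e-23 J/K * 1e30 A^3/m^3)
  NA_mol    = 6.02214076e23,    # 1/mol
  R_kJ      = 8.31446261815324e-3, # kJ/(mol K)
  e2_eps0kB = 2.0998164e6,      # e^2/(eps0*kB) in Angstrom*Kelvin
  Mw_water  = 18.015268,        # g/mol
  mol_per_kg_water = 1000 / 18.015268, # 55.5084 mol water per kg
  P_ambient = 1.01325e5         # Pa; ambient-lab default pressure
)

#' Relative permittivity of pure water
#'
#' Empirical temperature correlation for the static relative permittivity of
#' liquid water (valid 273-373 K), used by the Debye-Hueckel contribution.
#' Yields 78.4 at 298.15 K.
#'
#' @param T temperature in K.
#' @return dimensionless relative permittivity.
#' @export
water_permittivity <- function(T) {
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 0.8292e-6 * T^3
}

#' Temperature-dependent segment diameter of water
#'
#' @param T temperature in K.
#' @return sigma of water in Angstrom.
#' @export
water_sigma <- function(T) {
  2.7927 + 10.11 * exp(-0.01775 * T) - 1.417 * exp(-0.01146 * T)
}
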