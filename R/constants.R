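# Internal unit system: k_B = 1, energies in kelvin, lengths in nm,
# number densities in nm^-3.  Conversions happen only at the I/O boundary.

.kB_J <- 1.380649e-23        # J/K
.N_A <- 6.02214076e23        # 1/mol
.M_WATER <- 18.015           # g/mol

# 1 K nm^-3 (times k_B) expressed in MPa
.P_K_NM3_TO_MPA <- .kB_J / 1e-27 / 1e6

# 1 K nm^-2 (times k_B) expressed in mN/m
.G_K_NM2_TO_MN_M <- .kB_J / 1e-18 * 1e3

#' Unit conversions between the internal simulation units and SI
#'
#' The package works internally with \eqn{k_B = 1}: energies and temperatures
#' in kelvin, lengths in nm, number densities in nm\eqn{^{-3}}.  These helpers
#' convert the quantities that are conventionally reported in SI-flavoured
#' units: mass density in kg/m\eqn{^3} (molar mass 18.015 g/mol for water),
#' pressure in MPa, surface tension in mN/m and isothermal compressibility in
#' 1/MPa.
#'
#' @param rho number density in nm^-3
#' @param rho_si mass density in kg/m^3
#' @param p pressure in K nm^-3 (internal units)
#' @param gamma surface tension in K nm^-2 (internal units)
#' @param beta compressibility in (K nm^-3)^-1 (internal units)
#' @param molar_mass molar mass in g/mol (default water, 18.015)
#' @return the converted quantity
#' @examples
#' rho_to_kg_m3(33.33)   # about 997 kg/m^3, liquid water
#' @name units
NULL

#' @rdname units
#' @export
rho_to_kg_m3 <- function(rho, molar_mass = .M_WATER) {
  rho * molar_mass * 1e-3 / .N_A / 1e-27
}

#' @rdname units
#' @export
kg_m3_to_rho <- function(rho_si, molar_mass = .M_WATER) {
  rho_si * 1e-27 * .N_A / (molar_mass * 1e-3)
}

#' @rdname units
#' @export
pressure_to_MPa <- function(p) p * .P_K_NM3_TO_MPA

#' @rdname units
#' @export
MPa_to_pressure <- function(p) p / .P_K_NM3_TO_MPA

#' @rdname units
#' @export
gamma_to_mN_m <- function(gamma) gamma * .G_K_NM2_TO_MN_M

#' @rdname units
#' @export
beta_to_per_MPa <- function(beta) beta / .P_K_NM3_TO_MPA
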