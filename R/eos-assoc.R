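#' Association (hydrogen-bonding) parameters
#'
#' Four-site Wertheim TPT1 description of hydrogen bonding in water: two
#' hydrogen-type sites and two lone-pair-type sites (the symmetric "4C"
#' scheme, H sites bond only to e sites).  `epsilon_assoc` is the association
#' well depth in kelvin and `bond_volume` the bonding-volume parameter in
#' nm^3.
#'
#' @param epsilon_assoc association energy, kelvin; non-negative
#' @param bond_volume bonding volume, nm^3; non-negative
#' @param n_H,n_e site counts (fixed at 2 and 2 for the 4C water scheme)
#' @return an object of class `association_parameters`
#' @export
association_parameters <- function(epsilon_assoc, bond_volume,
                                   n_H = 2L, n_e = 2L) {
  if (epsilon_assoc < 0) stop("epsilon_assoc must be non-negative")
  if (bond_volume < 0) stop("bond_volume must be non-negative")
  if (n_H != 2L || n_e != 2L) {
    stop("only the symmetric 2H + 2e site scheme is supported")
  }
  structure(list(epsilon_assoc = epsilon_assoc, bond_volume = bond_volume,
                 n_H = 2L, n_e = 2L),
            class = "association_parameters")
}

#' Fraction of association sites not bonded
#'
#' Closed-form mass-action solution for the symmetric 2H + 2e site scheme.
#' With \eqn{\Delta} the association strength, every site satisfies
#' \eqn{X = 1/(1 + 2\rho\Delta X)}, whose physical root is
#' \deqn{X = \frac{-1 + \sqrt{1 + 8\rho\Delta}}{4\rho\Delta}
#'   = \frac{2}{1 + \sqrt{1 + 8\rho\Delta}},}
#' evaluated in the second, cancellation-free form.
#'
#' @param rho_delta dimensionless product \eqn{\rho\Delta} (vectorised);
#'   non-negative
#' @return fraction of sites not bonded, in (0, 1]
#' @export
#' @examples
#' association_fraction(0)  # 1: no bonding
#' association_fraction(1)  # 0.5
association_fraction <- function(rho_delta) {
  if (any(rho_delta < 0)) stop("rho_delta must be non-negative")
  2 / (1 + sqrt(1 + 8 * rho_delta))
}

# Association strength Delta(rho, T) in nm^3: standard TPT1 kernel built from
# the Mayer factor of the site-site well and the reference-fluid contact
# value, Delta = g_HS(d) [exp(eps_HB/T) - 1] K_HB.  (The cited source's
# density-temperature polynomial kernel is not reproduced here; the
# contact-value kernel is the textbook TPT1 closure.)
assoc_delta <- function(rho, T, ap, mie) {
  d <- bh_diameter(T, mie)
  eta <- pi * rho * d^3 / 6
  g_contact <- (1 - eta / 2) / (1 - eta)^3
  g_contact * expm1(ap$epsilon_assoc / T) * ap$bond_volume
}

#' Association contribution to the excess free energy
#'
#' Wertheim TPT1 free energy for the symmetric four-site scheme,
#' \deqn{a^{assoc}/(k_B T) = 4\left(\ln X - X/2\right) + 2,}
#' with \eqn{X} the fraction of sites not bonded from
#' [association_fraction()].  Vanishes when `epsilon_assoc` is zero (then
#' \eqn{\Delta = 0}, \eqn{X = 1}).
#'
#' @param rho number density, nm^-3 (vectorised)
#' @param T temperature, kelvin
#' @param p an [association_parameters()] object
#' @param mie the [mie_parameters()] of the reference fluid (sets the
#'   effective diameter used in the contact value)
#' @return excess free energy per particle, kelvin
#' @export
a_assoc <- function(rho, T, p, mie) {
  stopifnot(inherits(p, "association_parameters"),
            inherits(mie, "mie_parameters"), T > 0)
  if (any(rho < 0)) stop("rho must be non-negative")
  if (p$epsilon_assoc == 0 || p$bond_volume == 0) return(rep(0, length(rho)))
  delta <- assoc_delta(rho, T, p, mie)
  x <- association_fraction(rho * delta)
  T * (4 * (log(x) - x / 2) + 2)
}
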