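#' Mie interaction parameters
#'
#' Container for the four parameters of the Mie (generalised Lennard-Jones)
#' potential: well depth `epsilon` (as \eqn{\epsilon/k_B}, kelvin), size
#' parameter `sigma` (nm), and the repulsive/attractive exponents
#' `lambda_r` > `lambda_a` > 3 (the attractive tail must be integrable).
#'
#' @param epsilon well depth, kelvin (epsilon/k_B convention)
#' @param sigma size parameter, nm
#' @param lambda_r repulsive exponent
#' @param lambda_a attractive exponent (default 6)
#' @return an object of class `mie_parameters`
#' @export
#' @examples
#' mie_parameters(epsilon = 266.68, sigma = 0.30555, lambda_r = 17.02)
mie_parameters <- function(epsilon, sigma, lambda_r, lambda_a = 6) {
  stopifnot(is.numeric(epsilon), is.numeric(sigma),
            is.numeric(lambda_r), is.numeric(lambda_a))
  if (epsilon <= 0) stop("epsilon must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (!(lambda_r > lambda_a && lambda_a > 3)) {
    stop("exponents must satisfy lambda_r > lambda_a > 3")
  }
  structure(list(epsilon = epsilon, sigma = sigma,
                 lambda_r = lambda_r, lambda_a = lambda_a),
            class = "mie_parameters")
}

# Analytic Mie prefactor C(lambda_r, lambda_a)
mie_prefactor <- function(lambda_r, lambda_a) {
  (lambda_r / (lambda_r - lambda_a)) *
    (lambda_r / lambda_a)^(lambda_a / (lambda_r - lambda_a))
}

#' Mie pair potential
#'
#' \deqn{\phi(r) = C\,\epsilon\,[(\sigma/r)^{\lambda_r} -
#'   (\sigma/r)^{\lambda_a}]}
#' with the prefactor \eqn{C = \frac{\lambda_r}{\lambda_r-\lambda_a}
#' (\lambda_r/\lambda_a)^{\lambda_a/(\lambda_r-\lambda_a)}} chosen so the
#' minimum depth equals \eqn{-\epsilon}.  In this package the Mie potential
#' only enters through the equation of state (Barker-Henderson diameter and
#' perturbation terms); it is never summed over particle pairs.
#'
#' @param r separation, nm (vectorised); must be positive
#' @param p a [mie_parameters()] object
#' @return potential energy in kelvin (epsilon/k_B convention)
#' @export
#' @examples
#' p <- mie_parameters(1, 1, 12, 6)
#' mie_potential(2^(1/6), p)   # -1, the Lennard-Jones minimum
mie_potential <- function(r, p) {
  stopifnot(inherits(p, "mie_parameters"))
  if (any(r <= 0)) stop("r must be positive")
  C <- mie_prefactor(p$lambda_r, p$lambda_a)
  sr <- p$sigma / r
  C * p$epsilon * (sr^p$lambda_r - sr^p$lambda_a)
}

# Barker-Henderson effective hard-sphere diameter
#   d(T) = int_0^sigma [1 - exp(-phi(r)/T)] dr
# The integrand is 1 deep in the core (exp underflows harmlessly) and drops
# steeply near sigma; adaptive quadrature at tight tolerance handles both.
bh_diameter <- function(T, p) {
  stopifnot(T > 0)
  C <- mie_prefactor(p$lambda_r, p$lambda_a)
  f <- function(r) {
    sr <- p$sigma / r
    phi <- C * p$epsilon * (sr^p$lambda_r - sr^p$lambda_a)
    1 - exp(-phi / T)
  }
  stats::integrate(f, lower = 0, upper = p$sigma,
                   rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 400L)$value
}

# --- third-order Barker-Henderson perturbation machinery ------------------

# Effective packing-fraction coefficients for the mean-value approximation of
# the first-order perturbation integral (valid for 5 < lambda < 100).
.eta_eff_A <- matrix(c(
   0.81096,  1.7888,  -37.578,   92.284,
   1.02050, -19.341,  151.26,  -463.50,
  -1.90570,  22.845, -228.14,   973.92,
   1.08850, -6.1962,  106.98,  -677.64), nrow = 4, byrow = TRUE)

eta_eff <- function(eta, lambda) {
  cvec <- .eta_eff_A %*% c(1, 1 / lambda, 1 / lambda^2, 1 / lambda^3)
  cvec[1] * eta + cvec[2] * eta^2 + cvec[3] * eta^3 + cvec[4] * eta^4
}

# a1s: first-order Sutherland-fluid term at exponent lambda (per particle, K)
a1s_term <- function(eta, lambda, epsilon) {
  ee <- eta_eff(eta, lambda)
  -12 * epsilon * eta / (lambda - 3) * (1 - ee / 2) / (1 - ee)^3
}

# B: correction integral between d and sigma (x0 = sigma/d >= 1)
b_term <- function(eta, lambda, epsilon, x0) {
  I <- (1 - x0^(3 - lambda)) / (lambda - 3)
  J <- (1 - x0^(4 - lambda) * (lambda - 3) + x0^(3 - lambda) * (lambda - 4)) /
    ((lambda - 3) * (lambda - 4))
  12 * epsilon * eta *
    ((1 - eta / 2) / (1 - eta)^3 * I - 9 * eta * (1 + eta) / (2 * (1 - eta)^3) * J)
}

asb <- function(eta, lambda, epsilon, x0) {
  a1s_term(eta, lambda, epsilon) + b_term(eta, lambda, epsilon, x0)
}

# Pade-style alpha functions used by the second- and third-order terms.
# Rows are powers n = 0..6 of alpha; columns k = 1..6.
.phi_table <- matrix(c(
   7.5365557, -37.60463,   71.745953, -46.83552,  -2.467982, -0.50272,
  -359.44,     1825.6,    -3168.0,     1884.2,    -0.82376,  -3.1935,
   1550.9,    -5070.1,     6534.6,    -3288.7,    -2.7171,    2.0883,
  -1.19932,    9.063632,  -17.9482,    11.34027,  20.52142, -56.6377,
  -1911.28,    21390.175, -51320.7,    37064.54, 1103.742, -3264.61,
   9236.9,   -129430,      357230,   -315530,     1390.2,   -4518.2,
   10,         10,         0.57,       -6.7,       -8,          0),
  nrow = 7, byrow = TRUE)

f_alpha <- function(k, alpha) {
  num <- sum(.phi_table[1:4, k] * alpha^(0:3))
  den <- 1 + sum(.phi_table[5:7, k] * alpha^(1:3))
  num / den
}

# Isothermal hard-sphere compressibility factor correction
k_hs <- function(eta) {
  (1 - eta)^4 / (1 + 4 * eta + 4 * eta^2 - 4 * eta^3 + eta^4)
}

.ETA_MAX <- 0.7405  # close-packing bound for the effective diameter

#' Monomer excess free energy of a Mie fluid
#'
#' Excess Helmholtz free energy per particle of a fluid of single Mie
#' segments, from the third-order Barker-Henderson perturbation expansion
#' about a hard-sphere reference with temperature-dependent effective
#' diameter \eqn{d(T)}:
#' \deqn{a^{mono} = a^{HS} k_B T + a_1 + a_2/(k_B T) + a_3/(k_B T)^2.}
#' \eqn{a^{HS}} is the Carnahan-Starling term at packing fraction
#' \eqn{\eta = \pi\rho d^3/6}; \eqn{a_1} is the mean-attractive energy,
#' \eqn{a_2} the fluctuation term with its packing-fraction correction, and
#' \eqn{a_3} an empirical third-order term.
#'
#' @param rho number density, nm^-3 (vectorised); must stay below the
#'   close-packing bound of the effective diameter
#' @param T temperature, kelvin
#' @param p a [mie_parameters()] object
#' @return excess free energy per particle, kelvin
#' @export
a_mono <- function(rho, T, p) {
  stopifnot(inherits(p, "mie_parameters"), T > 0)
  if (any(rho < 0)) stop("rho must be non-negative")
  if (p$epsilon == 0) return(rep(0, length(rho)))  # documented limit
  d <- bh_diameter(T, p)
  x0 <- p$sigma / d
  eta <- pi * rho * d^3 / 6
  if (any(eta >= .ETA_MAX)) {
    stop("density above the hard-sphere packing limit for the effective diameter")
  }
  C <- mie_prefactor(p$lambda_r, p$lambda_a)
  la <- p$lambda_a; lr <- p$lambda_r
  eps <- p$epsilon

  a_hs <- (4 * eta - 3 * eta^2) / (1 - eta)^2

  a1 <- C * (x0^la * asb(eta, la, eps, x0) - x0^lr * asb(eta, lr, eps, x0))

  alpha <- C * (1 / (la - 3) - 1 / (lr - 3))
  zx <- pi * rho * p$sigma^3 / 6         # packing fraction with sigma
  chi <- f_alpha(1, alpha) * zx + f_alpha(2, alpha) * zx^5 +
    f_alpha(3, alpha) * zx^8
  a2 <- 0.5 * k_hs(eta) * (1 + chi) * eps * C^2 *
    (x0^(2 * la) * asb(eta, 2 * la, eps, x0) -
       2 * x0^(la + lr) * asb(eta, la + lr, eps, x0) +
       x0^(2 * lr) * asb(eta, 2 * lr, eps, x0))

  a3 <- -eps^3 * f_alpha(4, alpha) * zx *
    exp(f_alpha(5, alpha) * zx + f_alpha(6, alpha) * zx^2)

  a_hs * T + a1 + a2 / T + a3 / T^2
}
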