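#' Equation-of-state models
#'
#' An `eos_model` bundles a named excess Helmholtz free energy per particle
#' \eqn{a^{ex}(\rho, T)} with its parameters.  Available kinds:
#'
#' * `ideal` -- \eqn{a^{ex} \equiv 0} (useful for exact checks),
#' * `vdw` -- van der Waals, \eqn{a^{ex} = -k_BT\ln(1-b\rho) - a\rho}
#'   (closed-form oracle),
#' * `mie` -- single-site Mie fluid via the third-order Barker-Henderson
#'   perturbation theory, optionally with a four-site association term,
#' * `mie_tdep` -- as `mie` but with polynomial temperature-dependent
#'   \eqn{\epsilon(T)} and \eqn{\sigma(T)}, valid only inside a stated
#'   temperature window.
#'
#' For single-site models the chain contribution is identically zero, so
#' \eqn{a^{ex} = a^{mono} + a^{assoc}}.
#'
#' @param a,b van der Waals constants: `a` in K nm^3, `b` in nm^3
#' @param name model name used in printing and the registry
#' @param mie a [mie_parameters()] object
#' @param assoc optional [association_parameters()]; enables association
#' @param eps_coef,sigma_coef polynomial coefficients (ascending powers of T
#'   in kelvin) for \eqn{\epsilon(T)} (K) and \eqn{\sigma(T)} (nm)
#' @param T_range length-2 numeric, the valid temperature window in kelvin
#' @return an object of class `eos_model`
#' @name eos_model
NULL

new_eos_model <- function(name, kind, ...) {
  structure(c(list(name = name, kind = kind), list(...)), class = "eos_model")
}

#' @rdname eos_model
#' @export
eos_ideal <- function(name = "ideal") {
  new_eos_model(name, "ideal", has_association = FALSE)
}

#' @rdname eos_model
#' @export
eos_vdw <- function(a, b, name = "vdw") {
  stopifnot(a >= 0, b >= 0)
  new_eos_model(name, "vdw", a = a, b = b, has_association = FALSE)
}

#' @rdname eos_model
#' @export
eos_mie <- function(mie, assoc = NULL, name = "mie") {
  stopifnot(inherits(mie, "mie_parameters"))
  if (!is.null(assoc)) stopifnot(inherits(assoc, "association_parameters"))
  new_eos_model(name, "mie", mie = mie, assoc = assoc,
                has_association = !is.null(assoc))
}

#' @rdname eos_model
#' @export
eos_mie_tdep <- function(eps_coef, sigma_coef, lambda_r, lambda_a = 6,
                         T_range, assoc = NULL, name = "mie_tdep") {
  stopifnot(length(T_range) == 2, T_range[1] < T_range[2])
  if (!is.null(assoc)) stopifnot(inherits(assoc, "association_parameters"))
  m <- new_eos_model(name, "mie_tdep",
                     eps_coef = as.numeric(eps_coef),
                     sigma_coef = as.numeric(sigma_coef),
                     lambda_r = lambda_r, lambda_a = lambda_a,
                     T_range = as.numeric(T_range), assoc = assoc,
                     has_association = !is.null(assoc))
  # fail early if the window itself yields invalid parameters
  invisible(mie_at(m, mean(T_range)))
  m
}

#' @export
print.eos_model <- function(x, ...) {
  cat("<eos_model>", x$name, paste0("(", x$kind, ")"),
      if (isTRUE(x$has_association)) "+ association" else "", "\n")
  invisible(x)
}

polyval_T <- function(coef, T) {
  drop(outer(T, seq_along(coef) - 1, `^`) %*% coef)
}

#' Mie parameters of a model at a temperature
#'
#' For `mie_tdep` models evaluates the \eqn{\epsilon(T)}, \eqn{\sigma(T)}
#' polynomials (erroring outside the valid window); for plain `mie` models
#' returns the stored parameters.
#'
#' @param model an `eos_model` of kind `mie` or `mie_tdep`
#' @param T temperature, kelvin
#' @return a [mie_parameters()] object
#' @export
mie_at <- function(model, T) {
  stopifnot(inherits(model, "eos_model"))
  if (model$kind == "mie") return(model$mie)
  if (model$kind != "mie_tdep") stop("model has no Mie parameters")
  if (T < model$T_range[1] || T > model$T_range[2]) {
    stop(sprintf("T = %.6g K outside the valid range [%g, %g] K of model '%s'",
                 T, model$T_range[1], model$T_range[2], model$name))
  }
  mie_parameters(epsilon = polyval_T(model$eps_coef, T),
                 sigma = polyval_T(model$sigma_coef, T),
                 lambda_r = model$lambda_r, lambda_a = model$lambda_a)
}

#' van der Waals excess free energy (closed form)
#'
#' \deqn{a^{ex} = -k_B T \ln(1 - b\rho) - a\rho,} the analytic oracle used
#' throughout the test suite.
#'
#' @param rho number density, nm^-3 (vectorised); requires \eqn{b\rho < 1}
#' @param T temperature, kelvin
#' @param a,b van der Waals constants (K nm^3 and nm^3)
#' @return excess free energy per particle, kelvin
#' @export
vdw_a_excess <- function(rho, T, a, b) {
  if (any(rho < 0)) stop("rho must be non-negative")
  if (any(b * rho >= 1)) stop("b*rho must be below 1 (excluded-volume bound)")
  -T * log1p(-b * rho) - a * rho
}

#' Excess Helmholtz free energy per particle
#'
#' Dispatches to the model's free-energy function:
#' monomer (plus association where enabled) for Mie-based models, the closed
#' form for `vdw`, zero for `ideal`.  Satisfies \eqn{a^{ex}(0, T) = 0} for
#' every model.
#'
#' @param rho number density, nm^-3 (vectorised)
#' @param T temperature, kelvin
#' @param model an [eos_model]
#' @return excess free energy per particle, kelvin
#' @export
a_excess <- function(rho, T, model) {
  stopifnot(inherits(model, "eos_model"), T > 0)
  switch(model$kind,
    ideal = rep(0, length(rho)),
    vdw = vdw_a_excess(rho, T, model$a, model$b),
    mie = ,
    mie_tdep = {
      mie <- mie_at(model, T)
      out <- a_mono(rho, T, mie)
      if (isTRUE(model$has_association)) {
        out <- out + a_assoc(rho, T, model$assoc, mie)
      }
      out
    },
    stop("unknown model kind: ", model$kind)
  )
}

# Maximum density the model supports (used for brackets and lookup tables)
rho_max_model <- function(model, T) {
  switch(model$kind,
    ideal = 200,
    vdw = 0.97 / model$b,
    mie = ,
    mie_tdep = {
      d <- bh_diameter(T, mie_at(model, T))
      6 * 0.70 / (pi * d^3)
    })
}

# d a^ex / d rho.  Analytic for ideal/vdw; five-point central stencil for
# the perturbation models (step scaled to the density, O(h^4) error).
da_excess_drho <- function(rho, T, model) {
  switch(model$kind,
    ideal = rep(0, length(rho)),
    vdw = model$b * T / (1 - model$b * rho) - model$a,
    {
      h <- pmax(rho, 1e-3 * rho_max_model(model, T)) * 1e-4
      h <- pmin(h, pmax(rho_max_model(model, T) - rho, 1e-12) / 2.5)
      f <- function(x) a_excess(pmax(x, 0), T, model)
      (-f(rho + 2 * h) + 8 * f(rho + h) - 8 * f(rho - h) + f(rho - 2 * h)) /
        (12 * h)
    })
}

#' Pressure from an equation of state
#'
#' Thermodynamic identity \eqn{p = \rho k_B T + \rho^2 \partial a^{ex} /
#' \partial\rho}.  Exact for the ideal and van der Waals models; for the
#' Mie-based models the density derivative uses a high-order finite-difference
#' stencil.
#'
#' @inheritParams a_excess
#' @return pressure in K nm^-3 (multiply by [pressure_to_MPa()] for MPa)
#' @export
pressure_from_eos <- function(rho, T, model) {
  stopifnot(inherits(model, "eos_model"), T > 0)
  rho * T + rho^2 * da_excess_drho(rho, T, model)
}

# Chemical potential up to the temperature-dependent ideal constant
# (common to both phases, so it cancels in coexistence conditions)
mu_from_eos <- function(rho, T, model) {
  T * log(rho) + a_excess(rho, T, model) + rho * da_excess_drho(rho, T, model)
}

#' Isothermal compressibility from an equation of state
#'
#' \deqn{\beta_T = \frac{1}{\rho\,\partial p/\partial\rho}} at a mechanically
#' stable state (\eqn{\partial p/\partial\rho > 0}).
#'
#' @inheritParams a_excess
#' @return compressibility in (K nm^-3)^-1; see [beta_to_per_MPa()]
#' @export
compressibility_from_eos <- function(rho, T, model) {
  stopifnot(inherits(model, "eos_model"), T > 0, rho > 0)
  dpdrho <- switch(model$kind,
    ideal = rep(T, length(rho)),
    vdw = T / (1 - model$b * rho)^2 - 2 * model$a * rho,
    {
      h <- rho * 1e-4
      (-pressure_from_eos(rho + 2 * h, T, model) +
         8 * pressure_from_eos(rho + h, T, model) -
         8 * pressure_from_eos(rho - h, T, model) +
         pressure_from_eos(rho - 2 * h, T, model)) / (12 * h)
    })
  if (any(dpdrho <= 0)) {
    stop("mechanically unstable state: dp/drho <= 0 (inside the spinodal)")
  }
  1 / (rho * dpdrho)
}

# Locate the spinodal densities (local extrema of p(rho)) on a dense grid.
# Returns NULL when p is monotone (no two-phase region at this T).
spinodal_scan <- function(T, model, n = 600) {
  rmax <- 0.98 * rho_max_model(model, T)
  grid <- rmax * (seq_len(n) / n)^2        # denser at low density
  p <- pressure_from_eos(grid, T, model)
  dp <- diff(p)
  dec <- which(dp < 0)
  if (length(dec) == 0) return(NULL)
  i_hi <- dec[1]                           # vapour spinodal: first decrease
  inc_after <- which(dp > 0 & seq_along(dp) > i_hi)
  if (length(inc_after) == 0) return(NULL)
  i_lo <- inc_after[1]                     # liquid spinodal: van der Waals loop ends
  list(rho_sv = grid[i_hi], rho_sl = grid[i_lo],
       p_max = p[i_hi], p_min = p[i_lo], grid = grid, p = p)
}

#' Vapour-liquid coexistence of an equation of state
#'
#' Solves for equal pressure and equal chemical potential in the two phases by
#' a nested iteration: for a trial pressure the vapour and liquid density
#' roots of \eqn{p(\rho) = p} are found inside brackets delimited by a
#' spinodal scan, then the pressure is adjusted until the chemical potentials
#' match (relative tolerance `tol`).
#'
#' @param T temperature, kelvin
#' @param model an [eos_model]
#' @param tol relative tolerance on the coexistence conditions
#' @param n_scan grid resolution of the spinodal scan that brackets the
#'   density roots; the converged solution is insensitive to it
#' @return an object of class `vle_result`: list with `rho_l`, `rho_v`,
#'   `p_v` (internal units), `T`, and `supercritical`.  When no two-phase
#'   solution exists (at or above the critical point, or for the ideal model)
#'   `supercritical` is `TRUE` and the densities are `NA`.
#' @export
solve_vle <- function(T, model, tol = 1e-8, n_scan = 600) {
  stopifnot(inherits(model, "eos_model"), T > 0)
  sup <- function() structure(list(T = T, rho_l = NA_real_, rho_v = NA_real_,
                                   p_v = NA_real_, supercritical = TRUE),
                              class = "vle_result")
  if (model$kind == "ideal") return(sup())
  sp <- spinodal_scan(T, model, n = n_scan)
  if (is.null(sp) || sp$p_max <= 0) return(sup())

  p_lo <- max(sp$p_min, 0) * (1 + 1e-10) + sp$p_max * 1e-10
  p_hi <- sp$p_max * (1 - 1e-10)
  rmax <- rho_max_model(model, T)

  root_rho <- function(p, lower, upper) {
    stats::uniroot(function(r) pressure_from_eos(r, T, model) - p,
                   lower = lower, upper = upper, tol = tol * upper * 1e-3,
                   extendInt = "no")$root
  }
  dmu <- function(p) {
    rv <- root_rho(p, lower = p / T * 1e-6, upper = sp$rho_sv)
    rl <- root_rho(p, lower = sp$rho_sl, upper = rmax)
    mu_from_eos(rl, T, model) - mu_from_eos(rv, T, model)
  }
  f_lo <- dmu(p_lo); f_hi <- dmu(p_hi)
  if (f_lo * f_hi > 0) return(sup())     # extremely close to critical
  p_v <- stats::uniroot(dmu, lower = p_lo, upper = p_hi,
                        f.lower = f_lo, f.upper = f_hi,
                        tol = tol * p_hi)$root
  rho_v <- root_rho(p_v, lower = p_v / T * 1e-6, upper = sp$rho_sv)
  rho_l <- root_rho(p_v, lower = sp$rho_sl, upper = rmax)
  structure(list(T = T, rho_l = rho_l, rho_v = rho_v, p_v = p_v,
                 supercritical = FALSE),
            class = "vle_result")
}

#' @export
print.vle_result <- function(x, ...) {
  if (x$supercritical) {
    cat("<vle_result> T =", x$T, "K: supercritical (no two-phase solution)\n")
  } else {
    cat(sprintf(
      "<vle_result> T = %g K: rho_l = %.6g nm^-3 (%.4g kg/m^3), rho_v = %.6g nm^-3, p_v = %.6g MPa\n",
      x$T, x$rho_l, rho_to_kg_m3(x$rho_l), x$rho_v, pressure_to_MPa(x$p_v)))
  }
  invisible(x)
}

#' Estimate the critical point of a model
#'
#' Bisects on temperature for the disappearance of the spinodal region and
#' reports the density at the flattest point of the near-critical isotherm.
#' Intended for setting up direct-coexistence boxes (the overall slab density
#' is chosen near critical), not for precision critical-point work.
#'
#' @param model an [eos_model]
#' @param T_lo,T_hi bracketing temperatures, kelvin
#' @param tol absolute temperature tolerance, kelvin
#' @return list with `T_c` and `rho_c`
#' @export
estimate_critical <- function(model, T_lo = 100, T_hi = 2000, tol = 0.01) {
  stopifnot(inherits(model, "eos_model"))
  if (model$kind == "vdw") {
    return(list(T_c = 8 * model$a / (27 * model$b), rho_c = 1 / (3 * model$b)))
  }
  if (model$kind == "ideal") stop("ideal model has no critical point")
  has2 <- function(T) !is.null(spinodal_scan(T, model))
  if (!has2(T_lo)) stop("T_lo is already supercritical")
  if (has2(T_hi)) stop("T_hi is still subcritical; raise it")
  while (T_hi - T_lo > tol) {
    Tm <- (T_lo + T_hi) / 2
    if (has2(Tm)) T_lo <- Tm else T_hi <- Tm
  }
  sp <- spinodal_scan(T_lo, model)
  list(T_c = (T_lo + T_hi) / 2, rho_c = (sp$rho_sv + sp$rho_sl) / 2)
}
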