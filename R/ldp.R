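#' Particle configurations
#'
#' A `configuration` holds N particle positions (nm) in a periodic
#' orthorhombic box.  Coordinates are wrapped into `[0, L)` on construction.
#'
#' @param positions N x 3 numeric matrix of coordinates, nm
#' @param box length-3 numeric, box edges (Lx, Ly, Lz) in nm; all positive
#' @return an object of class `configuration`
#' @export
configuration <- function(positions, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (nrow(positions) < 1) stop("at least one particle is required")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) {
    stop("box must be three positive edge lengths")
  }
  positions <- sweep(positions, 2, box, function(x, L) x - L * floor(x / L))
  structure(list(positions = positions, box = box), class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> N = %d, box = %.4g x %.4g x %.4g nm\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Lucy weighting function
#'
#' Compact-support kernel used to define the weighted local density,
#' \deqn{w(r) = \frac{105}{16\pi r_c^3}\left(1 + 3\frac{r}{r_c}\right)
#'   \left(1 - \frac{r}{r_c}\right)^3, \quad r < r_c,}
#' zero beyond the cutoff, normalized so \eqn{\int w(r)\,d\mathbf{r} = 1},
#' with a continuous first derivative at \eqn{r_c}.
#'
#' @param r separation, nm (vectorised, non-negative)
#' @param r_c cutoff, nm (positive)
#' @return weight density, nm^-3
#' @export
lucy_weight <- function(r, r_c) {
  if (r_c <= 0) stop("r_c must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  u <- r / r_c
  w <- 105 / (16 * pi * r_c^3) * (1 + 3 * u) * (1 - u)^3
  w[u >= 1] <- 0
  w
}

#' @rdname lucy_weight
#' @export
lucy_weight_gradient <- function(r, r_c) {
  if (r_c <= 0) stop("r_c must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  u <- r / r_c
  dw <- 105 / (16 * pi * r_c^3) * (-12) * u * (1 - u)^2 / r_c
  dw[u >= 1] <- 0
  dw
}

#' Lookup table (cubic Hermite spline) for the excess free energy
#'
#' Tabulates \eqn{a^{ex}(\rho)} of a model at fixed temperature on a uniform
#' density grid, storing values and analytic/stencil derivatives so the
#' simulation core can evaluate it by local cubic Hermite interpolation.
#' The zero-density endpoint is clamped to \eqn{a^{ex}(0) = 0}.  Mandatory
#' for temperature-dependent models (the table is per-temperature by
#' construction).
#'
#' @param model an [eos_model]
#' @param T temperature, kelvin
#' @param rho_max top of the tabulated density range, nm^-3; must exceed any
#'   density reachable in simulation (default: the model's domain bound)
#' @param n_points number of grid nodes (at least 16)
#' @return an object of class `aex_table` with elements `grid`, `value`,
#'   `deriv`, `model`, `T`, plus `fun`/`fallback` closures
#' @export
build_lookup_table <- function(model, T, rho_max = NULL, n_points = 2048L) {
  stopifnot(inherits(model, "eos_model"))
  if (n_points < 16) stop("n_points must be at least 16")
  if (is.null(rho_max)) rho_max <- 0.98 * rho_max_model(model, T)
  if (rho_max <= 0) stop("rho_max must be positive")
  grid <- seq(0, rho_max, length.out = n_points)
  value <- a_excess(grid, T, model)
  value[1] <- 0                                   # clamp a^ex(0) = 0
  deriv <- da_excess_drho(grid, T, model)
  # one-sided stencils are unreliable at the endpoints; use interior slopes
  deriv[1] <- da_excess_drho(grid[2] / 2, T, model)
  # beyond the model's density domain the free energy continues as a steep
  # linear penalty (5e3 K per nm^-3): an effectively impenetrable wall that
  # stays finite, so unequilibrated starting structures relax smoothly and
  # no Inf - Inf arithmetic can reach the estimators
  domain_max <- rho_max_model(model, T)
  a_wall <- a_excess(domain_max * (1 - 1e-9), T, model)
  fallback <- function(rho) {
    if (rho >= domain_max) return(a_wall + 5e3 * (rho - domain_max))
    a_excess(rho, T, model)
  }
  structure(list(grid = grid, value = value, deriv = deriv,
                 model = model, T = T, fallback = fallback),
            class = "aex_table")
}

# zero table used for the ideal backend / kappa-only potentials
zero_table <- function(rho_max = 200) {
  grid <- seq(0, rho_max, length.out = 16L)
  structure(list(grid = grid, value = numeric(16L), deriv = numeric(16L),
                 model = eos_ideal(), T = NA_real_,
                 fallback = function(rho) 0),
            class = "aex_table")
}

# Hermite evaluation in R (mirrors the C++ core; used by tests/observables)
eval_table <- function(tab, x) {
  n <- length(tab$grid)
  dx <- tab$grid[2] - tab$grid[1]
  out <- numeric(length(x))
  inside <- x >= tab$grid[1] & x <= tab$grid[n]
  if (any(!inside)) out[!inside] <- vapply(x[!inside], tab$fallback, numeric(1))
  xi <- x[inside]
  i <- pmin(pmax(floor((xi - tab$grid[1]) / dx), 0), n - 2)
  t <- (xi - tab$grid[1] - i * dx) / dx
  h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
  out[inside] <- h00 * tab$value[i + 1] + h10 * dx * tab$deriv[i + 1] +
    h01 * tab$value[i + 2] + h11 * dx * tab$deriv[i + 2]
  out
}

#' Potential specification
#'
#' Combines the free-energy backend, the local-density cutoff and the
#' square-gradient coefficient into the object consumed by the energy and
#' simulation routines.
#'
#' @param model an [eos_model]
#' @param r_c local-density cutoff, nm.  For Mie models the conventional
#'   choice is \eqn{r_c = 4\,\sigma(T)}; see [r_c_for_model()].
#' @param kappa square-gradient coefficient, K nm^8; `0` gives the pure
#'   local-density potential
#' @param T temperature at which lookup tables are built, kelvin (required
#'   for simulation; may be `NULL` for direct-evaluation use)
#' @param lookup optional precomputed [build_lookup_table()] result; built
#'   on demand when simulation requires it
#' @return an object of class `potential_spec`
#' @export
potential_spec <- function(model, r_c, kappa = 0, T = NULL, lookup = NULL) {
  stopifnot(inherits(model, "eos_model"))
  if (r_c <= 0) stop("r_c must be positive")
  if (kappa < 0) stop("kappa must be non-negative")
  if (!is.null(lookup)) stopifnot(inherits(lookup, "aex_table"))
  structure(list(model = model, r_c = r_c, kappa = kappa, T = T,
                 lookup = lookup),
            class = "potential_spec")
}

#' Cutoff rule for Mie-based models
#'
#' The local-density cutoff is defined relative to the Mie size parameter,
#' \eqn{r_c = m\,\sigma(T)} with `multiple` 4 by default; for
#' temperature-dependent models it therefore changes with temperature.
#'
#' @param model an [eos_model] of kind `mie` or `mie_tdep`
#' @param T temperature, kelvin
#' @param multiple cutoff in units of sigma (default 4)
#' @return cutoff in nm
#' @export
r_c_for_model <- function(model, T, multiple = 4) {
  multiple * mie_at(model, T)$sigma
}

check_box_rc <- function(config, r_c) {
  if (min(config$box) < 2 * r_c) {
    stop(sprintf(
      "minimum box edge %.4g nm is below 2*r_c = %.4g nm: minimum image invalid",
      min(config$box), 2 * r_c))
  }
}

spec_table <- function(spec) {
  if (!is.null(spec$lookup)) return(spec$lookup)
  if (spec$model$kind == "ideal") return(zero_table())
  if (is.null(spec$T)) {
    stop("potential_spec needs T (or a prebuilt lookup) for table evaluation")
  }
  build_lookup_table(spec$model, spec$T)
}

#' Weighted local densities and their gradients
#'
#' For every particle computes \eqn{\bar\rho_i = \sum_{j\ne i} w(r_{ij})} and
#' \eqn{\nabla\bar\rho_i = \sum_{j\ne i} w'(r_{ij})\,\hat r_{ij}} (unit vector
#' from j to i), with minimum-image periodic distances.  The self term is
#' excluded, so an isolated particle has zero local density and behaves
#' ideally.
#'
#' @param config a [configuration()]
#' @param r_c cutoff, nm; the minimum box edge must be at least `2 * r_c`
#' @return an object of class `local_density_field`: list with `rho_bar`
#'   (length N, nm^-3) and `grad_rho` (N x 3, nm^-4)
#' @export
compute_local_densities <- function(config, r_c) {
  stopifnot(inherits(config, "configuration"))
  check_box_rc(config, r_c)
  out <- .cpp_local_density(config$positions, config$box, r_c)
  structure(out, class = "local_density_field")
}

#' Total potential energy of a configuration
#'
#' The local-density potential with square-gradient correction:
#' \deqn{U = \sum_i a^{ex}(\bar\rho_i) +
#'   \frac{\kappa}{2}\sum_i |\nabla\bar\rho_i|^2.}
#' With `kappa = 0` this is the pure local-density potential; with the ideal
#' backend and `kappa = 0` it is identically zero.
#'
#' @param config a [configuration()]
#' @param spec a [potential_spec()]
#' @param use_lookup evaluate \eqn{a^{ex}} through the Hermite lookup table
#'   (the path the simulation engine uses) instead of direct EoS evaluation
#' @param T temperature for direct evaluation, kelvin; defaults to `spec$T`
#' @return potential energy, kelvin
#' @export
total_energy <- function(config, spec, use_lookup = FALSE, T = spec$T) {
  stopifnot(inherits(config, "configuration"), inherits(spec, "potential_spec"))
  check_box_rc(config, spec$r_c)
  field <- compute_local_densities(config, spec$r_c)
  if (use_lookup) {
    aex <- eval_table(spec_table(spec), field$rho_bar)
  } else {
    if (spec$model$kind == "ideal") {
      aex <- numeric(length(field$rho_bar))
    } else {
      if (is.null(T)) stop("temperature required: set spec$T or pass T")
      aex <- a_excess(field$rho_bar, T, spec$model)
    }
  }
  sum(aex) + spec$kappa / 2 * sum(field$grad_rho^2)
}

#' Incremental energy change of a single-particle move
#'
#' Energy difference produced by moving particle `i` to `new_position`,
#' computed from local updates only: the particles whose minimum-image
#' distance to the old or new position of `i` is below the cutoff have their
#' weighted density, gradient and energy terms re-evaluated; everything else
#' is untouched.  Agrees with a full before/after recomputation of
#' [total_energy()] to near machine precision.
#'
#' @param config a [configuration()]
#' @param field the current [compute_local_densities()] result for `config`
#' @param i particle index (1-based)
#' @param new_position length-3 numeric, nm (wrapped into the box)
#' @param spec a [potential_spec()]
#' @param T temperature for direct evaluation; defaults to `spec$T`
#' @return energy change, kelvin
#' @export
delta_energy_move <- function(config, field, i, new_position, spec,
                              T = spec$T) {
  stopifnot(inherits(config, "configuration"),
            inherits(spec, "potential_spec"))
  n <- nrow(config$positions)
  if (i < 1 || i > n) stop("particle index out of range")
  if (length(field$rho_bar) != n) {
    stop("field inconsistent with configuration")
  }
  box <- config$box
  aex <- function(rho) {
    if (spec$model$kind == "ideal") return(numeric(length(rho)))
    if (is.null(T)) stop("temperature required: set spec$T or pass T")
    a_excess(rho, T, spec$model)
  }
  wrap <- function(x) x - box * floor(x / box)
  newp <- wrap(as.numeric(new_position))
  oldp <- config$positions[i, ]

  minim <- function(d) d - box * round(d / box)
  others <- setdiff(seq_len(n), i)
  po <- config$positions[others, , drop = FALSE]
  d_old <- t(apply(sweep(po, 2, oldp, `-`), 1, minim))
  d_new <- t(apply(sweep(po, 2, newp, `-`), 1, minim))
  r_old <- sqrt(rowSums(d_old^2))
  r_new <- sqrt(rowSums(d_new^2))
  rc <- spec$r_c

  w_old <- lucy_weight(pmin(r_old, rc), rc) * (r_old < rc)
  w_new <- lucy_weight(pmin(r_new, rc), rc) * (r_new < rc)
  dw_old <- lucy_weight_gradient(pmin(r_old, rc), rc) * (r_old < rc)
  dw_new <- lucy_weight_gradient(pmin(r_new, rc), rc) * (r_new < rc)

  # unit vectors from i to j (rows of d_* are r_j - r_i)
  u_old <- d_old / ifelse(r_old > 0, r_old, 1)
  u_new <- d_new / ifelse(r_new > 0, r_new, 1)

  touched <- which(r_old < rc | r_new < rc)
  kap <- spec$kappa

  rho_i_new <- sum(w_new)
  # grad rho_i uses unit vectors from j to i = -u
  gi_new <- -colSums(u_new * dw_new)
  gi_old <- field$grad_rho[i, ]
  dU <- aex(rho_i_new) - aex(field$rho_bar[i]) +
    kap / 2 * (sum(gi_new^2) - sum(gi_old^2))

  for (t in touched) {
    j <- others[t]
    rho_j_new <- field$rho_bar[j] + (w_new[t] - w_old[t])
    gj_new <- field$grad_rho[j, ] + (dw_new[t] * u_new[t, ] -
                                       dw_old[t] * u_old[t, ])
    dU <- dU + aex(rho_j_new) - aex(field$rho_bar[j]) +
      kap / 2 * (sum(gj_new^2) - sum(field$grad_rho[j, ]^2))
  }
  dU
}

# energy of an arbitrary (positions, box) pair through the lookup table;
# used by the ghost-perturbation estimators
energy_raw <- function(positions, box, spec, tab = spec_table(spec)) {
  out <- .cpp_total_energy(positions, box, spec$r_c, spec$kappa,
                           tab$grid, tab$value, tab$deriv, tab$fallback)
  out$U
}
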