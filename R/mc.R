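#' Simulation protocol
#'
#' Ensemble, state point, move sizes and run lengths for a Monte Carlo run.
#' A cycle is defined as N attempts to displace a particle; in the NpT
#' ensemble one volume move (a random walk in \eqn{\ln V} with isotropic
#' rescaling) is additionally attempted per cycle.  Displacement step sizes
#' adapt towards `target_acceptance` during equilibration only and are frozen
#' for production.
#'
#' @param ensemble `"nvt"` or `"npt"`
#' @param T temperature, kelvin
#' @param p pressure in K nm^-3 (NpT only); see [MPa_to_pressure()]
#' @param n_equil_cycles,n_prod_cycles non-negative cycle counts; with zero
#'   production cycles the initial configuration is returned unchanged
#' @param max_displacement initial maximum displacement, nm
#' @param max_lnV_step maximum ln-volume step (NpT)
#' @param target_acceptance adaptation target for displacement moves
#' @param adapt_every adaptation interval in cycles (equilibration only)
#' @param sample_every production frame-sampling stride in cycles
#' @param seed integer RNG seed; identical seed and protocol give a
#'   bit-identical trajectory
#' @return an object of class `simulation_protocol`
#' @export
simulation_protocol <- function(ensemble = c("nvt", "npt"), T, p = NA_real_,
                                n_equil_cycles = 1000L,
                                n_prod_cycles = 2000L,
                                max_displacement = 0.3,
                                max_lnV_step = 0.02,
                                target_acceptance = 0.35,
                                adapt_every = 100L,
                                sample_every = 10L,
                                seed = 1L) {
  ensemble <- match.arg(ensemble)
  if (T <= 0) stop("T must be positive")
  if (ensemble == "npt" && (!is.finite(p) || p <= 0)) {
    stop("NpT requires a positive pressure")
  }
  if (n_prod_cycles < 0 || n_equil_cycles < 0) {
    stop("cycle counts must be non-negative")
  }
  structure(list(ensemble = ensemble, T = T, p = p,
                 n_equil_cycles = as.integer(n_equil_cycles),
                 n_prod_cycles = as.integer(n_prod_cycles),
                 max_displacement = max_displacement,
                 max_lnV_step = max_lnV_step,
                 target_acceptance = target_acceptance,
                 adapt_every = as.integer(adapt_every),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "simulation_protocol")
}

#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability \eqn{\min(1, e^{-\Delta U/k_BT}}).
#' Draws one uniform variate from the R RNG stream only when the move is
#' uphill.
#'
#' @param delta_U energy change, kelvin
#' @param T temperature, kelvin
#' @return logical: accepted?
#' @export
metropolis_accept <- function(delta_U, T) {
  if (T <= 0) stop("T must be positive")
  if (is.nan(delta_U)) stop("delta_U is NaN")
  if (delta_U <= 0) return(TRUE)
  if (is.infinite(delta_U)) return(FALSE)
  stats::runif(1) < exp(-delta_U / T)
}

run_mc_common <- function(config, spec, protocol) {
  stopifnot(inherits(config, "configuration"),
            inherits(spec, "potential_spec"),
            inherits(protocol, "simulation_protocol"))
  check_box_rc(config, spec$r_c)
  if (!is.null(spec$T) && !is.na(spec$T) && abs(spec$T - protocol$T) > 1e-9) {
    stop("potential_spec and protocol disagree on temperature")
  }
  if (is.null(spec$T)) spec$T <- protocol$T
  tab <- spec_table(spec)
  set.seed(protocol$seed)
  res <- .cpp_run_mc(config$positions, config$box, spec$r_c, spec$kappa,
                     tab$grid, tab$value, tab$deriv, tab$fallback,
                     protocol$T, protocol$ensemble == "npt",
                     ifelse(is.na(protocol$p), 0, protocol$p),
                     protocol$n_equil_cycles, protocol$n_prod_cycles,
                     protocol$max_displacement, protocol$max_lnV_step,
                     protocol$adapt_every, protocol$target_acceptance,
                     protocol$sample_every, 0L)
  frames <- lapply(seq_along(res$frames), function(k) {
    configuration(res$frames[[k]], res$frame_boxes[[k]])
  })
  n <- nrow(config$positions)
  obs <- list(
    u_series = res$u_series,
    v_series = res$v_series,
    rho_series = n / res$v_series,
    acceptance_displacement = res$acc_disp,
    acceptance_volume = res$acc_vol,
    n_rejected_small_box = res$n_rejected_small_box,
    n_lookup_fallback = res$n_fallback,
    max_displacement_final = res$max_disp_final,
    max_rho_dev = res$max_rho_dev,
    max_grad_dev = res$max_grad_dev,
    U_final = res$U,
    U_recomputed = res$U_recomputed,
    T = protocol$T, p = protocol$p, N = n, seed = protocol$seed)
  structure(list(config = configuration(res$positions, res$box),
                 observables = obs, frames = frames,
                 spec = spec, protocol = protocol),
            class = "mc_result")
}

#' Canonical (NVT) Monte Carlo run
#'
#' Metropolis displacement sampling of the local-density potential at fixed
#' N, V, T.  Energy bookkeeping is incremental; the cached total energy is
#' checked against a from-scratch recomputation at the end of the run (see
#' `observables$U_final` vs `observables$U_recomputed`).
#'
#' @param config starting [configuration()]
#' @param spec a [potential_spec()]
#' @param protocol a [simulation_protocol()] with `ensemble = "nvt"`
#' @return an object of class `mc_result`: final `config`, `observables`
#'   (energy series, acceptance rates, bookkeeping checks), and sampled
#'   `frames`
#' @export
run_nvt <- function(config, spec, protocol) {
  if (protocol$ensemble != "nvt") stop("protocol is not NVT")
  run_mc_common(config, spec, protocol)
}

#' Isothermal-isobaric (NpT) Monte Carlo run
#'
#' As [run_nvt()] plus one volume move per cycle: a symmetric random walk in
#' \eqn{\ln V} with isotropic rescaling of positions, accepted with
#' probability \eqn{\min(1, \exp(-[\Delta U + p\Delta V -
#' (N+1)k_BT\ln(V'/V)]/k_BT))}.  Moves that would shrink an edge below
#' \eqn{2 r_c} are rejected and counted.  The volume series is recorded every
#' production cycle.
#'
#' @inheritParams run_nvt
#' @param protocol a [simulation_protocol()] with `ensemble = "npt"` and a
#'   positive pressure
#' @return an `mc_result`; `observables$v_series` holds the volume series
#' @export
run_npt <- function(config, spec, protocol) {
  if (protocol$ensemble != "npt") stop("protocol is not NpT")
  run_mc_common(config, spec, protocol)
}

#' @export
print.mc_result <- function(x, ...) {
  o <- x$observables
  cat(sprintf(
    "<mc_result> %s, N = %d, T = %g K: <U>/N = %.5g K, acc(disp) = %.2f%s\n",
    toupper(x$protocol$ensemble), o$N, o$T, mean(o$u_series) / o$N,
    o$acceptance_displacement,
    if (!is.na(o$acceptance_volume))
      sprintf(", acc(vol) = %.2f", o$acceptance_volume) else ""))
  invisible(x)
}

# block averaging: mean and its standard error from n_blocks contiguous blocks
block_stats <- function(x, n_blocks = 20L) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(2L, n %/% 2L)
  if (n < 2) return(list(mean = mean(x), se = NA_real_, n_blocks = 1L))
  size <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  list(mean = mean(means), se = stats::sd(means) / sqrt(n_blocks),
       n_blocks = n_blocks)
}
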