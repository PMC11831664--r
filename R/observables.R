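#' Density profile along z
#'
#' Frame-averaged histogram of particle number density along the interface
#' normal.  Each frame conserves N exactly (every particle lands in one bin).
#'
#' @param frames list of [configuration()] frames (at least one); boxes must
#'   share Lx, Ly and Lz across frames (NVT sampling)
#' @param n_bins number of z bins (at least 10)
#' @return an object of class `density_profile`: `z` (bin centres, nm),
#'   `rho` (mean density per bin, nm^-3), `n_bins`, `box`, `n_frames`
#' @export
density_profile <- function(frames, n_bins = 100L) {
  if (length(frames) < 1) stop("at least one frame is required")
  if (n_bins < 10) stop("n_bins must be at least 10")
  box <- frames[[1]]$box
  for (f in frames) {
    if (max(abs(f$box - box)) > 1e-9 * max(box)) {
      stop("frames disagree on the box; density_profile expects NVT frames")
    }
  }
  dz <- box[3] / n_bins
  counts <- numeric(n_bins)
  for (f in frames) {
    idx <- pmin(floor(f$positions[, 3] / dz), n_bins - 1) + 1
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  rho <- counts / (length(frames) * box[1] * box[2] * dz)
  structure(list(z = (seq_len(n_bins) - 0.5) * dz, rho = rho,
                 n_bins = as.integer(n_bins), box = box,
                 n_frames = length(frames)),
            class = "density_profile")
}

# symmetric double-tanh slab profile used for the coexistence fit
slab_profile_fn <- function(z, rho_v, rho_l, z1, z2, w) {
  rho_v + (rho_l - rho_v) / 2 * (tanh((z - z1) / w) - tanh((z - z2) / w))
}

#' Coexistence densities from a density profile
#'
#' Fits the symmetric double-tanh slab form
#' \deqn{\rho(z) = \rho_v + \frac{\rho_l-\rho_v}{2}
#'   \left[\tanh\frac{z-z_1}{w} - \tanh\frac{z-z_2}{w}\right]}
#' (the slab is recentred first so it does not straddle the periodic
#' boundary), then reports plateau densities by averaging the bins that lie
#' deeper than the 10-90 interface bounds of the fit.  A profile without
#' two-plateau structure yields a "no coexistence" result rather than
#' numbers.
#'
#' @param profile a [density_profile()]
#' @return an object of class `coexistence_result`: `rho_l`, `rho_v`
#'   (nm^-3), `rho_l_kg_m3`, `rho_v_kg_m3`, `interface_width` (nm, the tanh
#'   width parameter), `fit` diagnostics (residual RMS, convergence), and
#'   `coexisting` flag
#' @export
coexistence_densities <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z; rho <- profile$rho
  no_coex <- function(reason) {
    structure(list(coexisting = FALSE, reason = reason,
                   rho_l = NA_real_, rho_v = NA_real_,
                   rho_l_kg_m3 = NA_real_, rho_v_kg_m3 = NA_real_,
                   interface_width = NA_real_, fit = NULL),
              class = "coexistence_result")
  }
  span <- max(rho) - min(rho)
  if (span < 0.25 * max(mean(rho), 1e-12)) {
    return(no_coex("profile is flat: single phase or supercritical"))
  }
  # recentre: roll the profile so the dense slab sits in the middle
  nb <- length(z)
  com_shift <- which.max(stats::filter(rep(rho, 2), rep(1, nb %/% 4),
                                       sides = 2)[seq_len(nb)])
  shift <- (nb %/% 2) - com_shift
  rho_c <- rho[((seq_len(nb) - 1 - shift) %% nb) + 1]

  hi <- stats::quantile(rho_c, 0.9); lo <- stats::quantile(rho_c, 0.1)
  above <- which(rho_c > (hi + lo) / 2)
  if (length(above) < 3 || length(above) > nb - 3) {
    return(no_coex("no two-plateau structure"))
  }
  dz <- z[2] - z[1]
  start <- list(rho_v = as.numeric(lo), rho_l = as.numeric(hi),
                z1 = z[min(above)] - dz / 2, z2 = z[max(above)] + dz / 2,
                w = max(2 * dz, diff(range(z)) / 20))
  # warnOnly: near-degenerate profiles may stall the optimizer after the
  # parameters have converged; the fit is still usable and diagnostics are
  # reported, so the iteration warning is not surfaced
  fit <- try(suppressWarnings(
    stats::nls(rho_c ~ slab_profile_fn(z, rho_v, rho_l, z1, z2, w),
               start = start,
               control = stats::nls.control(maxiter = 1000,
                                            warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(no_coex("tanh fit failed"))
  cf <- as.list(stats::coef(fit))
  if (!(cf$rho_l > cf$rho_v) || cf$z2 <= cf$z1 || cf$w <= 0) {
    return(no_coex("fit did not resolve two plateaus"))
  }
  # 10-90 bounds of tanh: |z - z0| > w * atanh(0.8) is "deeper than" the
  # interface region
  margin <- cf$w * atanh(0.8)
  liq <- z > cf$z1 + margin & z < cf$z2 - margin
  vap <- z < cf$z1 - margin | z > cf$z2 + margin
  if (sum(liq) < 1 || sum(vap) < 1) {
    return(no_coex("interfaces overlap: no bulk region left"))
  }
  # plateau = fitted plateau + mean residual over the deep bins: exact for a
  # noiseless profile (bins at the 10-90 edge still carry ~1% tanh shoulder,
  # which raw averaging would fold in) while retaining the noise averaging
  # of the bins
  shape <- slab_profile_fn(z, cf$rho_v, cf$rho_l, cf$z1, cf$z2, cf$w)
  rho_l <- cf$rho_l + mean(rho_c[liq] - shape[liq])
  rho_v <- cf$rho_v + mean(rho_c[vap] - shape[vap])
  resid <- sqrt(mean(stats::resid(fit)^2))
  structure(list(coexisting = TRUE, reason = NULL,
                 rho_l = rho_l, rho_v = max(rho_v, 0),
                 rho_l_kg_m3 = rho_to_kg_m3(rho_l),
                 rho_v_kg_m3 = rho_to_kg_m3(max(rho_v, 0)),
                 interface_width = cf$w,
                 fit = list(coef = cf, rms_residual = resid,
                            n_bins_liquid = sum(liq),
                            n_bins_vapour = sum(vap))),
            class = "coexistence_result")
}

#' @export
print.coexistence_result <- function(x, ...) {
  if (!x$coexisting) {
    cat("<coexistence_result> no coexistence:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<coexistence_result> rho_l = %.5g nm^-3 (%.4g kg/m^3), rho_v = %.5g nm^-3 (%.4g kg/m^3), width = %.3g nm\n",
      x$rho_l, x$rho_l_kg_m3, x$rho_v, x$rho_v_kg_m3, x$interface_width))
  }
  invisible(x)
}

#' Test-area settings
#'
#' @param xi dimensionless fractional area perturbation (default 5e-4);
#'   must be small and positive.  Estimates should be checked for
#'   xi-insensitivity by halving (see [test_area_gamma()]'s
#'   `check_convergence`).
#' @return an object of class `test_area_settings`
#' @export
test_area_settings <- function(xi = 5e-4) {
  if (xi <= 0 || xi >= 0.1) stop("xi must be in (0, 0.1)")
  structure(list(xi = xi), class = "test_area_settings")
}

#' Test-volume settings
#'
#' @param zeta dimensionless volume perturbation Delta V / V (default 1e-4);
#'   strictly positive (both expansion and compression are evaluated)
#' @param alpha perturbation direction, one of `"x"`, `"y"`, `"z"`
#' @return an object of class `test_volume_settings`
#' @export
test_volume_settings <- function(zeta = 1e-4, alpha = c("z", "x", "y")) {
  if (zeta <= 0) stop("zeta must be positive")
  alpha <- match.arg(alpha)
  structure(list(zeta = zeta, alpha = alpha), class = "test_volume_settings")
}

# scale a frame for an area perturbation of sign s (+1/-1) at fraction xi:
# (Lx, Ly) *= sqrt(1 + s*xi), Lz /= (1 + s*xi); box-relative positions fixed
area_perturbed <- function(config, xi, s) {
  f <- 1 + s * xi
  sc <- c(sqrt(f), sqrt(f), 1 / f)
  list(positions = sweep(config$positions, 2, sc, `*`),
       box = config$box * sc)
}

#' Surface tension by the test-area method
#'
#' Ghost (never accepted) area perturbations of each sampled slab frame:
#' the lateral edges are scaled by \eqn{\sqrt{1\pm\xi}} and the normal edge
#' by \eqn{1/(1\pm\xi)} at constant volume, positions following the box
#' affinely.  The free-energy change of each branch is
#' \eqn{\Delta A^\pm = -k_BT\ln\langle e^{-\Delta U^\pm/k_BT}\rangle} and the
#' surface tension follows from the central difference
#' \deqn{\gamma = \frac{\Delta A^+ - \Delta A^-}{2\,\Delta S_{tot}},}
#' with \eqn{\Delta S_{tot} = \xi\,S_{0,tot}} and \eqn{S_{0,tot} = 2 L_x L_y}
#' (a periodic slab has two interfaces).  Uncertainty by block averaging
#' over frames.
#'
#' @param frames list of [configuration()] slab frames (interface normal
#'   along z)
#' @param spec a [potential_spec()]
#' @param settings a [test_area_settings()]
#' @param T temperature, kelvin
#' @param check_convergence also evaluate at `xi/2` and report both
#' @param n_blocks blocks for the uncertainty estimate
#' @return an object of class `gamma_estimate`: `gamma`, `se` (K nm^-2),
#'   `gamma_mN_m`, `se_mN_m`, `xi`, and optionally `half_xi` (the `xi/2`
#'   re-estimate)
#' @export
test_area_gamma <- function(frames, spec, settings = test_area_settings(),
                            T, check_convergence = FALSE, n_blocks = 20L) {
  stopifnot(inherits(settings, "test_area_settings"), T > 0,
            length(frames) >= 1)
  tab <- spec_table(spec)
  estimate <- function(xi) {
    box0 <- frames[[1]]$box
    # per-frame Boltzmann factors for both branches
    bp <- bm <- numeric(length(frames))
    for (k in seq_along(frames)) {
      f <- frames[[k]]
      U0 <- energy_raw(f$positions, f$box, spec, tab)
      pp <- area_perturbed(f, xi, +1)
      pm <- area_perturbed(f, xi, -1)
      bp[k] <- exp(-(energy_raw(pp$positions, pp$box, spec, tab) - U0) / T)
      bm[k] <- exp(-(energy_raw(pm$positions, pm$box, spec, tab) - U0) / T)
    }
    ds_tot <- xi * 2 * box0[1] * box0[2]
    g_of <- function(mp, mm) (-T * log(mp) + T * log(mm)) / (2 * ds_tot)
    g <- g_of(mean(bp), mean(bm))
    # block the frame series jointly (the two branches are correlated)
    nb <- min(n_blocks, max(2L, length(frames) %/% 2L))
    size <- length(frames) %/% nb
    if (size >= 1 && nb >= 2) {
      gb <- vapply(seq_len(nb), function(b) {
        idx <- ((b - 1) * size + 1):(b * size)
        g_of(mean(bp[idx]), mean(bm[idx]))
      }, numeric(1))
      se <- stats::sd(gb) / sqrt(nb)
    } else se <- NA_real_
    list(gamma = g, se = se)
  }
  main <- estimate(settings$xi)
  out <- list(gamma = main$gamma, se = main$se,
              gamma_mN_m = gamma_to_mN_m(main$gamma),
              se_mN_m = gamma_to_mN_m(main$se),
              xi = settings$xi, n_frames = length(frames))
  if (check_convergence) {
    half <- estimate(settings$xi / 2)
    out$half_xi <- list(gamma = half$gamma, se = half$se)
  }
  structure(out, class = "gamma_estimate")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("<gamma_estimate> gamma = %.5g +/- %.2g K/nm^2 (%.4g +/- %.2g mN/m), xi = %g, %d frames\n",
              x$gamma, x$se, x$gamma_mN_m, x$se_mN_m, x$xi, x$n_frames))
  invisible(x)
}

#' Pressure by the test-volume method
#'
#' Ghost volume perturbations \eqn{\pm\zeta V} along one box direction
#' (positions rescaled in that direction only).  Each branch estimates the
#' normal pressure component
#' \deqn{p^{\pm}_{\alpha\alpha} = \frac{k_BT}{\pm\Delta V}
#'   \left[N\ln\frac{V_1}{V_0} +
#'   \ln\langle e^{-\Delta U^\pm/k_BT}\rangle\right]}
#' and the reported value is the central average of the expansion and
#' compression branches.  Uncertainty by block averaging over frames.
#'
#' @param frames list of [configuration()] frames of a bulk system
#' @param spec a [potential_spec()]
#' @param settings a [test_volume_settings()]
#' @param T temperature, kelvin
#' @param n_blocks blocks for the uncertainty estimate
#' @return an object of class `pressure_estimate`: `p`, `se` (K nm^-3),
#'   `p_MPa`, `se_MPa`, branch estimates `p_plus`, `p_minus`
#' @export
test_volume_pressure <- function(frames, spec,
                                 settings = test_volume_settings(), T,
                                 n_blocks = 20L) {
  stopifnot(inherits(settings, "test_volume_settings"), T > 0,
            length(frames) >= 1)
  tab <- spec_table(spec)
  k_alpha <- match(settings$alpha, c("x", "y", "z"))
  zeta <- settings$zeta
  n <- nrow(frames[[1]]$positions)
  bp <- bm <- numeric(length(frames))
  v0 <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    U0 <- energy_raw(f$positions, f$box, spec, tab)
    for (s in c(+1, -1)) {
      sc <- rep(1, 3); sc[k_alpha] <- 1 + s * zeta
      pos1 <- sweep(f$positions, 2, sc, `*`)
      box1 <- f$box * sc
      b <- exp(-(energy_raw(pos1, box1, spec, tab) - U0) / T)
      if (s > 0) bp[k] <- b else bm[k] <- b
    }
    v0[k] <- prod(f$box)
  }
  V0 <- mean(v0)
  p_of <- function(mp, mm) {
    pp <- T / (zeta * V0) * (n * log(1 + zeta) + log(mp))
    pm <- T / (-zeta * V0) * (n * log(1 - zeta) + log(mm))
    c(p = (pp + pm) / 2, p_plus = pp, p_minus = pm)
  }
  est <- p_of(mean(bp), mean(bm))
  nb <- min(n_blocks, max(2L, length(frames) %/% 2L))
  size <- length(frames) %/% nb
  se <- NA_real_
  if (size >= 1 && nb >= 2) {
    pb <- vapply(seq_len(nb), function(b) {
      idx <- ((b - 1) * size + 1):(b * size)
      p_of(mean(bp[idx]), mean(bm[idx]))[["p"]]
    }, numeric(1))
    se <- stats::sd(pb) / sqrt(nb)
  }
  structure(list(p = est[["p"]], se = se,
                 p_MPa = pressure_to_MPa(est[["p"]]),
                 se_MPa = pressure_to_MPa(se),
                 p_plus = est[["p_plus"]], p_minus = est[["p_minus"]],
                 zeta = zeta, alpha = settings$alpha,
                 n_frames = length(frames)),
            class = "pressure_estimate")
}

#' @export
print.pressure_estimate <- function(x, ...) {
  cat(sprintf("<pressure_estimate> p = %.5g +/- %.2g K/nm^3 (%.4g MPa), zeta = %g along %s\n",
              x$p, x$se, x$p_MPa, x$zeta, x$alpha))
  invisible(x)
}

#' Isothermal compressibility from NpT volume fluctuations
#'
#' \deqn{\beta_T = \frac{\langle V^2\rangle - \langle V\rangle^2}
#'   {k_B T \langle V\rangle}.}
#' Uncertainty by block averaging of the per-block fluctuation estimate.
#'
#' @param v_series volume series from an NpT run, nm^3 (length at least 100
#'   for a meaningful estimate; shorter series are accepted with a warning)
#' @param T temperature, kelvin
#' @param n_blocks blocks for the uncertainty estimate
#' @return list with `beta_T`, `se` in (K nm^-3)^-1 and `beta_T_per_MPa`
#' @export
isothermal_compressibility <- function(v_series, T, n_blocks = 20L) {
  if (T <= 0) stop("T must be positive")
  n <- length(v_series)
  if (n < 2) stop("need at least two volume samples")
  if (n < 100) warning("fewer than 100 volume samples; estimate is noisy")
  est <- function(v) (mean(v^2) - mean(v)^2) / (T * mean(v))
  beta <- est(v_series)
  nb <- min(n_blocks, max(2L, n %/% 2L))
  size <- n %/% nb
  bb <- vapply(seq_len(nb), function(b) {
    est(v_series[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  se <- stats::sd(bb) / sqrt(nb)
  list(beta_T = beta, se = se,
       beta_T_per_MPa = beta_to_per_MPa(beta),
       se_per_MPa = beta_to_per_MPa(se))
}

#' Percent absolute average deviation
#'
#' \deqn{\%AAD = \frac{100}{n}\sum_{i=1}^n
#'   \left|\frac{X^{sim}_i - X^{ref}_i}{X^{ref}_i}\right|.}
#'
#' @param sim_values,ref_values equal-length numeric vectors; reference
#'   entries must be nonzero
#' @return the %AAD (a percentage)
#' @export
#' @examples
#' percent_aad(c(1, 3), c(2, 2))  # 50
percent_aad <- function(sim_values, ref_values) {
  if (length(sim_values) != length(ref_values) || length(ref_values) < 1) {
    stop("sim and ref must have equal, positive length")
  }
  if (any(ref_values == 0)) {
    stop("reference values must be nonzero (relative deviation undefined)")
  }
  100 * mean(abs((sim_values - ref_values) / ref_values))
}
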