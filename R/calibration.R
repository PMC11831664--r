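#' Calibrate the square-gradient coefficient at one temperature
#'
#' The simulated surface tension grows approximately linearly with the
#' square-gradient coefficient \eqn{\kappa} at fixed temperature and cutoff.
#' This routine runs the supplied slab + test-area pipeline at each grid
#' value of \eqn{\kappa}, fits \eqn{\gamma = a + b\kappa} by weighted least
#' squares (weights \eqn{1/\sigma_\gamma^2} when uncertainties are
#' available), and inverts for the target:
#' \eqn{\kappa^\ast = (\gamma_{target} - a)/b}.
#'
#' @param T temperature, kelvin (recorded in the result)
#' @param gamma_target target surface tension, same units as the simulated
#'   values returned by `simulate_fn`; positive
#' @param kappa_grid at least 3 kappa values to sweep
#' @param simulate_fn function of one argument `kappa` returning a list (or
#'   named vector) with `gamma` and optionally `se`
#' @param r_squared_min linearity threshold below which the fit is flagged
#' @return an object of class `kappa_calibration_point`: `kappa_star`,
#'   `se_kappa_star`, `fit` (intercept, slope, `r_squared`), the sweep table,
#'   `extrapolated` (kappa* outside the swept grid) and `nonlinear` flags
#' @export
calibrate_kappa <- function(T, gamma_target, kappa_grid, simulate_fn,
                            r_squared_min = 0.98) {
  if (length(kappa_grid) < 3) stop("at least 3 kappa grid points are required")
  if (gamma_target <= 0) stop("gamma_target must be positive")
  res <- lapply(kappa_grid, simulate_fn)
  gamma <- vapply(res, function(r) as.numeric(r[["gamma"]]), numeric(1))
  se <- vapply(res, function(r) {
    s <- r[["se"]]
    if (is.null(s) || is.na(s)) NA_real_ else as.numeric(s)
  }, numeric(1))
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(se))
  fit <- stats::lm(gamma ~ kappa_grid, weights = w)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  if (b <= 0) {
    stop("calibration failed: fitted slope is not positive ",
         "(gamma must increase with kappa)")
  }
  r2 <- summary(fit)$r.squared
  kappa_star <- (gamma_target - a) / b
  # delta-method propagation of the (a, b) covariance
  V <- stats::vcov(fit)
  grad <- c(-1 / b, -(gamma_target - a) / b^2)
  se_k <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(
    T = T, gamma_target = gamma_target, kappa_star = kappa_star,
    se_kappa_star = se_k,
    fit = list(intercept = a, slope = b, r_squared = r2),
    sweep = data.frame(kappa = kappa_grid, gamma = gamma, se = se),
    extrapolated = kappa_star < min(kappa_grid) | kappa_star > max(kappa_grid),
    nonlinear = r2 < r_squared_min),
    class = "kappa_calibration_point")
}

#' @export
print.kappa_calibration_point <- function(x, ...) {
  cat(sprintf(
    "<kappa_calibration_point> T = %g K: kappa* = %.5g +/- %.2g (R^2 = %.4f%s%s)\n",
    x$T, x$kappa_star, x$se_kappa_star, x$fit$r_squared,
    if (x$nonlinear) ", NONLINEAR" else "",
    if (x$extrapolated) ", EXTRAPOLATED" else ""))
  invisible(x)
}

#' Cubic temperature fit of calibrated kappa values
#'
#' Least-squares cubic \eqn{\kappa(T) = c_0 + c_1 T + c_2 T^2 + c_3 T^3}
#' through per-temperature calibration points (at least 4, conventionally
#' spanning 280-520 K).  The returned object evaluates with a range warning
#' outside the fitted interval.
#'
#' @param T temperatures, kelvin (at least 4 distinct values)
#' @param kappa_star calibrated kappa values, same length
#' @return an object of class `kappa_polynomial`: `coefficients` (ascending
#'   powers), `T_range`, `residuals`, and callable via [predict()]
#' @export
fit_kappa_polynomial <- function(T, kappa_star) {
  if (length(T) != length(kappa_star)) stop("T and kappa_star lengths differ")
  if (length(unique(T)) < 4) {
    stop("at least 4 distinct temperatures are required for a cubic fit")
  }
  fit <- stats::lm(kappa_star ~ poly(T, 3, raw = TRUE))
  cf <- unname(stats::coef(fit))
  structure(list(coefficients = cf, T_range = range(T),
                 residuals = unname(stats::resid(fit)),
                 fitted = unname(stats::fitted(fit)),
                 summary = suppressWarnings(summary(fit))),
            class = "kappa_polynomial")
}

#' @rdname fit_kappa_polynomial
#' @param object a `kappa_polynomial`
#' @param newdata temperatures at which to evaluate, kelvin
#' @param ... unused
#' @export
predict.kappa_polynomial <- function(object, newdata, ...) {
  T <- as.numeric(newdata)
  if (any(T < object$T_range[1] | T > object$T_range[2])) {
    warning(sprintf("evaluating kappa(T) outside the fitted range [%g, %g] K",
                    object$T_range[1], object$T_range[2]))
  }
  polyval_T(object$coefficients, T)
}

#' @export
print.kappa_polynomial <- function(x, ...) {
  cat("<kappa_polynomial> kappa(T) =",
      paste(sprintf("%.6g*T^%d", x$coefficients, 0:3), collapse = " + "),
      sprintf("\n  fitted on [%g, %g] K, RMS residual %.3g\n",
              x$T_range[1], x$T_range[2], sqrt(mean(x$residuals^2))))
  invisible(x)
}
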