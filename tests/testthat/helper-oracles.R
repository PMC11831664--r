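# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately written without reusing the package's
# computational paths: plain double loops, quadrature, closed forms.

# water-like van der Waals fluid used across the suite:
# T_c = 647 K, rho_c = 33.33 nm^-3
VDW_A <- 27 * 0.01 * 647 / 8
VDW_B <- 0.01
vdw_water <- function() eos_vdw(VDW_A, VDW_B)

# corresponding-states sigma-equivalent (rho_c sigma^3 = 0.31) and 4-sigma
# cutoff for the vdW fluid
VDW_SIGMA_EQ <- (0.31 * 3 * VDW_B)^(1 / 3)
VDW_RC <- 4 * VDW_SIGMA_EQ

# --- brute-force local-density / energy oracle (pure R, no cell tricks) ---

oracle_min_image <- function(d, box) d - box * round(d / box)

oracle_lucy <- function(r, rc) {
  if (r >= rc) return(0)
  u <- r / rc
  105 / (16 * pi * rc^3) * (1 + 3 * u) * (1 - u)^3
}

oracle_lucy_grad <- function(r, rc) {
  if (r >= rc) return(0)
  u <- r / rc
  105 / (16 * pi * rc^3) * (-12) * u * (1 - u)^2 / rc
}

oracle_field <- function(pos, box, rc) {
  n <- nrow(pos)
  rho <- numeric(n)
  grad <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- oracle_min_image(pos[i, ] - pos[j, ], box)
      r <- sqrt(sum(d^2))
      if (r < rc) {
        rho[i] <- rho[i] + oracle_lucy(r, rc)
        if (r > 0) grad[i, ] <- grad[i, ] + oracle_lucy_grad(r, rc) * d / r
      }
    }
  }
  list(rho = rho, grad = grad)
}

oracle_energy <- function(pos, box, rc, aex_fun, kappa = 0) {
  f <- oracle_field(pos, box, rc)
  sum(vapply(f$rho, aex_fun, numeric(1))) + kappa / 2 * sum(f$grad^2)
}

# --- Maxwell equal-area construction for the van der Waals EoS -----------

# independent of the package's mu-equality route: works on p(v) with the
# analytic vdW isotherm and equal-area integral by quadrature
oracle_vdw_maxwell <- function(T, a, b) {
  p_of_v <- function(v) T / (v - b) - a / v^2
  # spinodal in v from dp/dv = 0
  dp <- function(v) -T / (v - b)^2 + 2 * a / v^3
  v_sp_l <- uniroot(dp, c(b * 1.001, 3 * b))$root
  v_sp_v <- uniroot(dp, c(3 * b, 5000 * b))$root
  p_lo <- max(p_of_v(v_sp_l), 1e-12)
  p_hi <- p_of_v(v_sp_v)
  # equal-area condition with the analytic antiderivative of the isotherm,
  # int p dv = T ln(v - b) + a/v  (avoids cancellation between the lobes)
  area <- function(p) {
    v_l <- uniroot(function(v) p_of_v(v) - p, c(b * 1.0001, v_sp_l),
                   tol = 1e-14)$root
    v_v <- uniroot(function(v) p_of_v(v) - p,
                   c(v_sp_v, max(10 * T / p, v_sp_v * 1.01)),
                   tol = 1e-13)$root
    T * log((v_v - b) / (v_l - b)) + a * (1 / v_v - 1 / v_l) -
      p * (v_v - v_l)
  }
  p_star <- uniroot(area, c(p_lo * 1.0001, p_hi * 0.9999), tol = 1e-13)$root
  v_l <- uniroot(function(v) p_of_v(v) - p_star, c(b * 1.0001, v_sp_l),
                 tol = 1e-14)$root
  v_v <- uniroot(function(v) p_of_v(v) - p_star,
                 c(v_sp_v, max(10 * T / p_star, v_sp_v * 1.01)),
                 tol = 1e-13)$root
  list(rho_l = 1 / v_l, rho_v = 1 / v_v, p_v = p_star)
}

# --- misc ----------------------------------------------------------------

random_config <- function(n, box, seed) {
  set.seed(seed)
  configuration(matrix(runif(3 * n) * rep(box, each = n), ncol = 3), box)
}

PROP_SEED <- 424242L  # fixed seed for property loops
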