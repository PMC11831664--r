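# Equation-of-state layer: Mie potential, monomer perturbation term,
# association closure, dispatch, and the bulk-property solvers.

test_that("Mie potential: zero at sigma, LJ minimum, numerical minimum", {
  p_lj <- mie_parameters(epsilon = 1, sigma = 1, lambda_r = 12, lambda_a = 6)
  expect_equal(mie_potential(1, p_lj), 0)
  expect_equal(mie_potential(2^(1 / 6), p_lj), -1, tolerance = 1e-12)

  # lambda_r = 8: minimum location/depth against 1-D numerical minimization
  p8 <- mie_parameters(epsilon = 266, sigma = 0.3, lambda_r = 8, lambda_a = 6)
  opt <- optimize(function(r) mie_potential(r, p8), c(0.2, 1.2), tol = 1e-12)
  # analytic minimum of the Mie form: r_min = (lr/la)^(1/(lr-la)) sigma
  r_min <- (8 / 6)^(1 / 2) * 0.3
  expect_equal(opt$minimum, r_min, tolerance = 1e-7)
  expect_equal(opt$objective, -266, tolerance = 1e-9)

  expect_error(mie_potential(0, p_lj), "positive")
  expect_error(mie_parameters(1, 1, 6, 8), "lambda_r > lambda_a")
  expect_error(mie_parameters(-1, 1, 12, 6), "epsilon")
})

test_that("monomer term: zero-density and zero-epsilon limits, smoothness", {
  p <- mie_parameters(300, 0.3, 12, 6)
  expect_equal(a_mono(0, 400, p), 0)
  p0 <- p; p0$epsilon <- 0
  expect_equal(a_mono(c(0, 5, 20), 400, p0), c(0, 0, 0))
  expect_error(a_mono(1e4, 400, p), "packing")
  # smooth, finite values over a density sweep
  rho <- seq(0, 35, length.out = 50)
  a <- a_mono(rho, 400, p)
  expect_true(all(is.finite(a)))
})

test_that("pressure route is consistent with a central-difference derivative
           of the monomer free energy to 6 significant figures", {
  model <- eos_mie(mie_parameters(266.68, 0.30555, 17.02, 6))
  T <- 450
  rho <- c(0.5, 2, 8, 20, 30)
  p_impl <- pressure_from_eos(rho, T, model)
  # independent central difference of rho * a_ex (simple 2-point stencil)
  h <- rho * 1e-6
  f <- function(x) x * a_excess(x, T, model)
  p_fd <- rho * T + rho * ((f(rho + h) - f(rho - h)) / (2 * h) -
                             a_excess(rho, T, model))
  expect_equal(p_impl, p_fd, tolerance = 1e-6)
})

test_that("association fraction: closed form, mass action, monotonicity", {
  expect_equal(association_fraction(0), 1)
  expect_equal(association_fraction(1), 0.5)
  # defining mass-action equation X = 1/(1 + 2 rho_delta X) to machine eps
  rd <- 10^seq(-6, 6, length.out = 40)
  x <- association_fraction(rd)
  expect_equal(x, 1 / (1 + 2 * rd * x), tolerance = 1e-14)
  expect_true(all(diff(x) < 0))
  expect_true(all(x > 0 & x <= 1))
  expect_error(association_fraction(-1), "non-negative")
})

test_that("association free energy: limits and density monotonicity", {
  mie <- mie_parameters(266.68, 0.30555, 17.02, 6)
  ap0 <- association_parameters(0, 1e-3)
  expect_equal(a_assoc(c(0, 10, 30), 300, ap0, mie), c(0, 0, 0))
  ap <- association_parameters(1985.4, 1e-3)
  expect_equal(a_assoc(0, 300, ap, mie), 0)
  rho <- seq(0.5, 35, length.out = 30)
  a <- a_assoc(rho, 300, ap, mie)
  expect_true(all(diff(a) < 0))  # monotone non-increasing in rho
  # epsilon_assoc -> 0 limit approaches zero continuously
  a_small <- a_assoc(20, 300, association_parameters(1e-3, 1e-3), mie)
  expect_lt(abs(a_small), 1e-3)
})

test_that("a_excess dispatch: ideal, additivity, vdW closed form", {
  expect_equal(a_excess(c(0, 1, 5), 300, eos_ideal()), c(0, 0, 0))

  mie <- mie_parameters(266.68, 0.30555, 17.02, 6)
  ap <- association_parameters(1985.4, 1e-3)
  m_assoc <- eos_mie(mie, ap)
  rho <- c(1, 10, 25)
  expect_equal(a_excess(rho, 350, m_assoc),
               a_mono(rho, 350, mie) + a_assoc(rho, 350, ap, mie))

  m_vdw <- vdw_water()
  rho <- seq(0, 90, length.out = 25)
  expect_equal(a_excess(rho, 500, m_vdw),
               -500 * log(1 - VDW_B * rho) - VDW_A * rho)
  expect_equal(vdw_a_excess(0, 500, VDW_A, VDW_B), 0)
  expect_equal(vdw_a_excess(c(1, 5), 500, 0, 0), c(0, 0))
  expect_error(vdw_a_excess(101, 500, VDW_A, VDW_B), "below 1")
  # a_ex(0, T) = 0 for every registered model
  for (nm in list_models()) {
    expect_equal(a_excess(0, 400, load_model(nm)), 0, info = nm)
  }
})

test_that("pressure: ideal exact, vdW analytic, FD invariant on log grid", {
  T <- 500
  rho <- 10^seq(-3, log10(60), length.out = 20)
  expect_equal(pressure_from_eos(rho, T, eos_ideal()), rho * T)

  m <- vdw_water()
  p_analytic <- rho * T / (1 - VDW_B * rho) - VDW_A * rho^2
  expect_equal(pressure_from_eos(rho, T, m), p_analytic, tolerance = 1e-12)

  # invariant: agreement with central FD of rho*a_ex to <= 1e-6 relative
  # (grid restricted to the associating model's packing domain at 500 K)
  model <- load_model("associating")
  rho_a <- 10^seq(-3, log10(45), length.out = 20)
  h <- rho_a * 1e-6
  f <- function(x) x * a_excess(x, T, model)
  p_fd <- rho_a * T + rho_a * ((f(rho_a + h) - f(rho_a - h)) / (2 * h) -
                                 a_excess(rho_a, T, model))
  expect_equal(pressure_from_eos(rho_a, T, model), p_fd, tolerance = 1e-6)
})

test_that("compressibility: ideal 1/p, vdW analytic, FD cross-check", {
  T <- 500; rho <- c(1, 5, 20)
  expect_equal(compressibility_from_eos(rho, T, eos_ideal()),
               1 / (rho * T))
  m <- vdw_water()
  rho_liq <- 70
  beta_analytic <- 1 / (rho_liq * (T / (1 - VDW_B * rho_liq)^2 -
                                     2 * VDW_A * rho_liq))
  expect_equal(compressibility_from_eos(rho_liq, T, m), beta_analytic)
  # FD cross-check on the associating model at a stable liquid state
  model <- load_model("associating")
  r0 <- 33; h <- r0 * 1e-5
  dpdr <- (pressure_from_eos(r0 + h, 300, model) -
             pressure_from_eos(r0 - h, 300, model)) / (2 * h)
  expect_equal(compressibility_from_eos(r0, 300, model), 1 / (r0 * dpdr),
               tolerance = 1e-6)
  expect_error(compressibility_from_eos(45, 500, m), "unstable")
})

test_that("VLE solver matches the Maxwell equal-area oracle and behaves
           towards the critical point", {
  m <- vdw_water()
  T <- 0.9 * 647
  v <- solve_vle(T, m)
  mx <- oracle_vdw_maxwell(T, VDW_A, VDW_B)
  expect_false(v$supercritical)
  expect_equal(v$rho_l, mx$rho_l, tolerance = 1e-7)
  expect_equal(v$rho_v, mx$rho_v, tolerance = 1e-7)
  expect_equal(v$p_v, mx$p_v, tolerance = 1e-7)
  # equal pressure and chemical potential at the reported solution
  expect_equal(pressure_from_eos(v$rho_l, T, m),
               pressure_from_eos(v$rho_v, T, m), tolerance = 1e-8)
  expect_equal(ldpmc:::mu_from_eos(v$rho_l, T, m),
               ldpmc:::mu_from_eos(v$rho_v, T, m), tolerance = 1e-8)

  # density gap shrinks monotonically towards T_c
  gaps <- vapply(c(0.80, 0.90, 0.95, 0.99) * 647, function(Ti) {
    vi <- solve_vle(Ti, m)
    vi$rho_l - vi$rho_v
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))

  expect_true(solve_vle(1.05 * 647, m)$supercritical)
  expect_true(solve_vle(300, eos_ideal())$supercritical)
})

test_that("VLE output is invariant to the bracketing scan resolution", {
  m <- vdw_water()
  sp_coarse <- ldpmc:::spinodal_scan(550, m, n = 150)
  sp_fine <- ldpmc:::spinodal_scan(550, m, n = 2000)
  expect_gt(abs(sp_coarse$rho_sv - sp_fine$rho_sv), 1e-6)  # brackets differ
  v1 <- solve_vle(550, m, n_scan = 150)
  v2 <- solve_vle(550, m, n_scan = 2000)
  expect_equal(v1$rho_l, v2$rho_l, tolerance = 1e-8)
  expect_equal(v1$rho_v, v2$rho_v, tolerance = 1e-8)
  expect_equal(v1$p_v, v2$p_v, tolerance = 1e-8)
})

test_that("temperature-dependent registry models evaluate inside their window
           and error outside it", {
  vle <- load_model("vle")
  p1 <- mie_at(vle, 400)
  expect_s3_class(p1, "mie_parameters")
  expect_gt(p1$epsilon, 0)
  expect_error(mie_at(vle, 700), "outside the valid range")
  expect_error(mie_at(vle, 200), "outside the valid range")
  # the refit reproduces the reference table at a fit temperature
  v <- solve_vle(460, vle)
  expect_equal(rho_to_kg_m3(v$rho_l), 879.5, tolerance = 0.005)
  expect_equal(pressure_to_MPa(v$p_v), 1.1709, tolerance = 0.01)
  # ift stand-in: liquid density constrained, vapour pressure free
  ift <- load_model("ift")
  vi <- solve_vle(460, ift)
  expect_equal(rho_to_kg_m3(vi$rho_l), 879.5, tolerance = 0.01)
  expect_error(load_model("nope"), "registered models")
})
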