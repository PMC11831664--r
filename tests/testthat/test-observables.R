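# Measurement suite: profiles, coexistence fits, ghost estimators, %AAD.

make_tanh_frames <- function(rho_l, rho_v, n = 4000, box = c(2, 2, 10),
                             z1 = 3, z2 = 7, w = 0.25, seed = 1) {
  # draw particle z-positions from the double-tanh slab density by rejection
  set.seed(seed)
  dens <- function(z) {
    rho_v + (rho_l - rho_v) / 2 * (tanh((z - z1) / w) - tanh((z - z2) / w))
  }
  zs <- numeric(0)
  while (length(zs) < n) {
    cand <- runif(2 * n, 0, box[3])
    keep <- runif(2 * n) < dens(cand) / rho_l
    zs <- c(zs, cand[keep])
  }
  zs <- zs[seq_len(n)]
  configuration(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), zs), box)
}

test_that("density profile: conservation, flat gas, single-bin delta,
           constructed slab occupancy", {
  box <- c(2, 2, 8)
  cfg <- random_config(2000, box, seed = 41)
  prof <- density_profile(list(cfg), n_bins = 40)
  # exact conservation: sum(rho * bin volume) = N
  expect_equal(sum(prof$rho) * 2 * 2 * (8 / 40), 2000)
  # flat within 3 binomial standard errors per bin
  lam <- 2000 / 40
  expect_true(all(abs(prof$rho * 2 * 2 * (8 / 40) - lam) < 3.5 * sqrt(lam)))

  # all particles in one bin
  pos <- cbind(runif(100, 0, 2), runif(100, 0, 2), rep(0.05, 100))
  delta_prof <- density_profile(list(configuration(pos, box)), n_bins = 80)
  expect_equal(sum(delta_prof$rho > 0), 1)

  # constructed two-region occupancy is exact
  pos2 <- cbind(runif(300, 0, 2), runif(300, 0, 2),
                c(runif(200, 0, 4), runif(100, 4, 8)))
  p2 <- density_profile(list(configuration(pos2, box)), n_bins = 16)
  counts <- p2$rho * 2 * 2 * 0.5
  expect_equal(sum(counts[1:8]), 200)
  expect_equal(sum(counts[9:16]), 100)

  expect_error(density_profile(list(), 20), "at least one frame")
  expect_error(density_profile(list(cfg), 5), "at least 10")
})

test_that("coexistence fit: noiseless tanh recovered exactly, flat profile
           reports no coexistence", {
  z <- seq(0.05, 9.95, by = 0.1)
  rho <- 0.1 + (1.0 - 0.1) / 2 * (tanh((z - 3) / 0.3) - tanh((z - 7) / 0.3))
  prof <- structure(list(z = z, rho = rho, n_bins = length(z),
                         box = c(2, 2, 10), n_frames = 1),
                    class = "density_profile")
  out <- coexistence_densities(prof)
  expect_true(out$coexisting)
  expect_equal(out$rho_l, 1.0, tolerance = 1e-3)
  expect_equal(out$rho_v, 0.1, tolerance = 1e-2)

  flat <- structure(list(z = z, rho = rep(0.5, length(z)),
                         n_bins = length(z), box = c(2, 2, 10), n_frames = 1),
                    class = "density_profile")
  out_flat <- coexistence_densities(flat)
  expect_false(out_flat$coexisting)
})

test_that("coexistence fit handles a slab straddling the periodic boundary", {
  z <- seq(0.05, 9.95, by = 0.1)
  rho_sym <- 0.1 + 0.9 / 2 * (tanh((z - 3) / 0.3) - tanh((z - 7) / 0.3))
  # circular shift: liquid now occupies the two ends of the box
  shift <- 50
  rho <- rho_sym[((seq_along(z) - 1 + shift) %% length(z)) + 1]
  prof <- structure(list(z = z, rho = rho, n_bins = length(z),
                         box = c(2, 2, 10), n_frames = 1),
                    class = "density_profile")
  out <- coexistence_densities(prof)
  expect_true(out$coexisting)
  expect_equal(out$rho_l, 1.0, tolerance = 2e-3)
  expect_equal(out$rho_v, 0.1, tolerance = 2e-2)
})

test_that("coexistence fit: mean recovery within 0.5% under 2% noise", {
  z <- seq(0.05, 9.95, by = 0.1)
  shape <- (tanh((z - 3) / 0.3) - tanh((z - 7) / 0.3)) / 2
  set.seed(PROP_SEED)
  rl <- rv <- numeric(50)
  for (k in 1:50) {
    rho_true <- 0.1 + 0.9 * shape
    rho <- rho_true * (1 + rnorm(length(z), 0, 0.02))   # 2% relative noise
    prof <- structure(list(z = z, rho = rho, n_bins = length(z),
                           box = c(2, 2, 10), n_frames = 1),
                      class = "density_profile")
    out <- coexistence_densities(prof)
    rl[k] <- out$rho_l; rv[k] <- out$rho_v
  }
  expect_lt(abs(mean(rl) / 1.0 - 1), 0.005)
  expect_lt(abs(mean(rv) - 0.1), 0.005)
})

test_that("test-area estimator: identically zero for the ideal backend and
           zero within error for a homogeneous bulk", {
  slab <- make_tanh_frames(60, 5, n = 800, seed = 51)
  spec0 <- potential_spec(eos_ideal(), r_c = 0.6, kappa = 0)
  g0 <- test_area_gamma(list(slab), spec0, T = 500)
  expect_identical(g0$gamma, 0)

  # homogeneous vdW bulk at a mechanically stable compressed-liquid state
  # (a density inside the two-phase region would nucleate real interfaces)
  m <- vdw_water()
  spec <- potential_spec(m, r_c = VDW_RC, kappa = 0, T = 500)
  cfg <- build_bulk_configuration(400, 75, seed = 3)
  proto <- simulation_protocol("nvt", T = 500, n_equil_cycles = 100,
                               n_prod_cycles = 400, sample_every = 5,
                               seed = 21)
  res <- run_nvt(cfg, spec, proto)
  g <- test_area_gamma(res$frames, spec, T = 500)
  expect_lt(abs(g$gamma), 3 * g$se)
})

test_that("test-area estimator is invariant to frame order", {
  m <- vdw_water()
  spec <- potential_spec(m, r_c = 0.7, kappa = 0.01, T = 500)
  frames <- lapply(1:6, function(k) make_tanh_frames(60, 5, n = 300,
                                                     box = c(1.6, 1.6, 6),
                                                     z1 = 2, z2 = 4,
                                                     seed = 60 + k))
  g1 <- test_area_gamma(frames, spec, T = 500, n_blocks = 3)
  g2 <- test_area_gamma(rev(frames), spec, T = 500, n_blocks = 3)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-12)
})

test_that("test-volume estimator: exact for the ideal gas, settings errors", {
  box <- c(2, 2, 2)
  cfg <- random_config(250, box, seed = 71)
  spec0 <- potential_spec(eos_ideal(), r_c = 0.6, kappa = 0)
  p <- test_volume_pressure(list(cfg), spec0, T = 300)
  # dU = 0: central average reproduces rho k_B T up to O(zeta^2)
  expect_equal(p$p, 250 / 8 * 300, tolerance = 1e-6)
  expect_error(test_volume_settings(zeta = -1), "positive")
  # single particle limit
  one <- configuration(matrix(c(1, 1, 1), 1), box)
  p1 <- test_volume_pressure(list(one), spec0, T = 300)
  expect_equal(p1$p, 300 / 8, tolerance = 1e-6)
})

test_that("volume-fluctuation compressibility: degenerate and arithmetic
           cases", {
  expect_warning(b <- isothermal_compressibility(rep(2, 150), 300), NA)
  expect_equal(b$beta_T, 0)
  expect_error(isothermal_compressibility(c(1), 300), "at least two")
  suppressWarnings({
    b2 <- isothermal_compressibility(rep(c(0.9, 1.1), 60), 300)
  })
  expect_equal(b2$beta_T, 0.01 / (300 * 1.0))
})

test_that("%AAD: identity, uniform scaling, mixed example, zero reference", {
  expect_equal(percent_aad(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percent_aad(1.1 * c(2, 5, 9), c(2, 5, 9)), 10)
  expect_equal(percent_aad(c(1, 3), c(2, 2)), 50)
  expect_error(percent_aad(c(1, 2), c(1, 0)), "nonzero")
  expect_error(percent_aad(c(1, 2), c(1)), "equal")
})
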