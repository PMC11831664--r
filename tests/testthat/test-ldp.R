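# Local-density core: kernel, fields, energies, incremental moves, tables.

test_that("Lucy kernel: compact support, normalization, smooth cutoff", {
  for (rc in c(1, 4)) {
    expect_equal(lucy_weight(rc, rc), 0)
    expect_equal(lucy_weight(rc * 1.5, rc), 0)
    # 3-D normalization by quadrature: int 4 pi r^2 w(r) dr = 1
    I <- integrate(function(r) 4 * pi * r^2 * lucy_weight(r, rc),
                   0, rc, rel.tol = 1e-12)$value
    expect_equal(I, 1, tolerance = 1e-10)
  }
  # the normalization constant itself
  expect_equal(lucy_weight(0, 2) * (16 * pi * 2^3 / 105), 1, tolerance = 1e-14)
  expect_error(lucy_weight(0.5, -1), "positive")
})

test_that("Lucy kernel gradient matches a finite difference and vanishes at
           the origin and cutoff", {
  rc <- 1.7
  expect_equal(lucy_weight_gradient(0, rc), 0)
  expect_equal(lucy_weight_gradient(rc, rc), 0)
  r <- seq(0.05, rc * 0.95, length.out = 20)
  h <- 1e-7
  fd <- (lucy_weight(r + h, rc) - lucy_weight(r - h, rc)) / (2 * h)
  expect_equal(lucy_weight_gradient(r, rc), fd, tolerance = 1e-6)
})

test_that("local densities: single particle, symmetric pair, brute force", {
  rc <- 1
  single <- configuration(matrix(c(1, 1, 1), 1), c(3, 3, 3))
  f1 <- compute_local_densities(single, rc)
  expect_equal(f1$rho_bar, 0)
  expect_equal(unname(f1$grad_rho), matrix(0, 1, 3))

  pair <- configuration(rbind(c(1, 1, 1), c(1, 1, 1 + rc / 2)), c(4, 4, 4))
  f2 <- compute_local_densities(pair, rc)
  expect_equal(f2$rho_bar, rep(lucy_weight(rc / 2, rc), 2))
  expect_equal(f2$grad_rho[1, ], -f2$grad_rho[2, ])
  expect_equal(f2$grad_rho[1, 3], lucy_weight_gradient(rc / 2, rc) * (-1))

  cfg <- random_config(50, c(2.5, 2.5, 2.5), seed = 101)
  f <- compute_local_densities(cfg, rc)
  o <- oracle_field(cfg$positions, cfg$box, rc)
  expect_equal(f$rho_bar, o$rho, tolerance = 1e-12)
  expect_equal(unname(f$grad_rho), unname(o$grad), tolerance = 1e-12)

  expect_error(compute_local_densities(cfg, 1.5), "minimum image")
})

test_that("total energy: ideal zero, brute-force oracle with SG term,
           translation and permutation invariance", {
  cfg <- random_config(30, c(2.2, 2.2, 2.2), seed = 7)
  spec0 <- potential_spec(eos_ideal(), r_c = 1, kappa = 0)
  expect_equal(total_energy(cfg, spec0), 0)

  m <- vdw_water()
  spec <- potential_spec(m, r_c = 1, kappa = 0.02, T = 500)
  U <- total_energy(cfg, spec)
  U_oracle <- oracle_energy(cfg$positions, cfg$box, 1,
                            function(r) vdw_a_excess(r, 500, VDW_A, VDW_B),
                            kappa = 0.02)
  expect_equal(U, U_oracle, tolerance = 1e-12)

  # rigid translation (with wrapping) leaves U unchanged
  shifted <- configuration(sweep(cfg$positions, 2, c(0.37, -1.12, 2.05), `+`),
                           cfg$box)
  expect_equal(total_energy(shifted, spec), U, tolerance = 1e-12)

  # permutation of particle labels leaves U unchanged
  set.seed(PROP_SEED)
  perm <- sample(nrow(cfg$positions))
  permuted <- configuration(cfg$positions[perm, ], cfg$box)
  expect_equal(total_energy(permuted, spec), U, tolerance = 1e-12)
})

test_that("uniform bulk limit: U/N approaches a_ex(rho) at 4-sigma cutoff", {
  m <- vdw_water()
  rho <- 66
  cfg <- build_bulk_configuration(600, rho, seed = 3, jitter = 0.05)
  spec <- potential_spec(m, r_c = VDW_RC, kappa = 0, T = 500)
  U_per_N <- total_energy(cfg, spec) / 600
  expect_equal(U_per_N, vdw_a_excess(rho, 500, VDW_A, VDW_B),
               tolerance = 0.02)
})

test_that("incremental move energy matches full recomputation", {
  m <- vdw_water()
  cfg <- random_config(50, c(2.4, 2.4, 2.4), seed = 11)
  spec <- potential_spec(m, r_c = 1, kappa = 0.01, T = 500)
  field <- compute_local_densities(cfg, spec$r_c)

  # null move and isolated-particle move are exactly zero
  expect_equal(delta_energy_move(cfg, field, 5, cfg$positions[5, ], spec), 0)
  iso <- configuration(rbind(c(1, 1, 1), c(3.5, 3.5, 3.5)), c(7, 7, 7))
  fiso <- compute_local_densities(iso, 1)
  spec_iso <- potential_spec(m, r_c = 1, kappa = 0.01, T = 500)
  expect_equal(delta_energy_move(iso, fiso, 1, c(1.2, 1, 1), spec_iso), 0)

  # 100 random moves: delta agrees with before/after total energies
  set.seed(PROP_SEED)
  U0 <- total_energy(cfg, spec)
  for (k in 1:100) {
    i <- sample(50, 1)
    newp <- cfg$positions[i, ] + runif(3, -0.4, 0.4)
    dU <- delta_energy_move(cfg, field, i, newp, spec)
    pos2 <- cfg$positions
    pos2[i, ] <- newp
    cfg2 <- configuration(pos2, cfg$box)
    dU_full <- total_energy(cfg2, spec) - U0
    expect_lt(abs(dU - dU_full), 1e-9 * max(1, abs(dU_full)))
    # accept the move and carry the state forward
    cfg <- cfg2
    U0 <- U0 + dU_full
    field <- compute_local_densities(cfg, spec$r_c)
  }
})

test_that("field inconsistency and bad indices are caught", {
  cfg <- random_config(20, c(2.2, 2.2, 2.2), seed = 5)
  spec <- potential_spec(vdw_water(), r_c = 1, kappa = 0, T = 500)
  field <- compute_local_densities(cfg, 1)
  expect_error(delta_energy_move(cfg, list(rho_bar = numeric(3)), 1,
                                 c(0, 0, 0), spec), "inconsistent")
  expect_error(delta_energy_move(cfg, field, 0, c(0, 0, 0), spec),
               "out of range")
})

test_that("lookup tables: ideal zero, vdW spline accuracy off grid,
           construction errors", {
  tab0 <- ldpmc:::zero_table()
  expect_equal(ldpmc:::eval_table(tab0, c(0, 3, 17)), c(0, 0, 0))

  m <- vdw_water()
  tab <- build_lookup_table(m, 500, rho_max = 90, n_points = 2048)
  expect_equal(tab$value[1], 0)
  expect_true(all(diff(tab$grid) > 0))
  set.seed(PROP_SEED)
  x <- runif(1000, 0.01, 89.9)
  direct <- vdw_a_excess(x, 500, VDW_A, VDW_B)
  expect_equal(ldpmc:::eval_table(tab, x), direct, tolerance = 1e-6)

  expect_error(build_lookup_table(m, 500, rho_max = 90, n_points = 8),
               "at least 16")
  # out-of-range densities fall back to direct evaluation
  expect_equal(ldpmc:::eval_table(tab, 95),
               vdw_a_excess(95, 500, VDW_A, VDW_B))
  # beyond the model's domain the fallback is a steep finite wall
  wall <- ldpmc:::eval_table(tab, c(98, 99, 100, 120))
  expect_true(all(is.finite(wall)))
  expect_true(all(diff(wall) > 4e3))   # ~5e3 K per nm^-3 slope
})

test_that("lookup-table and direct-evaluation energies agree", {
  cfg <- random_config(40, c(2.2, 2.2, 2.2), seed = 23)
  spec <- potential_spec(vdw_water(), r_c = 1, kappa = 0, T = 500)
  expect_equal(total_energy(cfg, spec, use_lookup = TRUE),
               total_energy(cfg, spec, use_lookup = FALSE),
               tolerance = 1e-7)
})

test_that("cutoff rule tracks sigma(T) for temperature-dependent models", {
  vle <- load_model("vle")
  expect_equal(r_c_for_model(vle, 400), 4 * mie_at(vle, 400)$sigma)
  expect_false(isTRUE(all.equal(r_c_for_model(vle, 300),
                                r_c_for_model(vle, 600))))
})
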