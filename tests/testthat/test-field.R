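test_that("conformation weights follow the insertion-work Boltzmann factor", {
  v <- c(0, 2, 1)
  expect_equal(conformation_weight(v, c(0, 0, 0)), 1)
  v0 <- bead_volume(0.6)
  x <- 1.7
  expect_equal(conformation_weight(c(v0, 0), c(x / v0, 5)), exp(-x))
  # exponent additivity for a disjoint union of molecules
  f <- c(0.3, 0.8, 0.1)
  a <- c(1, 0, 2)
  b <- c(0, 1.5, 0.5)
  expect_equal(
    conformation_weight(a + b, f),
    conformation_weight(a, f) * conformation_weight(b, f)
  )
})

test_that("partition function is 1 with uniform P in the field-free limit", {
  sys <- small_test_system()
  e <- sys$ensembles$A
  pf <- partition_function(e, numeric(sys$grid$n_layers))
  expect_equal(pf$q, 1)
  expect_equal(pf$P, rep(1 / e$n_conf, e$n_conf))
  # single conformation: P = 1 whatever the field
  e1 <- species_ensemble(e$V[1, , drop = FALSE], e$com[1], "A", 0,
                         e$molecular_volume, sys$grid)
  pf1 <- partition_function(e1, runif(sys$grid$n_layers))
  expect_equal(pf1$P, 1)
})

test_that("q decreases when the field is raised where the ensemble lives", {
  sys <- small_test_system()
  e <- sys$ensembles$Aa
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(sys$grid$n_layers, 0, 0.05)
    q0 <- partition_function(e, x)$q
    support <- which(colSums(e$V) > 0)
    k <- sample(support, 1)
    x2 <- x
    x2[k] <- x2[k] + 0.01
    expect_lt(partition_function(e, x2)$q, q0)
  }
})

test_that("solution densities reduce to bulk and respond to the field", {
  g <- radial_grid(20, dr = 1, r_max = 30)
  bulk0 <- bulk_solution(kd = 1e-9) # no solutes: pure water
  prof0 <- solution_density_profiles(bulk0, numeric(g$n_layers), g)
  expect_equal(prof0$phi_water, rep(1, g$n_layers))
  bulk <- bulk_solution(c_antigen = 1e-6, c_antibody = 1e-7, kd = 1e-9)
  prof <- solution_density_profiles(bulk, numeric(g$n_layers), g)
  expect_equal(prof$rho_a, rep(molar_to_density(1e-6), g$n_layers))
  expect_equal(prof$phi_water + prof$phi_solution, rep(1, g$n_layers))
  # raising the field in one shell lowers every finite-volume density there
  x <- numeric(g$n_layers)
  x[3] <- 0.5
  prof2 <- solution_density_profiles(bulk, x, g)
  expect_lt(prof2$rho_a[3], prof$rho_a[3])
  expect_lt(prof2$rho_w[3], prof$rho_w[3])
  expect_equal(prof2$rho_a[-3], prof$rho_a[-3])
})

test_that("packing residual is zero for pure water and signs overfilling", {
  g <- radial_grid(20, dr = 1, r_max = 25)
  bulk <- bulk_solution(kd = 1e-9)
  expect_equal(
    packing_residual(numeric(g$n_layers), numeric(g$n_layers), bulk),
    numeric(g$n_layers)
  )
  phi_b <- c(1.2, rep(0, g$n_layers - 1))
  r <- packing_residual(numeric(g$n_layers), phi_b, bulk)
  expect_gt(r[1], 0)
  expect_equal(r[-1], numeric(g$n_layers - 1))
})
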