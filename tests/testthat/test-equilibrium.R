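test_that("Kd converts to the standard-state potential", {
  expect_equal(kd_to_potential(1), 0)
  expect_equal(kd_to_potential(1e-9), -9 * log(10))
  expect_error(kd_to_potential(0), "positive")
  expect_error(kd_to_potential(-1), "positive")
})

test_that("covalent surface fractions recover dilute mass action", {
  expect_equal(
    surface_fractions_covalent(1, 1, 1, c_a = 0, kd = 1e-9),
    c(A = 1, Aa = 0, Aaa = 0)
  )
  # single-ligation limit at c = Kd
  expect_equal(
    surface_fractions_covalent(1, 1, 1, c_a = 1e-9, kd = 1e-9,
                               avidity_ratio = Inf, g_stat = 1),
    c(A = 0.5, Aa = 0.5, Aaa = 0),
    tolerance = 1e-12
  )
  # two equal independent ligations at c = Kd: dilute two-site partition
  # function enumerates states 1 : x : x^2 -> equal thirds
  expect_equal(
    surface_fractions_covalent(1, 1, 1, c_a = 1e-9, kd = 1e-9,
                               avidity_ratio = 1, g_stat = 1),
    c(A = 1, Aa = 1, Aaa = 1) / 3,
    tolerance = 1e-12
  )
  # avidity enters as an effective second-site constant Kd2 = Kd * rho_av
  f <- surface_fractions_covalent(1, 1, 1, c_a = 1e-9, kd = 1e-9,
                                  avidity_ratio = 50, g_stat = 1)
  expect_equal(f[["Aaa"]] / f[["Aa"]], 1e-9 / (1e-9 * 50))
})

test_that("streptavidin fractions follow site mass action", {
  f <- surface_fractions_streptavidin(c(1, 1, 1), c(1e-14, 0, 0),
                                      kd_biotin = 1e-14)
  expect_equal(f[["S"]], 0.5)
  expect_equal(f[["A"]], 0.5)
  # vanishing Kd fills the surface
  f2 <- surface_fractions_streptavidin(c(1, 1, 1), c(1e-9, 0, 0),
                                       kd_biotin = 1e-30)
  expect_lt(f2[["S"]], 1e-15)
  expect_warning(
    f3 <- surface_fractions_streptavidin(c(1, 1, 1), c(0, 0, 0)),
    "empty"
  )
  expect_equal(unname(f3), c(1, 0, 0, 0))
})

test_that("a bare particle in pure solvent converges immediately to zero", {
  sys <- small_test_system()
  bulk <- bulk_solution(kd = 1e-9)
  st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = 0)
  expect_equal(st$diagnostics$iterations, 0)
  expect_equal(st$field, numeric(sys$grid$n_layers))
  expect_equal(st$beta_F, 0)
  expect_equal(st$captured_antigen, 0)
})

test_that("dilute limit reproduces the Langmuir isotherm within 1%", {
  sys <- small_test_system(r_np = 100, spacer = 5, seed = 13)
  for (ratio in c(0.01, 1, 100)) {
    kd <- 1e-9
    bulk <- bulk_solution(c_antigen = ratio * kd, kd = kd,
                          avidity_ratio = Inf, g_stat = 1)
    st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = 1e-3)
    occ <- st$f[["Aa"]]
    expect_equal(occ, langmuir_occupancy(ratio * kd, kd), tolerance = 0.01)
  }
})

test_that("converged states satisfy packing and normalization invariants", {
  sys <- small_test_system()
  bulk <- bulk_solution(c_antigen = 1e-7, kd = 1e-9)
  for (ns in c(1, 30, 200)) {
    st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = ns)
    expect_true(st$diagnostics$converged)
    expect_lte(st$diagnostics$residual_max, 1e-8)
    expect_lte(st$diagnostics$f_norm_dev, 1e-12)
    expect_lte(st$diagnostics$p_norm_dev, 1e-12)
    prof <- tidy(st)
    expect_lte(max(abs(prof$residual)), 1e-8)
  }
})

test_that("the osmotic field decays to zero at the outer boundary", {
  sys <- small_test_system()
  bulk <- bulk_solution(c_antigen = 1e-7, kd = 1e-9)
  st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = 100)
  L <- sys$grid$n_layers
  expect_lt(abs(st$field[L]), 1e-8)
  # enlarging the box does not change the physics
  sys2 <- small_test_system()
  g2 <- radial_grid(20, dr = 1, r_max = 20 + 50)
  ens2 <- lapply(sys2$ensembles, function(e) {
    species_ensemble(
      cbind(e$V, matrix(0, e$n_conf, g2$n_layers - ncol(e$V))),
      e$com, e$species, e$n_antigens, e$molecular_volume, g2, e$acceptance
    )
  })
  st2 <- solve_equilibrium(ens2, bulk, "covalent", n_sites = 100)
  expect_equal(st2$captured_antigen, st$captured_antigen,
               tolerance = 1e-3)
})

test_that("random feasible perturbations never lower the converged free energy", {
  sys <- small_test_system()
  bulk <- bulk_solution(c_antigen = 1e-7, kd = 1e-9)
  st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = 60)
  base <- st$beta_F
  set.seed(99)
  species <- c("A", "Aa", "Aaa")
  for (i in 1:100) {
    f <- st$f
    P <- st$P
    if (i %% 2 == 0) {
      eps <- rnorm(3, sd = 0.02)
      f <- pmax(st$f[species] + eps, 1e-12)
      f <- f / sum(f)
    } else {
      sp <- sample(species, 1)
      p <- P[[sp]] * exp(rnorm(length(P[[sp]]), sd = 0.05))
      P[[sp]] <- p / sum(p)
    }
    fe <- acnp:::.free_energy_eval(
      f = f, P = P, x = NULL, ensembles = sys$ensembles, bulk = bulk,
      n_sites = 60, logK = st$logK, scheme = "covalent", grid = sys$grid
    )
    expect_gte(fe$total, base - 1e-7)
  }
})

test_that("captured antigen counts one- and two-antigen complexes", {
  sys <- small_test_system()
  bulk <- bulk_solution(c_antigen = 1e-7, kd = 1e-9)
  st <- solve_equilibrium(sys$ensembles, bulk, "covalent", n_sites = 10)
  ca <- captured_antigen(st)
  f <- st$f
  expect_equal(ca$count, 10 * (f[["Aa"]] + 2 * f[["Aaa"]]))
  expect_equal(ca$per_area, ca$count / (4 * pi * sys$grid$r_np^2))
  # per-antibody capture is bounded by the two Fab sites
  expect_lte(ca$count / 10, 2)
  g <- glance(st)
  expect_equal(g$captured, ca$count)
  expect_true(g$converged)
})
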