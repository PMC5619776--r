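test_that("Langmuir oracle matches the closed form", {
  expect_equal(langmuir_occupancy(1e-9, 1e-9), 0.5)
  expect_equal(langmuir_occupancy(100e-9, 1e-9), 100 / 101)
  expect_equal(langmuir_occupancy(0, 1e-9), 0)
})

test_that("the exhaustive oracle recovers analytic dilute adsorption", {
  # one conformation per species with negligible volume on a tiny grid:
  # the streptavidin fractions must reduce to field-free mass action
  grid <- radial_grid(5, dr = 1, r_max = 7)
  ens <- lapply(c(A = 0, Aa = 1, Aaa = 2), function(na) {
    species_ensemble(matrix(1e-6, 1, 2), 5.5, c("A", "Aa", "Aaa")[na + 1],
                     na, 2e-6, grid)
  })
  kd_b <- 1e-9
  bulk <- bulk_solution(c_antigen = 0, c_antibody = 1e-9, kd = 1e-9,
                        kd_biotin = kd_b, v_antigen = 1, v_antibody = 2)
  bf <- brute_force_minimum(ens, bulk, "streptavidin", n_sites = 3)
  expect_equal(bf$f[["A"]] / (bf$f[["S"]] + bf$f[["A"]]),
               langmuir_occupancy(1e-9, kd_b), tolerance = 1e-4)
})

test_that("solver matches the exhaustive oracle on randomized tiny systems", {
  for (s in c(3, 14, 27, 41)) {
    ts <- tiny_system(s)
    bf <- brute_force_minimum(ts$ensembles, ts$bulk, "covalent", ts$n_sites)
    st <- solve_equilibrium(ts$ensembles, ts$bulk, "covalent", ts$n_sites)
    expect_lt(st$beta_F, bf$beta_F + 1e-6)
    expect_lt(abs(st$beta_F - bf$beta_F),
              1e-3 * max(1, abs(bf$beta_F)))
  }
})

test_that("oracle minimum is insensitive to the refinement depth", {
  ts <- tiny_system(8)
  a <- brute_force_minimum(ts$ensembles, ts$bulk, "covalent", ts$n_sites,
                           h_min = 1e-5)
  b <- brute_force_minimum(ts$ensembles, ts$bulk, "covalent", ts$n_sites,
                           h_min = 1e-6)
  expect_equal(a$beta_F, b$beta_F, tolerance = 1e-6)
  expect_equal(a$f, b$f, tolerance = 1e-3)
})

test_that("oracle refuses oversized state spaces with a size estimate", {
  ts <- tiny_system(3)
  expect_error(
    brute_force_minimum(ts$ensembles, ts$bulk, "covalent", ts$n_sites,
                        resolution = 0.01),
    "state space too large"
  )
})

test_that("mini sweep configurations validate and solve", {
  cfgs <- mini_sweep_configs(seed = 3)
  expect_true(all(c("covalent-spacer", "covalent-nospacer", "strep-base")
                  %in% names(cfgs)))
  for (cfg in cfgs) expect_s3_class(cfg, "acnp_sweep_config")
  # the smallest configuration solves to convergence end to end
  cfg <- cfgs[["covalent-spacer"]]
  cfg$coverage <- cfg$coverage[c(2, 4)]
  cfg$n_spacer_samples <- 30
  curve <- run_sweep(cfg)
  expect_true(all(curve$converged))
  expect_true(all(curve$residual_max <= 1e-8))
})
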