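test_that("grid shells have exact spherical volumes", {
  g <- radial_grid(50, dr = 0.5, r_max = 60)
  k <- seq_len(g$n_layers)
  expect_equal(
    g$shell_volumes,
    (4 * pi / 3) * ((50 + k * 0.5)^3 - (50 + (k - 1) * 0.5)^3)
  )
  expect_equal(sum(g$shell_volumes), (4 * pi / 3) * (60^3 - 50^3))
})

test_that("center-rule binning conserves volume exactly", {
  g <- radial_grid(50, dr = 0.5, r_max = 60)
  # single bead at r = r_np + 3.25 dr -> all volume in the 4th shell (1-based)
  v <- bin_shell_volumes(matrix(c(0, 0, 50 + 3.25 * 0.5), 1), g)
  expect_equal(which(v > 0), 4L)
  expect_equal(sum(v), bead_volume(0.6))
  # two beads in one shell double it
  pos2 <- rbind(c(0, 0, 51.1), c(0.2, 0, 51.2))
  v2 <- bin_shell_volumes(pos2, g)
  expect_equal(max(v2), 2 * bead_volume(0.6))
  # a 50-bead chain conserves total volume to 1e-9 relative
  set.seed(1)
  chain <- matrix(rnorm(150), 50, 3)
  chain <- 52 * chain / sqrt(rowSums(chain^2)) + rnorm(150, 0, 0.5)
  v50 <- bin_shell_volumes(chain, g)
  expect_equal(sum(v50), 50 * (pi / 6) * 0.6^3, tolerance = 1e-9)
})

test_that("binning rejects positions outside the grid", {
  g <- radial_grid(50, dr = 0.5, r_max = 55)
  expect_error(bin_shell_volumes(matrix(c(0, 0, 56), 1), g), "increase r_max")
  expect_error(bin_shell_volumes(matrix(c(0, 0, 10), 1), g), "inside")
})

test_that("center-of-mass radius follows the mean position vector", {
  expect_equal(com_radius(matrix(c(0, 0, 53), 1)), 53)
  two <- rbind(c(1, 0, 53), c(-1, 0, 53))
  expect_lte(com_radius(two), sqrt(1 + 53^2))
  expect_equal(com_radius(two), 53)
  expect_error(com_radius(matrix(numeric(0), 0, 3)), "empty")
})

test_that("assembled ensembles conserve volume and clear the particle", {
  sys <- small_test_system()
  for (sp in c("A", "Aa", "Aaa")) {
    e <- sys$ensembles[[sp]]
    expect_equal(
      rowSums(e$V),
      rep(e$molecular_volume, e$n_conf),
      tolerance = 1e-9
    )
    expect_true(all(e$V >= 0))
  }
  # additivity: each antigen adds its model volume
  v_ag <- model_volume(sys$antigen)
  expect_equal(sys$ensembles$Aa$molecular_volume,
               sys$ensembles$A$molecular_volume + v_ag)
  expect_equal(sys$ensembles$Aaa$molecular_volume,
               sys$ensembles$A$molecular_volume + 2 * v_ag)
})

test_that("assembly is deterministic and seed-sensitive", {
  sys1 <- small_test_system(seed = 11)
  sys2 <- small_test_system(seed = 11)
  expect_identical(sys1$ensembles$Aa$V, sys2$ensembles$Aa$V)
  sys3 <- small_test_system(seed = 12)
  expect_false(identical(sys1$ensembles$Aa$V, sys3$ensembles$Aa$V))
})

test_that("higher curvature frees volume: acceptance grows as radius shrinks", {
  ab <- toy_antibody(6)
  ag <- toy_antigen()
  sp <- spacer_conformations(30, 60, seed = 5)
  acc <- vapply(c(50, 500), function(r) {
    g <- radial_grid(r, dr = 1, r_max = r + 40)
    e <- assemble_conformers(sp, ab, ag, n_antigens = 2, n_orientations = 8,
                             grid = g, seed = 21, min_accept = 1,
                             max_batches = 1)
    e$acceptance
  }, numeric(1))
  expect_gt(acc[1], acc[2])
})

test_that("an impossible geometry raises the geometric-bottleneck error", {
  # octahedral cross: in any orientation one 2-nm arm points below the
  # nearly flat surface of a very large particle
  cross6 <- bead_model(rbind(2 * diag(3), -2 * diag(3), c(0, 0, 0)),
                       anchor = 7L)
  g <- radial_grid(5000, dr = 1, r_max = 5020)
  sp0 <- spacer_conformations(0, 10, seed = 1)
  expect_error(
    assemble_conformers(sp0, cross6, n_antigens = 0, n_orientations = 5,
                        grid = g, seed = 2, min_accept = 1, max_batches = 2),
    "clears the nanoparticle"
  )
})
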