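test_that("binding maximum: parabolic interpolation and boundary flags", {
  curve <- tibble::tibble(coverage = c(1, 2, 3), captured = 1 - (c(1, 2, 3) - 2)^2)
  m <- find_binding_maximum(curve)
  expect_equal(m$coverage_at_max, 2)
  expect_equal(m$value_at_max, 1)
  expect_false(m$boundary)
  inc <- tibble::tibble(coverage = 1:5, captured = 1:5)
  m2 <- find_binding_maximum(inc)
  expect_true(m2$boundary)
  expect_equal(m2$coverage_at_max, 5)
  expect_error(find_binding_maximum(inc[1:2, ]), "3 points")
})

test_that("interpolated maximum agrees with a dense-grid argmax", {
  f <- function(x) -(x - 0.35)^2 * (x + 1)^2 + 0.2 * x
  x21 <- seq(0, 1, length.out = 21)
  curve <- tibble::tibble(coverage = x21, captured = f(x21))
  m <- find_binding_maximum(curve)
  dense <- seq(0, 1, length.out = 20001)
  x_star <- dense[which.max(f(dense))]
  expect_lt(abs(m$coverage_at_max - x_star), diff(x21)[1])
})

test_that("a vanishing-coverage sweep point captures nothing", {
  cfg <- sweep_config(
    scheme = "covalent", spacer = 5, kd = 1e-9, c_antigen = 1e-7,
    coverage = 1e-10, n_spacer_samples = 20, n_orientations = 5,
    antibody = toy_antibody(3), antigen = toy_antigen(),
    r_np = 20, r_max_offset = 30, dr = 1, seed = 5
  )
  curve <- run_sweep(cfg)
  expect_equal(nrow(curve), 1)
  expect_lt(curve$captured, 1e-5)
  expect_true(curve$converged)
})

test_that("sweep outputs round-trip through TSV and are reproducible", {
  cfg <- sweep_config(
    scheme = "covalent", spacer = 5, kd = 1e-9, c_antigen = 1e-7,
    coverage = c(1e-4, 1e-3), n_spacer_samples = 20, n_orientations = 5,
    antibody = toy_antibody(3), antigen = toy_antigen(),
    r_np = 20, r_max_offset = 30, dr = 1, seed = 5
  )
  c1 <- run_sweep(cfg)
  c2 <- run_sweep(cfg)
  expect_equal(as.data.frame(c1), as.data.frame(c2),
               ignore_attr = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sweep_outputs(c1, d1)
  p2 <- write_sweep_outputs(c2, d2)
  tsv1 <- p1[grepl("curve_", p1)]
  tsv2 <- p2[grepl("curve_", p2)]
  expect_length(tsv1, 1)
  expect_identical(readLines(tsv1), readLines(tsv2))
  back <- readr::read_tsv(tsv1, show_col_types = FALSE)
  expect_equal(back$captured, c1$captured)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # empty curve set: manifest only
  p0 <- write_sweep_outputs(c1[0, ], withr::local_tempdir())
  expect_length(p0, 1)
  expect_match(p0, "manifest.json")
})

test_that("autoplot and species-breakdown plots build silently", {
  cfg <- sweep_config(
    scheme = "covalent", spacer = 5, kd = 1e-9, c_antigen = 1e-7,
    coverage = c(1e-4, 1e-3, 1e-2), n_spacer_samples = 20,
    n_orientations = 5, antibody = toy_antibody(3), antigen = toy_antigen(),
    r_np = 20, r_max_offset = 30, dr = 1, seed = 5
  )
  curve <- run_sweep(cfg)
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")
  expect_s3_class(plot_species_breakdown(curve), "ggplot")
})

test_that("ensemble caches and state dumps round-trip through text files", {
  sys <- small_test_system()
  d <- withr::local_tempdir()
  pre <- file.path(d, "ensA")
  write_ensemble(sys$ensembles$Aa, pre)
  back <- read_ensemble(pre)
  expect_equal(back$V, sys$ensembles$Aa$V)
  expect_equal(back$com, sys$ensembles$Aa$com)
  expect_equal(back$molecular_volume, sys$ensembles$Aa$molecular_volume)
  st <- solve_equilibrium(sys$ensembles, bulk_solution(c_antigen = 1e-7),
                          "covalent", n_sites = 20)
  paths <- write_state(st, file.path(d, "state"))
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
  expect_equal(meta$captured, st$captured_antigen, tolerance = 1e-12)
})
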