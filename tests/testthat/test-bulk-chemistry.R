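test_that("degenerate mixtures resolve without complexes", {
  eq <- solve_bulk_equilibrium(2e-8, 0, kd = 1e-9)
  expect_equal(eq$c_a, 2e-8)
  expect_equal(eq$c_Aa + eq$c_Aaa, 0)
  eq2 <- solve_bulk_equilibrium(0, 1e-8, kd = 1e-9)
  expect_equal(eq2$c_A, 1e-8)
  expect_equal(eq2$c_a, 0)
})

test_that("picomolar mixtures stay essentially unbound at weak affinity", {
  # perturbative bound: c_Aa <~ A_total a_total / Kd
  eq <- solve_bulk_equilibrium(20e-12, 10e-12, kd = 1e-8, g_stat = 1)
  expect_lt(eq$c_Aa + eq$c_Aaa, 3e-14)
  expect_equal(eq$c_a, 20e-12, tolerance = 1.1e-3)
  expect_equal(eq$c_A, 10e-12, tolerance = 2.1e-3)
})

test_that("single-ligation equilibrium matches the quadratic closed form", {
  kd <- 1e-9
  eq <- solve_bulk_equilibrium(kd, kd, kd = kd, avidity_ratio = Inf,
                               g_stat = 1)
  # c_Aa = (A - c_Aa)(a - c_Aa)/Kd with A = a = Kd has root Kd (3 - sqrt(5))/2
  expect_equal(eq$c_Aa, kd * (3 - sqrt(5)) / 2, tolerance = 1e-10)
  expect_equal(eq$c_Aaa, 0)
})

test_that("mass balances close to 1e-10 over randomized mixtures", {
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    a_tot <- 10^runif(1, -12, -6)
    ab_tot <- 10^runif(1, -12, -6)
    kd <- 10^runif(1, -12, -7)
    rho <- 10^runif(1, 0, 3)
    eq <- solve_bulk_equilibrium(a_tot, ab_tot, kd, avidity_ratio = rho)
    res <- mass_balance(eq)
    worst <- max(worst, abs(res))
  }
  expect_lt(worst, 1e-10)
})

test_that("hand-perturbing free antigen shifts the antigen balance alone", {
  eq <- solve_bulk_equilibrium(1e-8, 5e-9, kd = 1e-9)
  spec <- attr(eq, "spec")
  eq2 <- eq
  delta <- 1e-10
  eq2$c_a <- eq2$c_a + delta
  res <- mass_balance(eq2, spec)
  expect_equal(res[["antigen"]] * spec$a_total, delta, tolerance = 1e-6)
  expect_lt(abs(res[["antibody"]]), 1e-10)
})

test_that("captured antigen in solution is monotone in totals and affinity", {
  bound <- function(a, kd) {
    eq <- solve_bulk_equilibrium(a, 1e-8, kd)
    eq$c_Aa + 2 * eq$c_Aaa
  }
  a_grid <- c(1e-9, 1e-8, 1e-7, 1e-6)
  b <- vapply(a_grid, bound, numeric(1), kd = 1e-9)
  expect_true(all(diff(b) > 0))
  kd_grid <- c(1e-11, 1e-10, 1e-9, 1e-8)
  b2 <- vapply(kd_grid, function(k) bound(1e-8, k), numeric(1))
  expect_true(all(diff(b2) < 0))
  # limits: vanishing affinity frees everything; infinite affinity with
  # excess antigen consumes every antibody
  eqw <- solve_bulk_equilibrium(1e-8, 1e-8, kd = 1)
  expect_equal(eqw$c_a, 1e-8, tolerance = 1e-6)
  eqs <- solve_bulk_equilibrium(1e-7, 1e-9, kd = 1e-18)
  expect_lt(eqs$c_A / 1e-9, 1e-6)
})
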