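# Osmotic-pressure field operations. The field beta*pi(r) is the Lagrange
# multiplier enforcing local incompressibility; it is the single interaction
# potential of the theory. Multiplied by a volume it is dimensionless.

#' Boltzmann weight of one conformation in the osmotic field
#'
#' `exp(-sum_r beta*pi(r) v(r))`: the work of inserting the conformation's
#' per-shell volume against the local osmotic pressure.
#'
#' @param v per-shell occupied volume of the conformation (nm^3).
#' @param field per-shell `beta*pi(r)` (nm^-3).
#' @return positive scalar weight.
#' @export
conformation_weight <- function(v, field) {
  stopifnot(length(v) == length(field))
  exp(-sum(field * v))
}

#' Single-molecule partition function and conformer probabilities
#'
#' `q = sum_alpha P0(alpha) exp(-sum_r beta*pi(r) v(alpha, r))`, the
#' prior-weighted average Boltzmann factor over the sampled ensemble (for a
#' plain uniformly sampled ensemble the prior `P0` is uniform and `q` is the
#' simple conformer mean). Computed on the log scale (log-sum-exp) so
#' strongly crowded fields cannot underflow. Also returns the normalized
#' conformer probabilities `P(alpha)`.
#'
#' @param ensemble an `acnp_ensemble`.
#' @param field per-shell `beta*pi(r)`.
#' @return list with `q`, `log_q` and `P` (sums to 1).
#' @export
partition_function <- function(ensemble, field) {
  stopifnot(inherits(ensemble, "acnp_ensemble"),
            length(field) == ensemble$grid$n_layers)
  s <- as.vector(ensemble$V %*% field) - ensemble$log_prior
  m <- max(-s)
  w <- exp(-s - m)
  sw <- sum(w)
  lp0 <- max(ensemble$log_prior)
  log_norm <- lp0 + log(sum(exp(ensemble$log_prior - lp0)))
  list(
    q = exp(m + log(sw) - log_norm),
    log_q = m + log(sw) - log_norm,
    P = w / sw
  )
}

#' Solution-species and water density profiles in a given field
#'
#' Dilute solution species couple to the field through their total molecular
#' volume at the molecule's own shell:
#' `rho_j(r) = rho_j_bulk exp(-beta*pi(r) v_j)`; water satisfies
#' `rho_w(r) v_w = rho_w_bulk v_w exp(-beta*pi(r) v_w)`. At the outer
#' boundary (field ~ 0) all profiles reduce to their bulk values.
#'
#' @param bulk an [bulk_solution()] object.
#' @param field per-shell `beta*pi(r)`.
#' @param grid the [radial_grid()] the field lives on.
#' @return tibble with columns `r`, `rho_a`, `rho_A`, `rho_Aa`, `rho_Aaa`,
#'   `rho_w` (nm^-3) and `phi_solution`, `phi_water` (volume fractions).
#' @export
solution_density_profiles <- function(bulk, field, grid) {
  stopifnot(inherits(bulk, "acnp_bulk"), length(field) == grid$n_layers)
  rho <- vapply(
    names(bulk$rho),
    function(j) bulk$rho[[j]] * exp(-field * bulk$vols[[j]]),
    numeric(grid$n_layers)
  )
  rho_w <- bulk$rho_water * exp(-field * bulk$v_water)
  tibble::tibble(
    r = grid$mid,
    rho_a = rho[, "a"], rho_A = rho[, "A"],
    rho_Aa = rho[, "Aa"], rho_Aaa = rho[, "Aaa"],
    rho_w = rho_w,
    phi_solution = as.vector(rho %*% bulk$vols),
    phi_water = rho_w * bulk$v_water
  )
}

# Volume fraction of solution + water at field x (vectorized over shells)
.solvent_fill <- function(x, bulk) {
  fill <- bulk$rho_water * bulk$v_water * exp(-x * bulk$v_water)
  for (j in seq_along(bulk$rho)) {
    fill <- fill + bulk$phi[[j]] * exp(-x * bulk$vols[[j]])
  }
  fill
}

#' Local packing (incompressibility) residual
#'
#' `residual(r) = phi_bound(r) + phi_solution(r) + phi_water(r) - 1`; the
#' converged osmotic field makes this zero in every shell.
#'
#' @param field per-shell `beta*pi(r)`.
#' @param phi_bound per-shell volume fraction of surface-bound species.
#' @param bulk an [bulk_solution()] object.
#' @return numeric vector of per-shell residuals.
#' @export
packing_residual <- function(field, phi_bound, bulk) {
  stopifnot(length(field) == length(phi_bound))
  phi_bound + .solvent_fill(field, bulk) - 1
}

# Solve, per shell, for the field value that exactly fills the shell:
# .solvent_fill(x) = 1 - phi_bound. Vectorized damped Newton; the function is
# strictly decreasing in x. Shells with phi_bound >= 1 have no solution and
# are assigned `cap`.
.field_for_packing <- function(phi_bound, bulk, x0 = NULL, cap = 2e4,
                               tol = 1e-13, max_newton = 60) {
  n <- length(phi_bound)
  target <- 1 - phi_bound
  x <- rep(cap, n)
  feasible <- target > 1e-12
  if (any(feasible)) {
    tg <- target[feasible]
    # water-dominated closed form; exact when the dilute solutes are
    # negligible, and a monotonically convergent Newton start otherwise
    xi <- log(bulk$rho_water * bulk$v_water / tg) / bulk$v_water
    for (it in seq_len(max_newton)) {
      ew <- bulk$rho_water * bulk$v_water * exp(-xi * bulk$v_water)
      f <- ew
      df <- -bulk$v_water * ew
      for (j in seq_along(bulk$rho)) {
        ej <- bulk$phi[[j]] * exp(-xi * bulk$vols[[j]])
        f <- f + ej
        df <- df - bulk$vols[[j]] * ej
      }
      g <- f - tg
      if (max(abs(g)) < tol) break
      step <- g / pmin(df, -1e-300)
      step <- pmin(pmax(step, -50 / bulk$v_water), 50 / bulk$v_water)
      xi <- pmin(pmax(xi - step, -cap), cap)
    }
    x[feasible] <- xi
  }
  x
}
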