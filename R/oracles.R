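# Small independent oracles and synthetic fixtures. Everything here is
# deliberately simple and numerically independent of the self-consistent
# solver: the brute-force minimizer enumerates compositions on a simplex grid
# and solves each shell's packing equation by bisection, so that agreement
# with the solver is a genuine cross-check and not a tautology.

#' Ideal single-site occupancy (Langmuir isotherm)
#'
#' The dilute, field-free limit of the surface equilibrium: occupancy
#' `c / (c + Kd)`.
#'
#' @param c ligand concentration (M).
#' @param kd dissociation constant (M).
#' @return occupancy fraction in [0, 1].
#' @examples
#' langmuir_occupancy(1e-7, 1e-9) # 0.990099
#' @export
langmuir_occupancy <- function(c, kd) {
  stopifnot(all(c >= 0), all(kd >= 0), all(c + kd > 0))
  c / (c + kd)
}

#' A deterministic miniature world for tests and examples
#'
#' Small toy antibody and antigen, a coarse few-shell grid on a small
#' particle, and a reference constant set. Everything is closed-form
#' checkable and fast.
#'
#' @param n_shells number of radial shells.
#' @param r_np particle radius (nm).
#' @param dr shell thickness (nm).
#' @return list with `antibody`, `antigen`, `grid`, `kd`, `c_antigen`,
#'   `avidity_ratio`.
#' @export
toy_world <- function(n_shells = 4, r_np = 10, dr = 2) {
  list(
    antibody = toy_antibody(3),
    antigen = toy_antigen(),
    grid = radial_grid(r_np, dr = dr, r_max = r_np + n_shells * dr),
    kd = 1e-9, c_antigen = 100e-9, avidity_ratio = 100
  )
}

#' Random tiny surface system for solver validation
#'
#' Draws a small radial grid (2-5 shells), synthetic tethered-species
#' ensembles (1-3 conformations each, random sparse per-shell volumes) and
#' random binding conditions, sized so that crowding is appreciable. The
#' ensembles are built with [species_ensemble()] directly; they do not come
#' from conformer sampling.
#'
#' @param seed integer seed.
#' @return list with `ensembles`, `bulk`, `n_sites`, `grid`.
#' @export
tiny_system <- function(seed) {
  withr::with_seed(seed, {
    n_shells <- sample(2:5, 1)
    r_np <- stats::runif(1, 4, 8)
    dr <- stats::runif(1, 1, 2)
    grid <- radial_grid(r_np, dr, r_max = r_np + n_shells * dr)
    n_conf <- c(A = sample(1:3, 1), Aa = sample(1:3, 1), Aaa = sample(1:3, 1))
    # keep the exhaustive-oracle state space modest: at most one species
    # with the full three conformations
    while (sum(n_conf == 3) > 1) n_conf[sample(which(n_conf == 3), 1)] <- 2L
    mean_shell <- mean(grid$shell_volumes)
    n_sites <- stats::runif(1, 5, 40)
    ens <- lapply(names(n_conf), function(sp) {
      n <- n_conf[[sp]]
      scale <- c(A = 1, Aa = 1.5, Aaa = 2)[[sp]]
      V <- matrix(stats::runif(n * n_shells, 0, 0.02 * mean_shell * scale),
                  n, n_shells)
      V[stats::runif(length(V)) < 0.3] <- 0
      # keep the system feasible but appreciably crowded: no single
      # conformation may overfill any shell on its own
      over <- max(sweep(n_sites * V, 2, grid$shell_volumes, "/"))
      if (over > 0.8) V <- V * (0.8 / over)
      species_ensemble(
        V, com = stats::runif(n, grid$r_np, grid$r_np + n_shells * grid$dr),
        species = sp, n_antigens = match(sp, c("A", "Aa", "Aaa")) - 1L,
        molecular_volume = max(rowSums(V)), grid = grid
      )
    })
    names(ens) <- names(n_conf)
    bulk <- bulk_solution(
      c_antigen = 10^stats::runif(1, -9, -6),
      kd = 10^stats::runif(1, -10, -8),
      avidity_ratio = 10^stats::runif(1, 0, 2),
      v_antigen = 0.8, v_antibody = 2.7
    )
    list(ensembles = ens, bulk = bulk, n_sites = n_sites, grid = grid)
  })
}

#' Exhaustive-grid minimizer of the surface free energy (oracle)
#'
#' Independent cross-check for [solve_equilibrium()]. In joint-occupancy
#' coordinates `y[i, alpha] = f_i P_i(alpha)` the excess free energy is
#' convex: the entropy terms become `sum y ln y` plus linear terms, the
#' bound volume-fraction profile is linear in `y`, and the per-shell solvent
#' work (obtained here by bisection, not by the solver's Newton path) is
#' convex and increasing in the bound volume fraction. The oracle therefore
#' enumerates the full occupancy simplex exhaustively at `resolution`, then
#' refines the grid minimum by pairwise-exchange pattern search with
#' successively halved steps, which for a convex function converges to the
#' constrained minimum without basin ambiguity. Compositions overfilling any
#' shell are infeasible (+Inf).
#'
#' @param ensembles named list of `acnp_ensemble` (A, Aa, Aaa) with few
#'   conformations each, on a grid of at most 5 shells.
#' @param bulk an [bulk_solution()] object.
#' @param scheme "covalent" or "streptavidin".
#' @param n_sites number of surface sites.
#' @param resolution initial simplex grid step (default 0.1).
#' @param h_min final pattern-search step (default 1e-6).
#' @param max_states refuse coarse enumerations larger than this.
#' @return list with `beta_F`, `f`, `P`, `resolution` (final step).
#' @export
brute_force_minimum <- function(ensembles, bulk, scheme = "covalent",
                                n_sites, resolution = 0.1, h_min = 1e-6,
                                max_states = 1e6) {
  species <- c("A", "Aa", "Aaa")
  stopifnot(all(species %in% names(ensembles)))
  grid <- ensembles[[1]]$grid
  L <- grid$n_layers
  if (L > 5) stop("oracle limited to <= 5 shells")
  logK <- .log_binding_constants(bulk, scheme)
  n_conf <- vapply(ensembles[species], `[[`, integer(1), "n_conf")

  # occupancy slots: one per (species, conformation), plus an empty-site
  # slot for the streptavidin scheme (zero volume, unit weight)
  Vall <- do.call(rbind, lapply(ensembles[species], `[[`, "V"))
  slot_species <- rep(species, n_conf)
  # -log P0 per slot (uniform prior: log n) minus the species binding term
  log_p0 <- unlist(lapply(ensembles[species], function(e) {
    lp <- e$log_prior
    lp - (max(lp) + log(sum(exp(lp - max(lp)))))
  }))
  slot_const <- -log_p0 - rep(logK[species], n_conf)
  if (scheme == "streptavidin") {
    Vall <- rbind(0, Vall)
    slot_species <- c("S", slot_species)
    slot_const <- c(-logK[["S"]], slot_const)
  }
  d <- nrow(Vall)
  phi_per_y <- n_sites * sweep(Vall, 2, grid$shell_volumes, "/")

  # exact solvent excess per shell as a function of phi_bound (bisection on
  # a dense table + monotone spline; error far below the search resolution)
  excess_exact <- function(pb) {
    lo <- rep(0, length(pb))
    hi <- rep(1, length(pb))
    fill <- function(x) .solvent_fill(x, bulk)
    while (any(fill(hi) > 1 - pb)) hi <- hi * 2
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      too_full <- fill(mid) > 1 - pb
      lo[too_full] <- mid[too_full]
      hi[!too_full] <- mid[!too_full]
    }
    x <- (lo + hi) / 2
    rho_def <- bulk$rho_water * (1 - exp(-x * bulk$v_water))
    for (j in seq_along(bulk$rho)) {
      rho_def <- rho_def + bulk$rho[[j]] * (1 - exp(-x * bulk$vols[[j]]))
    }
    rho_def + x * (pb - 1)
  }
  pb_tab <- unique(sort(c(
    seq(0, 0.99, length.out = 3000),
    1 - 10^seq(-2, -6, length.out = 1500)
  )))
  exc_fun <- stats::splinefun(pb_tab, excess_exact(pb_tab), method = "hyman")

  finite_const <- ifelse(is.finite(slot_const), slot_const, 0)
  barred <- !is.finite(slot_const) # species absent from solution: no mass
  obj <- function(Y) {
    # Y: matrix of occupancy vectors, one per row
    phi_b <- Y %*% phi_per_y
    ent <- rowSums(ifelse(Y > 0, Y * log(pmax(Y, 1e-300)), 0)) +
      as.vector(Y %*% finite_const)
    if (any(barred)) {
      ent[rowSums(Y[, barred, drop = FALSE]) > 0] <- Inf
    }
    sol <- rep(Inf, length(phi_b))
    feas <- phi_b < 1 - 1e-6
    sol[feas] <- exc_fun(phi_b[feas])
    sol <- matrix(sol, nrow(Y), L)
    n_sites * ent + as.vector(sol %*% grid$shell_volumes)
  }

  # coarse exhaustive enumeration of the occupancy simplex
  N <- round(1 / resolution)
  n_states <- choose(N + d - 1, d - 1)
  if (n_states > max_states) {
    stop(sprintf("oracle state space too large: %g states", n_states))
  }
  comps <- .compositions(N, d) / N
  vals <- obj(comps)
  y <- comps[which.min(vals), ]
  best <- min(vals)

  # pairwise-exchange pattern search (sound for a convex objective)
  h <- resolution
  while (h >= h_min) {
    repeat {
      moves <- NULL
      for (i in seq_len(d)) {
        for (j in seq_len(d)) {
          if (i == j || y[j] < 1e-15) next
          cand <- y
          step <- min(h, cand[j])
          cand[i] <- cand[i] + step
          cand[j] <- cand[j] - step
          moves <- rbind(moves, cand)
        }
      }
      if (is.null(moves)) break
      mv <- obj(moves)
      if (min(mv) < best - 1e-14 * max(1, abs(best))) {
        k <- which.min(mv)
        y <- moves[k, ]
        best <- mv[k]
      } else {
        break
      }
    }
    h <- h / 2
  }

  y <- unname(y)
  f <- vapply(split(y, slot_species), sum, numeric(1))
  f <- f[unique(slot_species)]
  P <- lapply(species, function(sp) {
    ys <- unname(y[slot_species == sp])
    if (sum(ys) > 0) ys / sum(ys) else rep(1 / length(ys), length(ys))
  })
  names(P) <- species
  list(beta_F = unname(best), f = f, P = P, resolution = h * 2, y = y)
}

# all compositions of integer N into d non-negative parts, as a matrix of
# fractions-of-N rows
.compositions <- function(N, d) {
  if (d == 1) return(matrix(N, 1, 1))
  out <- vector("list", N + 1)
  for (k in 0:N) {
    sub <- .compositions(N - k, d - 1)
    out[[k + 1]] <- cbind(k, sub)
  }
  do.call(rbind, out)
}

#' Miniature sweep configurations mirroring the study conditions
#'
#' Named reduced-sampling configurations covering the qualitative regimes of
#' the theory (covalent scheme with and without spacer, affinity series,
#' small-particle limit, streptavidin scheme at low and high concentration).
#' Seeds are fixed; each runs in well under two minutes on one CPU.
#'
#' @param seed base seed.
#' @return named list of [sweep_config()] objects.
#' @export
mini_sweep_configs <- function(seed = 1) {
  base <- list(
    n_spacer_samples = 60, n_orientations = 6,
    dr = 0.5, seed = seed
  )
  cov_cover <- 10^seq(-3.2, -1.2, length.out = 7)
  strep_cover <- 10^seq(-3.2, -1.2, length.out = 7)
  make <- function(...) do.call(sweep_config, utils::modifyList(base, list(...)))
  list(
    "covalent-spacer" = make(
      scheme = "covalent", spacer = 50, kd = 1e-9, c_antigen = 100e-9,
      coverage = cov_cover
    ),
    "covalent-nospacer" = make(
      scheme = "covalent", spacer = 0, kd = 1e-9, c_antigen = 100e-9,
      coverage = cov_cover
    ),
    "covalent-kd11" = make(
      scheme = "covalent", spacer = 50, kd = 1e-11, c_antigen = 100e-9,
      coverage = cov_cover
    ),
    "covalent-smallnp" = make(
      scheme = "covalent", spacer = 50, kd = 1e-9, c_antigen = 100e-9,
      r_np = 10, coverage = cov_cover
    ),
    "strep-base" = make(
      scheme = "streptavidin", spacer = 50, kd = 1e-9,
      c_antigen = 200e-9, c_antibody = 100e-9, coverage = strep_cover
    ),
    "strep-hiconc" = make(
      scheme = "streptavidin", spacer = 50, kd = 1e-9,
      c_antigen = 2000e-9, c_antibody = 1000e-9, coverage = strep_cover
    )
  )
}
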