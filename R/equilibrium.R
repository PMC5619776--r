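#' Convert a dissociation constant to a dimensionless binding potential
#'
#' `ln(Kd / c0)` with standard state `c0 = 1 M`, so that the dilute
#' mass-action ratio `f_bound / f_free = c / Kd` is recovered exactly when
#' the potential enters a Boltzmann factor with the concentration measured
#' in molar.
#'
#' @param kd dissociation constant (M), > 0.
#' @return dimensionless standard-state binding free energy (beta units).
#' @examples
#' kd_to_potential(1)     # 0
#' kd_to_potential(1e-9)  # -9 ln 10
#' @export
kd_to_potential <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("Kd must be positive")
  log(kd)
}

# log effective binding constants per surface species. The q_i multiply these
# in the surface equilibrium; fractions are f_i ~ q_i exp(logK_i).
.log_binding_constants <- function(bulk, scheme) {
  g <- bulk$g_stat
  if (scheme == "covalent") {
    l1 <- log(g) + log(bulk$conc[["a"]]) - log(bulk$kd)
    l2 <- l1 + log(bulk$conc[["a"]]) - log(g * bulk$kd * bulk$avidity_ratio)
    c(A = 0, Aa = unname(l1), Aaa = unname(l2))
  } else {
    c(
      S = 0,
      A = log(bulk$conc[["A"]]) - log(bulk$kd_biotin),
      Aa = log(bulk$conc[["Aa"]]) - log(bulk$kd_biotin),
      Aaa = log(bulk$conc[["Aaa"]]) - log(bulk$kd_biotin)
    )
  }
}

.softmax <- function(logw) {
  m <- max(logw)
  if (!is.finite(m)) logw <- rep(0, length(logw)) # all -Inf cannot happen
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Surface species fractions, covalent conjugation
#'
#' Antibodies cannot detach: the fractions of grafted sites carrying an
#' unbound antibody, a one-antigen and a two-antigen complex follow
#' `f_A : f_Aa : f_Aaa = q_A : q_Aa g (c_a/Kd) : q_Aaa g (c_a/Kd) *
#' c_a/(g Kd rho_av)` with statistical factor `g = 2` for two equivalent Fab
#' sites (the second ligation carries the compensating 1/2 so the bulk and
#' surface conventions agree); `g = 1` applies no statistical factors.
#'
#' @param q_A,q_Aa,q_Aaa single-molecule partition functions of the tethered
#'   species in the current osmotic field (1 in the field-free limit).
#' @param c_a free antigen concentration (M).
#' @param kd per-site dissociation constant (M).
#' @param avidity_ratio second-site Kd ratio (may be Inf).
#' @param g_stat statistical factor mode, 2 (default) or 1.
#' @return named numeric vector `(A, Aa, Aaa)` summing to 1.
#' @examples
#' surface_fractions_covalent(1, 1, 1, c_a = 1e-9, kd = 1e-9,
#'                            avidity_ratio = Inf, g_stat = 1)
#' @export
surface_fractions_covalent <- function(q_A, q_Aa, q_Aaa, c_a, kd,
                                       avidity_ratio = 100, g_stat = 2) {
  stopifnot(q_A >= 0, q_Aa >= 0, q_Aaa >= 0, c_a >= 0, kd > 0,
            avidity_ratio > 0, g_stat %in% c(1, 2))
  bulk <- list(conc = c(a = c_a), kd = kd, avidity_ratio = avidity_ratio,
               g_stat = g_stat)
  logK <- .log_binding_constants(bulk, "covalent")
  f <- .softmax(log(c(q_A, q_Aa, q_Aaa)) + logK)
  stats::setNames(f, c("A", "Aa", "Aaa"))
}

#' Surface species fractions, streptavidin-biotin conjugation
#'
#' Streptavidin sites are punctual and may stay empty; each biotinylated
#' solution species j adsorbs with mass action
#' `f_j / f_empty = q_j c_j / Kd_biotin`. Even with a femtomolar
#' `Kd_biotin`, `f_empty` can be large when crowding suppresses the `q_j`.
#'
#' @param q named or positional partition functions for (A, Aa, Aaa).
#' @param conc concentrations (M) of the biotinylated solution species
#'   (A, Aa, Aaa), typically from [solve_bulk_equilibrium()].
#' @param kd_biotin streptavidin-biotin dissociation constant (M).
#' @return named numeric vector `(S, A, Aa, Aaa)` summing to 1 (`S` = empty).
#' @export
surface_fractions_streptavidin <- function(q, conc, kd_biotin = 1e-14) {
  stopifnot(length(q) == 3, length(conc) == 3, all(q >= 0), all(conc >= 0),
            kd_biotin > 0)
  if (all(conc == 0)) {
    warning("no biotinylated species in solution; all sites empty")
    return(stats::setNames(c(1, 0, 0, 0), c("S", "A", "Aa", "Aaa")))
  }
  logw <- c(0, log(q) + log(conc) - log(kd_biotin))
  stats::setNames(.softmax(logw), c("S", "A", "Aa", "Aaa"))
}

#' Solve the self-consistent equilibrium of an antibody-conjugated
#' nanoparticle
#'
#' Finds the osmotic-pressure field `beta*pi(r)` for which the surface
#' composition, conformer probabilities and solution density profiles it
#' generates satisfy local incompressibility in every radial shell. The
#' iteration is an Anderson-accelerated damped fixed point: from the current
#' field compute conformer probabilities and surface fractions, obtain the
#' bound-layer volume-fraction profile, and solve each shell's packing
#' equation for the field that would fill it exactly (damped Newton per
#' shell); the accelerated mixture of these maps is the next field.
#'
#' @param ensembles named list of `acnp_ensemble` objects for the tethered
#'   species `A`, `Aa`, `Aaa` (all on one grid).
#' @param bulk an [bulk_solution()] object.
#' @param scheme "covalent" (antibodies permanently grafted) or
#'   "streptavidin" (punctual sites that bind biotinylated species, may stay
#'   empty).
#' @param n_sites number of active surface sites (mean-field, continuous).
#' @param control list: `tol` (max-norm packing residual, default 1e-8),
#'   `max_iter` (default 2000), `damping` (default 0.5), `anderson_m`
#'   (history length, default 5; 0 disables acceleration), `field_init`
#'   (warm-start field), `on_fail` ("error" or "return").
#' @return an object of class `acnp_state`; see [tidy.acnp_state()] and
#'   [glance.acnp_state()] for tabular views.
#' @export
solve_equilibrium <- function(ensembles, bulk, scheme = c("covalent", "streptavidin"),
                              n_sites, control = list()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(bulk, "acnp_bulk"), n_sites >= 0)
  stopifnot(all(c("A", "Aa", "Aaa") %in% names(ensembles)))
  species <- c("A", "Aa", "Aaa")
  grid <- ensembles[[1]]$grid
  for (e in ensembles[species]) {
    stopifnot(inherits(e, "acnp_ensemble"), e$grid$n_layers == grid$n_layers)
  }
  ctl <- utils::modifyList(
    list(tol = 1e-8, max_iter = 2000, damping = 0.5, anderson_m = 5,
         field_init = NULL, on_fail = "error"),
    control
  )
  L <- grid$n_layers
  logK <- .log_binding_constants(bulk, scheme)
  Vt <- lapply(ensembles[species], function(e) t(e$V))

  eval_at <- function(x) {
    pf <- lapply(ensembles[species], partition_function, field = x)
    log_q <- vapply(pf, `[[`, numeric(1), "log_q")
    if (scheme == "covalent") {
      f <- .softmax(log_q + logK)
      names(f) <- species
    } else {
      f <- .softmax(c(0, log_q + logK[species]))
      names(f) <- c("S", species)
    }
    u <- vapply(
      species,
      function(sp) as.vector(Vt[[sp]] %*% pf[[sp]]$P),
      numeric(L)
    ) # L x 3: expected per-shell volume per bound molecule
    phi_b <- n_sites * as.vector(u %*% f[species]) / grid$shell_volumes
    list(pf = pf, log_q = log_q, f = f, u = u, phi_b = phi_b,
         residual = packing_residual(x, phi_b, bulk))
  }

  x <- if (is.null(ctl$field_init)) numeric(L) else {
    stopifnot(length(ctl$field_init) == L)
    as.numeric(ctl$field_init)
  }
  m <- ctl$anderson_m
  X_hist <- G_hist <- NULL
  hist_res <- numeric(0)
  lambda <- ctl$damping
  cur <- eval_at(x)
  iter <- 0L
  while (iter < ctl$max_iter) {
    maxres <- max(abs(cur$residual))
    hist_res <- c(hist_res, maxres)
    if (maxres <= ctl$tol) break
    # stalled acceleration: hand over to the Newton fallback below
    if (iter >= 100 && maxres > 0.5 * hist_res[iter - 50]) break
    g <- .field_for_packing(cur$phi_b, bulk, x0 = x)
    fvec <- g - x
    x_acc <- NULL
    if (m > 0 && !is.null(X_hist) && ncol(X_hist) >= 1) {
      k <- ncol(X_hist)
      use <- max(1, k - m + 1):k
      Xa <- cbind(X_hist[, use, drop = FALSE], x)
      Ga <- cbind(G_hist[, use, drop = FALSE], g)
      Fa <- Ga - Xa
      j <- ncol(Xa)
      dX <- Xa[, -1, drop = FALSE] - Xa[, -j, drop = FALSE]
      dF <- Fa[, -1, drop = FALSE] - Fa[, -j, drop = FALSE]
      gamma <- tryCatch(
        qr.solve(dF, fvec, tol = 1e-12),
        error = function(e) NULL
      )
      if (!is.null(gamma) && all(is.finite(gamma))) {
        x_acc <- as.vector(x + fvec - (dX + dF) %*% gamma)
      }
    }
    X_hist <- cbind(X_hist, x)
    G_hist <- cbind(G_hist, g)
    if (ncol(X_hist) > m + 1) {
      X_hist <- X_hist[, -1, drop = FALSE]
      G_hist <- G_hist[, -1, drop = FALSE]
    }
    # try the accelerated step; accept if it does not worsen the residual,
    # otherwise fall back to damped fixed-point steps with step halving
    accepted <- FALSE
    if (!is.null(x_acc)) {
      nxt <- eval_at(x_acc)
      if (all(is.finite(nxt$residual)) &&
          max(abs(nxt$residual)) <= maxres * 1.5) {
        x <- x_acc
        cur <- nxt
        accepted <- TRUE
        lambda <- min(1, lambda * 1.5)
      }
    }
    if (!accepted) {
      lam <- lambda
      for (try in 1:10) {
        x_try <- x + lam * fvec
        nxt <- eval_at(x_try)
        if (all(is.finite(nxt$residual)) &&
            (max(abs(nxt$residual)) < maxres || try == 10)) {
          x <- x_try
          cur <- nxt
          break
        }
        lam <- lam / 2
      }
      lambda <- max(lam, 1e-3)
      X_hist <- G_hist <- NULL # history no longer consistent with damping
    }
    iter <- iter + 1L
  }
  maxres <- max(abs(cur$residual))
  if (maxres > ctl$tol) {
    # damped Newton on the packing residual with a forward-difference
    # Jacobian; robust for stiff, strongly crowded compositions where the
    # accelerated fixed point stalls
    for (nit in seq_len(60)) {
      R0 <- cur$residual
      maxres <- max(abs(R0))
      hist_res <- c(hist_res, maxres)
      if (maxres <= ctl$tol) break
      J <- matrix(0, L, L)
      for (kk in seq_len(L)) {
        h <- 1e-6 * (1 + abs(x[kk]))
        xh <- x
        xh[kk] <- xh[kk] + h
        J[, kk] <- (eval_at(xh)$residual - R0) / h
      }
      dx <- tryCatch(
        solve(J, -R0),
        error = function(e) {
          solve(J + diag(1e-10, L), -R0)
        }
      )
      lam <- 1
      for (try in 1:20) {
        nxt <- eval_at(x + lam * dx)
        if (all(is.finite(nxt$residual)) &&
            max(abs(nxt$residual)) < maxres) break
        lam <- lam / 2
      }
      x <- x + lam * dx
      cur <- nxt
      iter <- iter + 1L
    }
    maxres <- max(abs(cur$residual))
  }
  converged <- maxres <= ctl$tol
  if (!converged && ctl$on_fail == "error") {
    osc <- length(hist_res) > 50 &&
      stats::sd(utils::tail(hist_res, 20)) > 0.1 * mean(utils::tail(hist_res, 20))
    stop(sprintf(
      paste0("self-consistent field did not converge in %d iterations ",
             "(max residual %.3e)%s; residual history tail: %s"),
      iter, maxres,
      if (osc) "; oscillation detected, try stronger damping (smaller `damping`)" else "",
      paste(signif(utils::tail(hist_res, 6), 3), collapse = ", ")
    ))
  }

  fe <- .free_energy_eval(
    f = cur$f, P = lapply(cur$pf, `[[`, "P"), x = x,
    ensembles = ensembles[species], bulk = bulk,
    n_sites = n_sites, logK = logK, scheme = scheme, grid = grid
  )
  rcom <- vapply(
    species,
    function(sp) sum(cur$pf[[sp]]$P * ensembles[[sp]]$com),
    numeric(1)
  )
  f_ab <- cur$f[species]
  captured <- n_sites * (f_ab[["Aa"]] + 2 * f_ab[["Aaa"]])
  structure(
    list(
      grid = grid, field = x, bulk = bulk, scheme = scheme,
      n_sites = n_sites, coverage = n_sites / (4 * pi * grid$r_np^2),
      f = cur$f, P = lapply(cur$pf, `[[`, "P"), log_q = cur$log_q,
      phi_bound = cur$phi_b,
      phi_bound_species = sweep(cur$u, 2, n_sites * f_ab, "*") /
        grid$shell_volumes,
      beta_F = fe$total, beta_F_components = fe$components,
      captured_antigen = captured,
      captured_per_area = captured / (4 * pi * grid$r_np^2),
      rcom = rcom,
      diagnostics = list(
        iterations = iter, residual_max = maxres, converged = converged,
        residual_history = hist_res,
        f_norm_dev = abs(sum(cur$f) - 1),
        p_norm_dev = max(vapply(cur$pf, function(p) abs(sum(p$P) - 1),
                                numeric(1)))
      ),
      ensembles = ensembles[species], logK = logK
    ),
    class = "acnp_state"
  )
}

#' @export
print.acnp_state <- function(x, ...) {
  cat(sprintf(
    "<acnp_state> %s scheme, N_s = %.4g (sigma = %.3g /nm^2) on r_np = %g nm\n",
    x$scheme, x$n_sites, x$coverage, x$grid$r_np
  ))
  cat(sprintf("  captured antigen = %.4g (%.3g /nm^2), beta_F = %.6g\n",
              x$captured_antigen, x$captured_per_area, x$beta_F))
  cat("  fractions:", paste(sprintf("%s=%.4g", names(x$f), x$f), collapse = " "),
      "\n")
  cat(sprintf("  converged: %s (max residual %.2e, %d iterations)\n",
              x$diagnostics$converged, x$diagnostics$residual_max,
              x$diagnostics$iterations))
  invisible(x)
}

# Free-energy evaluation: excess semi-grand potential relative to the uniform
# bulk solution, for an arbitrary feasible surface composition (f, P). The
# osmotic field is the one that packs that composition (`x`); pass it when
# already available (converged state), otherwise it is recomputed.
.free_energy_eval <- function(f, P, x = NULL, ensembles, bulk, n_sites,
                              logK, scheme, grid) {
  species <- names(ensembles)
  u <- vapply(
    species,
    function(sp) as.vector(t(ensembles[[sp]]$V) %*% P[[sp]]),
    numeric(grid$n_layers)
  )
  f_ab <- f[species]
  phi_b <- n_sites * as.vector(u %*% f_ab) / grid$shell_volumes
  if (is.null(x)) x <- .field_for_packing(phi_b, bulk)
  if (any(phi_b >= 1 - 1e-12)) {
    return(list(total = Inf, components = NULL, field = x))
  }
  # conformational entropy relative to the sampling prior: KL(P || P0) >= 0
  kl <- function(p, lp) {
    p0 <- exp(lp - max(lp))
    p0 <- p0 / sum(p0)
    sum(ifelse(p > 0, p * (log(p) - log(p0)), 0))
  }
  conf <- n_sites * sum(vapply(
    species,
    function(sp) f_ab[[sp]] * kl(P[[sp]], ensembles[[sp]]$log_prior),
    numeric(1)
  ))
  # mixing entropy and self-energy (binding constants fold the standard
  # chemical potentials and bulk activities)
  fl <- f[f > 0]
  lk <- logK[names(fl)]
  mix <- n_sites * sum(fl * (log(fl) - lk))
  # solvent excess: partial minimization over water + dilute solutes
  rho_def <- bulk$rho_water * (1 - exp(-x * bulk$v_water))
  for (j in seq_along(bulk$rho)) {
    rho_def <- rho_def + bulk$rho[[j]] * (1 - exp(-x * bulk$vols[[j]]))
  }
  solvent <- sum(grid$shell_volumes * (rho_def + x * (phi_b - 1)))
  total <- conf + mix + solvent
  list(
    total = total,
    components = c(conformational = conf, mixing = mix, solvent = solvent),
    field = x
  )
}

#' Free energy of an equilibrium state
#'
#' The excess semi-grand potential (beta units) of the converged state
#' relative to the uniform bulk solution: the sum of the bound species'
#' conformational entropy (relative to the field-free ensemble), their
#' mixing entropy and effective binding free energies, and the solvent
#' (water + dilute solution species) osmotic work. Zero for a bare particle
#' in pure solvent.
#'
#' @param state an `acnp_state`.
#' @return scalar `beta F` with attribute `components`.
#' @export
free_energy <- function(state) {
  stopifnot(inherits(state, "acnp_state"))
  structure(state$beta_F, components = state$beta_F_components)
}

#' Captured antigen of an equilibrium state
#'
#' `N_s (f_Aa + 2 f_Aaa)`: one- plus twice the two-antigen complexes over
#' the active sites, as an absolute count and per unit particle area.
#'
#' @param state an `acnp_state`.
#' @return tibble with `count` and `per_area` (antigens/nm^2).
#' @export
captured_antigen <- function(state) {
  stopifnot(inherits(state, "acnp_state"))
  tibble::tibble(
    count = state$captured_antigen,
    per_area = state$captured_per_area
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-shell profiles of an equilibrium state
#'
#' @param x an `acnp_state`.
#' @param ... unused.
#' @return tibble with one row per radial shell: `r`, the osmotic field
#'   `beta_pi`, bound-species volume fractions, solution and water volume
#'   fractions, and the packing residual.
#' @exportS3Method generics::tidy
tidy.acnp_state <- function(x, ...) {
  sol <- solution_density_profiles(x$bulk, x$field, x$grid)
  tibble::tibble(
    r = x$grid$mid,
    beta_pi = x$field,
    phi_bound = x$phi_bound,
    phi_A = x$phi_bound_species[, "A"],
    phi_Aa = x$phi_bound_species[, "Aa"],
    phi_Aaa = x$phi_bound_species[, "Aaa"],
    phi_solution = sol$phi_solution,
    phi_water = sol$phi_water,
    residual = x$phi_bound + sol$phi_solution + sol$phi_water - 1
  )
}

#' One-row summary of an equilibrium state
#'
#' @param x an `acnp_state`.
#' @param ... unused.
#' @return tibble with coverage, species fractions, captured antigen,
#'   mean center-of-mass radii, free energy and convergence diagnostics.
#' @exportS3Method generics::glance
glance.acnp_state <- function(x, ...) {
  f <- x$f
  tibble::tibble(
    scheme = x$scheme,
    r_np = x$grid$r_np,
    n_sites = x$n_sites,
    coverage = x$coverage,
    f_empty = if ("S" %in% names(f)) f[["S"]] else 0,
    f_A = f[["A"]], f_Aa = f[["Aa"]], f_Aaa = f[["Aaa"]],
    captured = x$captured_antigen,
    captured_per_area = x$captured_per_area,
    bound_antibodies = x$n_sites * sum(f[c("A", "Aa", "Aaa")]),
    rcom_A = x$rcom[["A"]], rcom_Aa = x$rcom[["Aa"]],
    rcom_Aaa = x$rcom[["Aaa"]],
    beta_F = x$beta_F,
    iterations = x$diagnostics$iterations,
    residual_max = x$diagnostics$residual_max,
    converged = x$diagnostics$converged
  )
}

#' Write a converged equilibrium state to disk
#'
#' Scalars, fractions and diagnostics go to `<prefix>.json`; the per-shell
#' profiles ([tidy.acnp_state()]) to `<prefix>.tsv`.
#'
#' @param state an `acnp_state`.
#' @param prefix file path prefix.
#' @return invisibly, the two file paths.
#' @export
write_state <- function(state, prefix) {
  stopifnot(inherits(state, "acnp_state"))
  js <- paste0(prefix, ".json")
  tsv <- paste0(prefix, ".tsv")
  jsonlite::write_json(
    c(as.list(glance(state)),
      list(beta_F_components = as.list(state$beta_F_components))),
    js, auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(tidy(state), tsv)
  invisible(c(js, tsv))
}
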