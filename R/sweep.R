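#' Configuration for a binding-curve parameter sweep
#'
#' Describes one family of calculations: conjugation scheme, particle radii,
#' spacer lengths, affinities, bulk conditions and the coverage grid. All
#' sweep axes may be vectors; the sweep crosses them. Conformer ensembles are
#' generated once per (radius, spacer, species) combination and reused across
#' coverage points and affinities.
#'
#' @param scheme "covalent" or "streptavidin".
#' @param r_np nanoparticle radii (nm).
#' @param spacer spacer lengths (monomers; 0 = no spacer).
#' @param kd antibody-antigen dissociation constants (M).
#' @param avidity_ratio second-site Kd ratio.
#' @param kd_biotin streptavidin-biotin Kd (M).
#' @param g_stat statistical factor mode (2 or 1).
#' @param c_antigen bulk antigen concentration(s) (M). For the streptavidin
#'   scheme this is the total antigen mixed in.
#' @param c_antibody total antibody concentration(s) (M); streptavidin scheme
#'   only (the solution pre-equilibrium splits it into species).
#' @param coverage surface coverages sigma (antibodies or sites per nm^2);
#'   default 25 log-spaced points in [1e-4, 1e-2].
#' @param n_spacer_samples spacer conformations per ensemble.
#' @param stretch_bias trans-bias strata for spacer importance sampling
#'   (see [spacer_conformations()]); the default four strata keep strongly
#'   stretched layers statistically stable.
#' @param n_orientations rigid-body orientations per spacer conformation.
#' @param antibody,antigen optional `acnp_bead_model`s (e.g. from
#'   [read_alpha_carbon_beads()]); the defaults are the deterministic
#'   [toy_igg()] (~1320 beads) and a 480-bead [toy_globule()], which carry
#'   the molecular volumes of an IgG and a gp120-sized antigen.
#' @param dr,r_max_offset radial grid: shell thickness and extent beyond the
#'   particle surface (nm).
#' @param seed integer seed governing all conformer sampling.
#' @param solver control list passed to [solve_equilibrium()].
#' @return an object of class `acnp_sweep_config`.
#' @export
sweep_config <- function(scheme = "covalent", r_np = 50, spacer = 50,
                         kd = 1e-9, avidity_ratio = 100, kd_biotin = 1e-14,
                         g_stat = 2, c_antigen = 100e-9, c_antibody = 0,
                         coverage = 10^seq(-4, -2, length.out = 25),
                         n_spacer_samples = 200, n_orientations = 10,
                         stretch_bias = c(1, 4, 16, 64),
                         antibody = NULL, antigen = NULL,
                         dr = 0.5, r_max_offset = 60, seed = 1,
                         solver = list()) {
  scheme <- match.arg(scheme, c("covalent", "streptavidin"))
  stopifnot(length(r_np) >= 1, all(r_np > 0), length(spacer) >= 1,
            all(spacer >= 0), length(kd) >= 1, all(kd > 0),
            length(coverage) >= 1, all(coverage > 0),
            all(c_antigen >= 0), all(c_antibody >= 0),
            n_spacer_samples >= 1, n_orientations >= 1, dr > 0,
            r_max_offset > 0)
  if (scheme == "streptavidin" && all(c_antibody == 0)) {
    stop("streptavidin scheme needs a total antibody concentration")
  }
  structure(
    list(
      scheme = scheme, r_np = r_np, spacer = spacer, kd = kd,
      avidity_ratio = avidity_ratio, kd_biotin = kd_biotin, g_stat = g_stat,
      c_antigen = c_antigen, c_antibody = c_antibody, coverage = coverage,
      n_spacer_samples = n_spacer_samples, n_orientations = n_orientations,
      stretch_bias = stretch_bias,
      antibody = antibody, antigen = antigen,
      dr = dr, r_max_offset = r_max_offset, seed = seed, solver = solver
    ),
    class = "acnp_sweep_config"
  )
}

#' Build the tethered-species ensembles for one (radius, spacer) geometry
#'
#' Generates the spacer set and assembles the surface ensembles of the
#' unbound antibody and its one- and two-antigen complexes on a shared grid.
#'
#' @param config an [sweep_config()].
#' @param r_np particle radius (nm).
#' @param spacer spacer length (monomers).
#' @return list with `grid` and `ensembles` (named A/Aa/Aaa).
#' @export
build_ensembles <- function(config, r_np, spacer) {
  grid <- radial_grid(r_np, dr = config$dr, r_max = r_np + config$r_max_offset)
  ab <- if (is.null(config$antibody)) toy_igg() else config$antibody
  ag <- if (is.null(config$antigen)) toy_globule(480, label = "antigen") else config$antigen
  sp <- spacer_conformations(spacer, config$n_spacer_samples,
                             seed = config$seed,
                             stretch_bias = config$stretch_bias)
  # one seed for all three species: the same spacer conformations, rigid
  # rotations and joint directions underlie A, Aa and Aaa, so the sampling
  # noise of rare stretched conformations cancels in the q_Aa/q_A ratios
  # (common random numbers)
  ens <- lapply(0:2, function(na) {
    assemble_conformers(
      sp, ab, ag,
      n_antigens = na, n_orientations = config$n_orientations,
      grid = grid, seed = config$seed + 1L
    )
  })
  names(ens) <- c("A", "Aa", "Aaa")
  list(grid = grid, ensembles = ens, antibody = ab, antigen = ag)
}

#' Run a binding-curve sweep
#'
#' Solves one self-consistent equilibrium per grid point of the sweep
#' (crossing radii, spacer lengths, affinities, concentrations and the
#' coverage axis) and assembles the binding curves. Within one curve the
#' solver is warm-started from the previous coverage point. Failed points
#' are flagged (`converged = FALSE`) and reported, never silently dropped.
#'
#' @param config an [sweep_config()].
#' @param quiet suppress per-point progress messages.
#' @return a tibble of class `acnp_curves`: one row per solved point with
#'   identifying columns (`scheme`, `r_np`, `spacer`, `kd`, `c_antigen`,
#'   `c_antibody`), the coverage axis (`coverage`, `n_sites`), the
#'   observables of [glance.acnp_state()], and a `manifest` attribute
#'   (seeds, ensemble acceptances, timing).
#' @export
run_sweep <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "acnp_sweep_config"))
  t0 <- Sys.time()
  geo <- tidyr::expand_grid(r_np = config$r_np, spacer = config$spacer)
  acceptances <- list()
  rows <- list()
  n_fail <- 0L
  for (gi in seq_len(nrow(geo))) {
    built <- build_ensembles(config, geo$r_np[gi], geo$spacer[gi])
    acceptances[[paste0("r", geo$r_np[gi], "_s", geo$spacer[gi])]] <-
      vapply(built$ensembles, `[[`, numeric(1), "acceptance")
    conds <- tidyr::expand_grid(
      kd = config$kd,
      c_antigen = config$c_antigen,
      c_antibody = if (config$scheme == "streptavidin") config$c_antibody else 0
    )
    for (ci in seq_len(nrow(conds))) {
      bulk <- .sweep_bulk(config, conds$kd[ci], conds$c_antigen[ci],
                          conds$c_antibody[ci], built)
      field <- NULL
      for (sigma in sort(config$coverage)) {
        n_sites <- sigma * 4 * pi * geo$r_np[gi]^2
        ctl <- utils::modifyList(config$solver, list(field_init = field,
                                                     on_fail = "return"))
        state <- solve_equilibrium(
          built$ensembles, bulk, scheme = config$scheme,
          n_sites = n_sites, control = ctl
        )
        if (!state$diagnostics$converged) {
          n_fail <- n_fail + 1L
          warning(sprintf(
            "point not converged: r_np=%g spacer=%d kd=%.3g sigma=%.4g",
            geo$r_np[gi], geo$spacer[gi], conds$kd[ci], sigma
          ), call. = FALSE)
        } else {
          field <- state$field
        }
        if (!quiet) {
          message(sprintf(
            "r_np=%g spacer=%d kd=%.3g sigma=%.4g: captured=%.4g (%d it)",
            geo$r_np[gi], geo$spacer[gi], conds$kd[ci], sigma,
            state$captured_antigen, state$diagnostics$iterations
          ))
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            spacer = geo$spacer[gi], kd = conds$kd[ci],
            c_antigen = conds$c_antigen[ci], c_antibody = conds$c_antibody[ci]
          ),
          glance(state)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "scheme", "r_np", "spacer", "kd",
                         "c_antigen", "c_antibody", "coverage", "n_sites")
  attr(out, "manifest") <- list(
    seed = config$seed,
    n_spacer_samples = config$n_spacer_samples,
    n_orientations = config$n_orientations,
    ensemble_acceptance = acceptances,
    n_points = nrow(out), n_failed = n_fail,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("acnp"))
  )
  attr(out, "config") <- config
  class(out) <- c("acnp_curves", class(out))
  out
}

# bulk solution for one sweep condition (streptavidin: pre-equilibrate)
.sweep_bulk <- function(config, kd, c_antigen, c_antibody, built) {
  v_ag <- model_volume(built$antigen)
  v_ab <- model_volume(built$antibody)
  if (config$scheme == "covalent") {
    bulk_solution(
      c_antigen = c_antigen, kd = kd,
      avidity_ratio = config$avidity_ratio, kd_biotin = config$kd_biotin,
      g_stat = config$g_stat, v_antigen = v_ag, v_antibody = v_ab
    )
  } else {
    eq <- solve_bulk_equilibrium(
      c_antigen, c_antibody, kd,
      avidity_ratio = config$avidity_ratio, g_stat = config$g_stat
    )
    bulk_solution(
      c_antigen = eq$c_a, c_antibody = eq$c_A, c_complex1 = eq$c_Aa,
      c_complex2 = eq$c_Aaa, kd = kd,
      avidity_ratio = config$avidity_ratio, kd_biotin = config$kd_biotin,
      g_stat = config$g_stat, v_antigen = v_ag, v_antibody = v_ab
    )
  }
}

#' Locate the binding maximum of a curve
#'
#' Parabolic interpolation through the three points bracketing the discrete
#' argmax of the selected observable along the coverage axis. If the argmax
#' is an endpoint the endpoint is returned with `boundary = TRUE` (no
#' interior maximum). Ties break toward the lowest coverage.
#'
#' @param curve a tibble with a `coverage` column (one curve; filter a
#'   multi-condition [run_sweep()] result first).
#' @param observable column to maximize (default "captured").
#' @return one-row tibble: `coverage_at_max`, `value_at_max`, `boundary`.
#' @export
find_binding_maximum <- function(curve, observable = "captured") {
  stopifnot(observable %in% names(curve), "coverage" %in% names(curve))
  curve <- dplyr::arrange(curve, .data$coverage)
  x <- curve$coverage
  y <- curve[[observable]]
  if (length(x) < 3) stop("need at least 3 points to locate a maximum")
  i <- which.max(y)
  if (i == 1 || i == length(x)) {
    return(tibble::tibble(coverage_at_max = x[i], value_at_max = y[i],
                          boundary = TRUE))
  }
  x3 <- x[(i - 1):(i + 1)]
  y3 <- y[(i - 1):(i + 1)]
  d1 <- (y3[2] - y3[1]) / (x3[2] - x3[1])
  d2 <- (y3[3] - y3[2]) / (x3[3] - x3[2])
  a <- (d2 - d1) / (x3[3] - x3[1])
  if (a >= 0) { # flat or concave-up bracket: fall back to the grid argmax
    return(tibble::tibble(coverage_at_max = x[i], value_at_max = y[i],
                          boundary = FALSE))
  }
  xv <- (x3[1] + x3[2]) / 2 - d1 / (2 * a)
  yv <- y3[1] + d1 * (xv - x3[1]) + a * (xv - x3[1]) * (xv - x3[2])
  tibble::tibble(coverage_at_max = xv, value_at_max = yv, boundary = FALSE)
}

#' Write sweep outputs to disk
#'
#' Writes one TSV per condition group (scheme, radius, spacer, Kd,
#' concentrations), a run-manifest JSON, and optionally per-shell profile
#' TSVs for supplied states.
#'
#' @param curves an `acnp_curves` tibble from [run_sweep()].
#' @param outdir output directory (created if missing).
#' @param states optional named list of `acnp_state` objects whose per-shell
#'   profiles ([tidy.acnp_state()]) are written as `profile_<name>.tsv`.
#' @return invisibly, the vector of written file paths.
#' @export
write_sweep_outputs <- function(curves, outdir, states = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)
  if (nrow(curves) > 0) {
    grp <- dplyr::group_by(curves, .data$scheme, .data$r_np, .data$spacer,
                           .data$kd, .data$c_antigen, .data$c_antibody)
    keys <- dplyr::group_keys(grp)
    splits <- dplyr::group_split(grp)
    for (i in seq_along(splits)) {
      k <- keys[i, ]
      fn <- file.path(outdir, sprintf(
        "curve_%s_r%g_sp%g_kd%.0e_ca%.3g_cab%.3g.tsv",
        k$scheme, k$r_np, k$spacer, k$kd, k$c_antigen, k$c_antibody
      ))
      readr::write_tsv(splits[[i]], fn)
      paths <- c(paths, fn)
    }
  }
  for (nm in names(states)) {
    fn <- file.path(outdir, paste0("profile_", nm, ".tsv"))
    readr::write_tsv(tidy(states[[nm]]), fn)
    paths <- c(paths, fn)
  }
  mf <- file.path(outdir, "manifest.json")
  manifest <- attr(curves, "manifest")
  if (is.null(manifest)) manifest <- list(n_points = nrow(curves))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mf)
  invisible(paths)
}
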