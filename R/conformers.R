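#' Bin the occupied volume of a conformation into radial shells
#'
#' Each bead contributes its full volume to the shell containing its center
#' (the grid's default `dr` is comparable to the bead diameter, so exact
#' spherical-cap splitting is unnecessary; the total is exactly conserved).
#'
#' @param positions n x 3 matrix of bead centers in the nanoparticle frame
#'   (origin at the particle center), nm.
#' @param grid an [radial_grid()] object.
#' @param bead_diameter bead diameter (nm).
#' @return numeric vector of per-shell occupied volumes (nm^3), length
#'   `grid$n_layers`; the sum equals the total bead volume.
#' @export
bin_shell_volumes <- function(positions, grid, bead_diameter = 0.6) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) return(numeric(grid$n_layers))
  r <- sqrt(rowSums(positions^2))
  idx <- shell_index(grid, r)
  tabulate(idx, nbins = grid$n_layers) * bead_volume(bead_diameter)
}

#' Distance of a conformation's center of mass from the particle center
#'
#' All beads carry equal mass.
#'
#' @param positions n x 3 matrix of bead centers (nanoparticle frame, nm).
#' @return scalar radius (nm).
#' @export
com_radius <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("empty conformation")
  sqrt(sum(colMeans(positions)^2))
}

#' Uniform random rotation matrices
#'
#' Uniform over SO(3) via normalized quaternions.
#'
#' @param n number of rotations.
#' @return list of 3 x 3 rotation matrices.
#' @keywords internal
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  })
}

#' Low-level constructor for a species ensemble
#'
#' Builds a surface-species ensemble directly from a per-shell volume matrix.
#' Used internally by [assemble_conformers()] and exported so that small
#' synthetic systems (e.g. for solver validation) can be constructed in code.
#'
#' @param V numeric matrix, n_conformations x n_layers, of per-shell occupied
#'   volumes (nm^3).
#' @param com numeric vector of center-of-mass radii (nm), one per
#'   conformation.
#' @param species species tag ("A", "Aa", "Aaa", ...).
#' @param n_antigens antigens carried by the species (0, 1 or 2).
#' @param molecular_volume total molecular volume (nm^3).
#' @param grid the shared [radial_grid()].
#' @param acceptance fraction of attempted conformations accepted.
#' @param log_prior per-conformation log prior weights (importance weights
#'   of the sampling scheme); zeros (uniform) by default.
#' @return an object of class `acnp_ensemble`.
#' @export
species_ensemble <- function(V, com, species, n_antigens, molecular_volume,
                             grid, acceptance = NA_real_,
                             log_prior = NULL) {
  V <- as.matrix(V)
  stopifnot(nrow(V) >= 1, ncol(V) == grid$n_layers,
            length(com) == nrow(V), all(V >= 0),
            n_antigens %in% 0:2, molecular_volume >= 0)
  if (is.null(log_prior)) log_prior <- numeric(nrow(V))
  stopifnot(length(log_prior) == nrow(V), all(is.finite(log_prior)))
  structure(
    list(
      species = species, V = unname(V), com = as.numeric(com),
      n_antigens = as.integer(n_antigens),
      molecular_volume = molecular_volume,
      grid = grid, acceptance = acceptance, n_conf = nrow(V),
      log_prior = as.numeric(log_prior)
    ),
    class = "acnp_ensemble"
  )
}

#' @export
print.acnp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<acnp_ensemble> '%s': %d conformations, %d antigen(s), V_mol = %.4g nm^3, acceptance %.3f\n",
    x$species, x$n_conf, x$n_antigens, x$molecular_volume, x$acceptance
  ))
  invisible(x)
}

#' Assemble the surface-tethered conformational ensemble of a species
#'
#' For every spacer conformation and every sampled uniform random rigid
#' rotation, the antibody (with `n_antigens` antigens attached in the bound
#' pose) is joined to the free end of the spacer: the anchor bead is placed
#' one bond length from the last spacer bead along a uniformly random
#' direction (a ball joint) and the rigid body is rotated uniformly about
#' it. Without a spacer the ball joint connects the anchor bead directly to
#' the attachment point on the particle surface. Conformations with any
#' bead center closer than one bead radius to the particle surface are
#' rejected; if fewer than `min_accept` conformations survive, further
#' orientation batches are drawn (up to `max_batches`). Surviving
#' conformations are reduced to per-shell occupied volumes.
#'
#' @param spacers an [spacer_conformations()] set (may be the 0-monomer set).
#' @param antibody an `acnp_bead_model`.
#' @param antigen an `acnp_bead_model` or NULL if `n_antigens = 0`.
#' @param n_antigens 0, 1 or 2 antigens bound at the Fab tips.
#' @param n_orientations random rigid orientations per spacer conformation
#'   per batch.
#' @param grid an [radial_grid()]; its `r_np` sets the particle radius.
#' @param seed integer seed (deterministic output).
#' @param min_accept keep drawing orientation batches until this many
#'   conformations are accepted (or `max_batches` is exhausted).
#' @param max_batches cap on orientation batches.
#' @return an `acnp_ensemble` for the species tag "A", "Aa" or "Aaa".
#' @export
assemble_conformers <- function(spacers, antibody, antigen = NULL,
                                n_antigens = 0, n_orientations = 20,
                                grid, seed = 1, min_accept = 50,
                                max_batches = 40) {
  stopifnot(inherits(spacers, "acnp_spacer_set"),
            inherits(antibody, "acnp_bead_model"),
            n_antigens %in% 0:2, n_orientations >= 1)
  if (n_antigens > 0 && is.null(antigen)) {
    stop("antigen model required when n_antigens > 0")
  }
  complex_model <- bind_antigen(antibody, antigen, n_antigens)
  local_pos <- sweep(
    complex_model$positions, 2,
    complex_model$positions[complex_model$anchor, ], "-"
  )
  d <- complex_model$bead_diameter
  bond <- if (spacers$n_monomers > 0) spacers$bond_length else d
  r_min <- grid$r_np + d / 2 - 1e-9
  graft <- c(0, 0, grid$r_np + d / 2)
  surface_point <- c(0, 0, grid$r_np)
  species <- c("A", "Aa", "Aaa")[n_antigens + 1]
  n_sp <- length(spacers$chains)
  withr::with_seed(seed, {
    sp_np <- lapply(spacers$chains, function(sp) {
      if (nrow(sp)) sweep(sp, 2, graft, "+") else sp
    })
    sp_clear <- vapply(sp_np, function(p) {
      !nrow(p) || all(sqrt(rowSums(p^2)) >= r_min)
    }, logical(1))
    free_end <- lapply(sp_np, function(p) {
      if (nrow(p)) p[nrow(p), ] else surface_point
    })
    profs <- list()
    coms <- numeric(0)
    lps <- numeric(0)
    n_tot <- 0L
    for (batch in seq_len(max_batches)) {
      n_cand <- n_sp * n_orientations
      rots <- random_rotations(n_cand)
      joints <- matrix(stats::rnorm(3 * n_cand), n_cand, 3)
      joints <- joints / sqrt(rowSums(joints^2))
      for (s in seq_len(n_sp)) {
        if (!sp_clear[s]) {
          n_tot <- n_tot + n_orientations
          next
        }
        for (o in seq_len(n_orientations)) {
          k <- (s - 1L) * n_orientations + o
          n_tot <- n_tot + 1L
          anchor_pos <- free_end[[s]] + bond * joints[k, ]
          body <- local_pos %*% t(rots[[k]])
          body <- sweep(body, 2, anchor_pos, "+")
          all_pos <- rbind(sp_np[[s]], body)
          if (any(sqrt(rowSums(all_pos^2)) < r_min)) next
          profs[[length(profs) + 1L]] <- bin_shell_volumes(all_pos, grid, d)
          coms[length(coms) + 1L] <- com_radius(all_pos)
          lps[length(lps) + 1L] <- spacers$log_w[s]
        }
      }
      if (length(profs) >= min_accept) break
    }
    if (length(profs) == 0) {
      stop(sprintf(
        paste0("no conformation of species '%s' clears the nanoparticle ",
               "(r_np = %g nm, spacer = %d monomers); the geometry leaves no ",
               "room for the tethered molecule"),
        species, grid$r_np, spacers$n_monomers
      ))
    }
    V <- do.call(rbind, profs)
    spacer_vol <- spacers$n_monomers * bead_volume(spacers$bead_diameter)
    species_ensemble(
      V, coms,
      species = species, n_antigens = n_antigens,
      molecular_volume = spacer_vol + model_volume(complex_model),
      grid = grid, acceptance = length(profs) / n_tot,
      log_prior = lps
    )
  })
}

#' Write and read a conformer-ensemble cache
#'
#' Stores the per-shell volume matrix as TSV together with a JSON sidecar
#' carrying the ensemble's provenance (species, antigen count, molecular
#' volume, grid, acceptance, priors), so expensive ensembles can be reused
#' across runs.
#'
#' @param ensemble an `acnp_ensemble`.
#' @param prefix file path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the two file paths.
#' @export
write_ensemble <- function(ensemble, prefix) {
  stopifnot(inherits(ensemble, "acnp_ensemble"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  tab <- tibble::as_tibble(ensemble$V, .name_repair = ~ paste0("v", seq_along(.x)))
  tab$com <- ensemble$com
  tab$log_prior <- ensemble$log_prior
  readr::write_tsv(tab, tsv)
  jsonlite::write_json(
    list(
      species = ensemble$species, n_antigens = ensemble$n_antigens,
      molecular_volume = ensemble$molecular_volume,
      acceptance = ensemble$acceptance, n_conf = ensemble$n_conf,
      grid = list(r_np = ensemble$grid$r_np, dr = ensemble$grid$dr,
                  n_layers = ensemble$grid$n_layers)
    ),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, js))
}

#' @rdname write_ensemble
#' @param prefix file path prefix used by [write_ensemble()].
#' @export
read_ensemble <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE)
  grid <- radial_grid(meta$grid$r_np, meta$grid$dr,
                      r_max = meta$grid$r_np + meta$grid$n_layers * meta$grid$dr)
  V <- as.matrix(tab[, paste0("v", seq_len(meta$grid$n_layers))])
  species_ensemble(
    V, tab$com, meta$species, meta$n_antigens, meta$molecular_volume,
    grid, acceptance = meta$acceptance, log_prior = tab$log_prior
  )
}
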