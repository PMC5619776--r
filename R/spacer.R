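#' Generate self-avoiding spacer conformations (rotational isomeric states)
#'
#' Conformations of a PEG-like spacer are generated with a rotational
#' isomeric state (RIS) chain model: beads of 0.6 nm diameter (one per
#' ethylene-glycol monomer) connected at fixed bond length, fixed valence
#' angle, and backbone dihedrals drawn from the three RIS states
#' (trans, gauche+, gauche-). Chains start at the origin (the grafting
#' point, which is not itself a bead) with the first bond along +z (the
#' outward surface normal); the second bond has a uniformly random azimuth.
#' Chains with any hard-sphere overlap between beads separated by two or
#' more bonds are rejected and regenerated.
#'
#' @param n_monomers number of spacer beads (>= 0). 0 returns the single
#'   empty chain (the "no spacer" case).
#' @param n_samples number of conformations to generate (>= 1).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param bond_length distance between successive bead centers (nm).
#' @param bead_diameter hard-sphere diameter for self-avoidance (nm).
#' @param bond_angle_deg valence angle between successive bonds (degrees).
#' @param state_weights statistical weights of the (trans, gauche+, gauche-)
#'   states; equal by default.
#' @param stretch_bias vector of trans-bias factors for stratified
#'   importance sampling of the extension tail. The sample is split evenly
#'   across strata; within a stratum the trans state is proposed with its
#'   weight multiplied by the bias factor, and every chain carries the exact
#'   log importance weight of the target RIS statistics relative to its
#'   proposal. The default single stratum of 1 reproduces plain sampling
#'   with zero weights. Biased strata make deeply crowded (strongly
#'   stretched) layers statistically stable at moderate sample sizes.
#' @param self_avoid logical; disable only for ideal-chain validation runs.
#' @param max_attempt_factor sampling stops with an error if more than
#'   `max_attempt_factor * n_samples` chains had to be attempted.
#' @return an object of class `acnp_spacer_set`: list with `chains` (list of
#'   n_monomers x 3 matrices), `n_monomers`, `n_attempted`, `acceptance`, and
#'   the generation parameters.
#' @examples
#' sp <- spacer_conformations(10, 50, seed = 1)
#' sp$acceptance
#' @export
spacer_conformations <- function(n_monomers, n_samples, seed,
                                 bond_length = 0.6, bead_diameter = 0.6,
                                 bond_angle_deg = 109.47,
                                 state_weights = c(1, 1, 1),
                                 stretch_bias = 1,
                                 self_avoid = TRUE,
                                 max_attempt_factor = 200) {
  stopifnot(n_monomers >= 0, n_samples >= 1, length(state_weights) == 3,
            all(state_weights >= 0), sum(state_weights) > 0,
            length(stretch_bias) >= 1, all(stretch_bias > 0))
  n_monomers <- as.integer(n_monomers)
  n_samples <- as.integer(n_samples)
  meta <- list(
    n_monomers = n_monomers, bond_length = bond_length,
    bead_diameter = bead_diameter, bond_angle_deg = bond_angle_deg,
    state_weights = state_weights / sum(state_weights),
    stretch_bias = stretch_bias,
    self_avoid = self_avoid, seed = seed
  )
  if (n_monomers == 0) {
    return(structure(
      c(list(chains = rep(list(matrix(numeric(0), 0, 3)), n_samples),
             log_w = numeric(n_samples),
             n_attempted = n_samples, acceptance = 1), meta),
      class = "acnp_spacer_set"
    ))
  }
  n_strata <- length(stretch_bias)
  per <- diff(round(seq(0, n_samples, length.out = n_strata + 1)))
  withr::with_seed(seed, {
    chains <- list()
    log_w <- numeric(0)
    attempted <- 0L
    for (str_i in seq_len(n_strata)) {
      target_w <- meta$state_weights
      prop_w <- target_w * c(stretch_bias[str_i], 1, 1)
      prop_w <- prop_w / sum(prop_w)
      lw_state <- log(target_w) - log(prop_w)
      need <- per[str_i]
      while (need > 0) {
        batch <- .ris_chain_batch(need, n_monomers, bond_length,
                                  bond_angle_deg, prop_w)
        attempted <- attempted + need
        if (self_avoid && n_monomers >= 3) {
          ok <- vapply(batch$chains, .chain_self_clear, logical(1),
                       cutoff = bead_diameter * (1 - 1e-7))
        } else {
          ok <- rep(TRUE, length(batch$chains))
        }
        if (any(ok)) {
          take <- min(sum(ok), need)
          sel <- which(ok)[seq_len(take)]
          chains <- c(chains, batch$chains[sel])
          if (is.null(batch$states)) {
            log_w <- c(log_w, numeric(take))
          } else {
            log_w <- c(log_w, colSums(
              matrix(lw_state[batch$states[, sel, drop = FALSE]],
                     ncol = take)
            ))
          }
          need <- need - take
        }
        if (attempted > max_attempt_factor * n_samples) {
          stop(sprintf(
            paste0("spacer sampling failed: %d of %d chains accepted after ",
                   "%d attempts (dense self-avoidance rejection); shorten ",
                   "the chain or relax the hard-sphere cutoff"),
            n_samples - need, n_samples, attempted
          ))
        }
      }
    }
    structure(
      c(list(chains = chains, log_w = log_w, n_attempted = attempted,
             acceptance = n_samples / attempted), meta),
      class = "acnp_spacer_set"
    )
  })
}

#' @export
print.acnp_spacer_set <- function(x, ...) {
  cat(sprintf(
    "<acnp_spacer_set> %d chains of %d monomers (acceptance %.3f)\n",
    length(x$chains), x$n_monomers, x$acceptance
  ))
  invisible(x)
}

# Vectorized-over-samples RIS chain growth. Returns `chains` (list of n x 3
# matrices) and `states` (dihedral-state index matrix, steps x chains, NULL
# when no dihedral is drawn). The grafting point (origin) is not a bead;
# bead k sits at the end of bond k.
.ris_chain_batch <- function(n_chains, n_beads, l, bond_angle_deg, w) {
  a <- pi - bond_angle_deg * pi / 180 # deflection from the previous bond
  sa <- sin(a); ca <- cos(a)
  pos <- array(0, dim = c(n_chains, n_beads, 3))
  states <- if (n_beads >= 3) {
    matrix(0L, n_beads - 2, n_chains)
  } else {
    NULL
  }
  u_cur <- matrix(rep(c(0, 0, 1), each = n_chains), n_chains, 3)
  pos[, 1, ] <- l * u_cur
  if (n_beads >= 2) {
    psi <- stats::runif(n_chains, 0, 2 * pi)
    u_prev <- u_cur
    u_cur <- cbind(sa * cos(psi), sa * sin(psi), rep(ca, n_chains))
    pos[, 2, ] <- pos[, 1, ] + l * u_cur
    if (n_beads >= 3) {
      phi_states <- c(pi, pi / 3, -pi / 3) # trans, gauche+, gauche-
      for (k in 3:n_beads) {
        st <- sample.int(3, n_chains, replace = TRUE, prob = w)
        states[k - 2, ] <- st
        phi <- phi_states[st]
        t_ <- u_cur
        n_ <- .row_cross(u_prev, u_cur)
        n_ <- n_ / sqrt(rowSums(n_^2))
        m_ <- .row_cross(n_, t_)
        u_new <- t_ * ca + (m_ * cos(phi) + n_ * sin(phi)) * sa
        u_new <- u_new / sqrt(rowSums(u_new^2))
        pos[, k, ] <- pos[, k - 1, ] + l * u_new
        u_prev <- u_cur
        u_cur <- u_new
      }
    }
  }
  list(
    chains = lapply(seq_len(n_chains), function(i) {
      matrix(pos[i, , ], n_beads, 3)
    }),
    states = states
  )
}

.row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# TRUE if no two beads separated by >= 2 bonds (grafting origin included as
# position 0) come closer than `cutoff`.
.chain_self_clear <- function(chain, cutoff) {
  pts <- rbind(c(0, 0, 0), chain)
  d <- as.matrix(stats::dist(pts))
  min(d[col(d) - row(d) >= 2L]) >= cutoff
}

#' Mean squared end-to-end distance of a spacer set
#'
#' @param spacers an `acnp_spacer_set`.
#' @return list with `msee` (nm^2) and its standard error.
#' @export
spacer_msee <- function(spacers) {
  if (spacers$n_monomers == 0) return(list(msee = 0, se = 0))
  e2 <- vapply(
    spacers$chains,
    function(ch) sum(ch[nrow(ch), ]^2),
    numeric(1)
  )
  w <- exp(spacers$log_w - max(spacers$log_w))
  w <- w / sum(w)
  m <- sum(w * e2)
  v <- sum(w * (e2 - m)^2) * sum(w^2) # weighted variance of the mean
  list(msee = m, se = sqrt(v))
}
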