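# Shared fixtures: inline PDB text and an independent chain-statistics oracle.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z) {
  # strict fixed-width ATOM record (atom name in columns 13-16)
  name4 <- sprintf("%-3s", name)
  name4 <- if (nchar(name) < 4) paste0(" ", name4) else name
  sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name4, resname, chain, resno, x, y, z, 1, 0,
    substr(name, 1, 1)
  )
}

# three glycines with CA at (0,0,0), (0,0,3.8), (0,0,7.6) Angstrom
pdb_three_residues <- function() {
  c(
    pdb_line(1, "N", "GLY", "A", 1, -1.0, 0.0, 0.0),
    pdb_line(2, "CA", "GLY", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(3, "C", "GLY", "A", 1, 1.0, 0.5, 0.0),
    pdb_line(4, "N", "GLY", "A", 2, -1.0, 0.0, 3.8),
    pdb_line(5, "CA", "GLY", "A", 2, 0.0, 0.0, 3.8),
    pdb_line(6, "C", "GLY", "A", 2, 1.0, 0.5, 3.8),
    pdb_line(7, "N", "GLY", "A", 3, -1.0, 0.0, 7.6),
    pdb_line(8, "CA", "GLY", "A", 3, 0.0, 0.0, 7.6),
    pdb_line(9, "C", "GLY", "A", 3, 1.0, 0.5, 7.6),
    "END"
  )
}

# as above but residue 2 has no CA record
pdb_missing_ca <- function() {
  lines <- pdb_three_residues()
  lines[!grepl("CA  GLY A   2", lines, fixed = TRUE)]
}

# Independent rotational-isomeric-state chain sampler used as an oracle for
# the package's spacer generator. Built atom-by-atom with explicit axis-angle
# rotations (Rodrigues formula), a numerical path distinct from the
# generator's cross-product frame propagation.
oracle_ris_chain <- function(n_beads, l = 0.6, bond_angle_deg = 109.47,
                             weights = c(1, 1, 1)) {
  rotate_about <- function(v, axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    v * cos(ang) + pracma::cross(axis, v) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
  }
  defl <- pi - bond_angle_deg * pi / 180
  phis <- c(pi, pi / 3, -pi / 3)
  pos <- matrix(0, n_beads, 3)
  b_prev <- c(1, 0, 0) # virtual previous bond for the first dihedral frame
  b_cur <- c(0, 0, 1)
  pos[1, ] <- l * b_cur
  if (n_beads >= 2) {
    for (k in 2:n_beads) {
      if (k == 2) {
        phi <- stats::runif(1, 0, 2 * pi)
      } else {
        phi <- phis[sample.int(3, 1, prob = weights)]
      }
      # deflect away from b_cur within the plane set by the dihedral angle
      perp <- pracma::cross(b_prev, b_cur)
      if (sum(perp^2) < 1e-20) perp <- pracma::cross(c(0, 1, 0), b_cur)
      perp <- perp / sqrt(sum(perp^2))
      b_new <- rotate_about(b_cur, perp, defl)
      b_new <- rotate_about(b_new, b_cur, phi)
      pos[k, ] <- pos[k - 1, ] + l * b_new
      b_prev <- b_cur
      b_cur <- b_new
    }
  }
  pos
}

oracle_msee <- function(n_chains, n_beads, seed, ...) {
  args <- list(...)
  withr::with_seed(seed, {
    e2 <- vapply(seq_len(n_chains), function(i) {
      p <- do.call(oracle_ris_chain, c(list(n_beads), args))
      sum(p[n_beads, ]^2)
    }, numeric(1))
    list(msee = mean(e2), se = stats::sd(e2) / sqrt(n_chains))
  })
}

# small shared surface system (fast): Y-stick antibody on a small particle
small_test_system <- function(n_spacer = 40, n_orient = 5, r_np = 20,
                              spacer = 10, seed = 11) {
  grid <- radial_grid(r_np, dr = 1, r_max = r_np + 25)
  ab <- toy_antibody(4)
  ag <- toy_antigen()
  sp <- spacer_conformations(spacer, n_spacer, seed = seed)
  ens <- lapply(0:2, function(na) {
    assemble_conformers(sp, ab, ag, n_antigens = na, n_orientations = n_orient,
                        grid = grid, seed = seed + na)
  })
  names(ens) <- c("A", "Aa", "Aaa")
  list(grid = grid, ensembles = ens, antibody = ab, antigen = ag)
}
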