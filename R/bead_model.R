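#' Coarse-grained bead model of a molecule
#'
#' A rigid molecule represented as one bead per residue (or per monomer).
#' Positions are nm. `anchor` is the bead bonded to the spacer or surface;
#' `sites` are beads that act as antigen-binding sites (Fab tips), with
#' `site_dirs` the outward unit vectors along which a bound antigen extends.
#'
#' @param positions numeric matrix (n x 3) of bead centers in nm.
#' @param bead_diameter bead diameter in nm (default 0.6).
#' @param anchor index of the anchor bead.
#' @param sites integer vector of binding-site bead indices (possibly empty).
#' @param site_dirs matrix (length(sites) x 3) of unit vectors, or NULL.
#' @param label species tag.
#' @return an object of class `acnp_bead_model`.
#' @export
bead_model <- function(positions, bead_diameter = 0.6, anchor = 1L,
                       sites = integer(0), site_dirs = NULL, label = "model") {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1 || ncol(positions) != 3) {
    stop("positions must be a non-empty n x 3 matrix")
  }
  stopifnot(bead_diameter > 0)
  anchor <- as.integer(anchor)
  if (anchor < 1 || anchor > nrow(positions)) stop("anchor_index out of range")
  sites <- as.integer(sites)
  if (length(sites) && (any(sites < 1) || any(sites > nrow(positions)))) {
    stop("binding-site index out of range")
  }
  if (!is.null(site_dirs)) {
    site_dirs <- as.matrix(site_dirs)
    stopifnot(nrow(site_dirs) == length(sites), ncol(site_dirs) == 3)
    site_dirs <- site_dirs / sqrt(rowSums(site_dirs^2))
  }
  structure(
    list(
      positions = unname(positions), bead_diameter = bead_diameter,
      anchor = anchor, sites = sites, site_dirs = site_dirs, label = label
    ),
    class = "acnp_bead_model"
  )
}

#' @export
print.acnp_bead_model <- function(x, ...) {
  cat(sprintf(
    "<acnp_bead_model> '%s': %d beads (d = %g nm, V = %.4g nm^3), %d binding site(s)\n",
    x$label, nrow(x$positions), x$bead_diameter,
    model_volume(x), length(x$sites)
  ))
  invisible(x)
}

#' Total bead volume of a model (nm^3)
#' @param model an `acnp_bead_model`.
#' @export
model_volume <- function(model) {
  nrow(model$positions) * bead_volume(model$bead_diameter)
}

#' Extract an alpha-carbon bead model from a PDB structure
#'
#' Each amino acid becomes a single bead of 0.6 nm diameter centered at the
#' alpha carbon of the residue. Residues without a CA record are skipped and
#' counted in a warning. Coordinates are converted from Angstrom to nm.
#'
#' @param pdb path to a PDB file, or a character vector of PDB text lines.
#' @param chains chain identifiers to keep; NULL keeps all chains.
#' @param anchor anchor bead index of the resulting model (default: last bead,
#'   i.e. the C-terminal residue of the selection).
#' @param label species tag for the model.
#' @return an `acnp_bead_model` with attribute `skipped` giving the number of
#'   residues lacking a CA atom.
#' @export
read_alpha_carbon_beads <- function(pdb, chains = NULL, anchor = NULL,
                                    label = "pdb") {
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL)", pdb[1])) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
    on.exit(unlink(tf))
    pdb <- tf
  }
  parsed <- tryCatch(
    bio3d::read.pdb(pdb, verbose = FALSE),
    error = function(e) stop("malformed PDB input: ", conditionMessage(e))
  )
  atoms <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) {
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no residues selected")
  res_id <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  is_ca <- atoms$elety == "CA"
  n_res <- length(unique(res_id))
  ca <- atoms[is_ca, , drop = FALSE]
  # one bead per residue: keep first CA per residue (altloc duplicates)
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
           drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in the selected chains")
  skipped <- n_res - nrow(ca)
  if (skipped > 0) {
    warning(sprintf("%d residue(s) lacking a CA record were skipped", skipped))
  }
  pos <- cbind(ca$x, ca$y, ca$z) / 10 # Angstrom -> nm
  if (is.null(anchor)) anchor <- nrow(pos)
  out <- bead_model(pos, bead_diameter = 0.6, anchor = anchor, label = label)
  attr(out, "skipped") <- skipped
  out
}

#' Deterministic Y-shaped toy antibody
#'
#' A download-free stand-in for a real immunoglobulin structure: a rigid
#' Y-shape with a stem of `arm_length` beads along +z and two arms of
#' `arm_length` beads each, splayed at +/-55 degrees from the stem axis. The
#' ends of the two arms are the antigen-binding (Fab tip) sites; the base of
#' the stem is the anchor (Fc end). Beads are tangent at 0.6 nm spacing.
#' The output depends only on `arm_length`.
#'
#' @param arm_length beads per arm/stem (>= 1); total beads = 3 * arm_length.
#' @param seed accepted for interface uniformity; the construction is
#'   deterministic and ignores it.
#' @return an `acnp_bead_model` with two binding sites.
#' @examples
#' ab <- toy_antibody(5) # 15 beads
#' model_volume(ab)      # 15 * (pi/6) * 0.6^3
#' @export
toy_antibody <- function(arm_length = 8, seed = NULL) {
  if (!is.numeric(arm_length) || arm_length < 1) {
    stop("arm_length must be >= 1")
  }
  L <- as.integer(arm_length)
  d <- 0.6
  stem <- cbind(0, 0, d * (seq_len(L) - 1))
  top <- stem[L, ]
  ang <- 55 * pi / 180
  dir_r <- c(sin(ang), 0, cos(ang))
  dir_l <- c(-sin(ang), 0, cos(ang))
  arm_r <- sweep(outer(d * seq_len(L), dir_r), 2, top, "+")
  arm_l <- sweep(outer(d * seq_len(L), dir_l), 2, top, "+")
  pos <- rbind(stem, arm_r, arm_l)
  bead_model(
    pos,
    bead_diameter = d, anchor = 1L,
    sites = c(2L * L, 3L * L),
    site_dirs = rbind(dir_r, dir_l),
    label = "toy_antibody"
  )
}

#' Deterministic compact toy antigen
#'
#' A 7-bead close-packed cluster (central bead plus its six axial neighbors at
#' 0.6 nm), used as a download-free stand-in for a globular antigen. The
#' central bead is the attachment point to a Fab tip.
#'
#' @return an `acnp_bead_model` with anchor at the central bead.
#' @export
toy_antigen <- function() {
  d <- 0.6
  pos <- rbind(
    c(0, 0, 0),
    d * diag(3), -d * diag(3)
  )
  bead_model(pos, bead_diameter = d, anchor = 1L, label = "toy_antigen")
}

#' Attach antigens to an antibody in the bound pose
#'
#' Builds the rigid antibody-antigen complex in the antibody's local frame.
#' Each antigen copy is translated so that its anchor bead sits one bead
#' diameter beyond the Fab-tip site along the site direction (a straight
#' extension of the arm). For models built from a crystallographic complex,
#' build the complex directly with [read_alpha_carbon_beads()] on both chains
#' instead.
#'
#' @param antibody an `acnp_bead_model` with at least `n_antigens` sites.
#' @param antigen an `acnp_bead_model`.
#' @param n_antigens number of antigen copies to attach (0, 1 or 2).
#' @return an `acnp_bead_model` of the complex, label suffixed with the
#'   number of bound antigens.
#' @export
bind_antigen <- function(antibody, antigen, n_antigens) {
  stopifnot(n_antigens %in% 0:2)
  if (n_antigens > length(antibody$sites)) {
    stop("antibody model has fewer binding sites than requested antigens")
  }
  if (n_antigens == 0) return(antibody)
  if (is.null(antibody$site_dirs)) {
    stop("antibody model carries no site directions for the bound pose")
  }
  pos <- antibody$positions
  for (k in seq_len(n_antigens)) {
    site_pos <- antibody$positions[antibody$sites[k], ]
    offset <- site_pos + antibody$bead_diameter * antibody$site_dirs[k, ]
    ag <- sweep(antigen$positions, 2,
                antigen$positions[antigen$anchor, ] - offset, "-")
    pos <- rbind(pos, ag)
  }
  bead_model(
    pos,
    bead_diameter = antibody$bead_diameter, anchor = antibody$anchor,
    sites = antibody$sites, site_dirs = antibody$site_dirs,
    label = paste0(antibody$label, "+", n_antigens, "ag")
  )
}

#' Deterministic compact bead globule
#'
#' A roughly spherical cluster of `n_beads` beads on a simple-cubic lattice
#' at bead-diameter spacing, filled from the center outward. Used to build
#' stand-ins with realistic molecular volumes (one bead per residue): e.g.
#' ~480 beads approximates a gp120-sized antigen, ~440 beads one
#' immunoglobulin lobe. The anchor is the lowest (-z) bead, so a globule
#' attached via [bind_antigen()] extends outward from the binding site.
#'
#' @param n_beads number of beads (>= 1).
#' @param label species tag.
#' @return an `acnp_bead_model`.
#' @export
toy_globule <- function(n_beads = 480, label = "globule") {
  stopifnot(n_beads >= 1)
  d <- 0.6
  k <- ceiling((3 * n_beads / (4 * pi))^(1 / 3)) + 2
  ax <- (-k):k
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax)) * d
  ord <- order(rowSums(pts^2), pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord[seq_len(n_beads)], , drop = FALSE]
  anchor <- which.min(pts[, 3] * 1e6 + rowSums(pts[, 1:2, drop = FALSE]^2))
  bead_model(pts, bead_diameter = d, anchor = anchor, label = label)
}

#' Deterministic three-lobe immunoglobulin stand-in
#'
#' A compact IgG-shaped rigid model: three globular lobes (Fc and two Fabs)
#' of `lobe_beads` beads each, arranged in a Y with the Fab lobes splayed at
#' +/-55 degrees. With the default 440 beads per lobe the model has ~1320
#' beads (one per residue of an IgG) and a ~12 nm span, reproducing the
#' molecular volume that drives surface crowding. The anchor is the bottom
#' of the Fc lobe; the binding sites are the outermost Fab beads along the
#' arm directions.
#'
#' @param lobe_beads beads per lobe.
#' @return an `acnp_bead_model` with two binding sites.
#' @export
toy_igg <- function(lobe_beads = 440) {
  d <- 0.6
  lobe <- toy_globule(lobe_beads)$positions
  r_lobe <- max(sqrt(rowSums(lobe^2)))
  ang <- 55 * pi / 180
  dir_r <- c(sin(ang), 0, cos(ang))
  dir_l <- c(-sin(ang), 0, cos(ang))
  c_fc <- c(0, 0, r_lobe)
  sep <- 2 * r_lobe + d
  c_r <- c_fc + sep * dir_r
  c_l <- c_fc + sep * dir_l
  pos <- rbind(
    sweep(lobe, 2, c_fc, "+"),
    sweep(lobe, 2, c_r, "+"),
    sweep(lobe, 2, c_l, "+")
  )
  n <- nrow(lobe)
  tip_r <- n + which.max((sweep(lobe, 2, c_r, "+") %*% dir_r))
  tip_l <- 2 * n + which.max((sweep(lobe, 2, c_l, "+") %*% dir_l))
  anchor <- which.min(pos[seq_len(n), 3])
  bead_model(
    pos,
    bead_diameter = d, anchor = anchor,
    sites = c(tip_r, tip_l), site_dirs = rbind(dir_r, dir_l),
    label = "toy_igg"
  )
}
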