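#' Bulk solution state for the surface calculation
#'
#' Holds the bulk (reservoir) concentrations of the exchangeable species and
#' the binding constants that group all attractive interactions. For the
#' covalent scheme only the free antigen concentration matters; for the
#' streptavidin scheme supply the pre-equilibrated concentrations from
#' [solve_bulk_equilibrium()].
#'
#' @param c_antigen free antigen concentration (M).
#' @param c_antibody free (biotinylated) antibody concentration (M).
#' @param c_complex1,c_complex2 concentrations of the 1- and 2-antigen
#'   complexes (M).
#' @param kd antibody-antigen per-site dissociation constant (M).
#' @param avidity_ratio ratio of the second-site to first-site dissociation
#'   constant (Kd2/Kd1, dimensionless, >= 1 for negative cooperativity). May
#'   be `Inf` to switch the second ligation off.
#' @param kd_biotin streptavidin-biotin dissociation constant (M).
#' @param g_stat statistical factor mode: 2 (default) applies the two-
#'   equivalent-Fab factors (first ligation x2, second ligation x1/2);
#'   1 applies no statistical factors.
#' @param v_antigen,v_antibody molecular volumes of free antigen and
#'   antibody (nm^3), used for the (dilute) solution excluded volume.
#' @param v_water water molecular volume (nm^3).
#' @return an object of class `acnp_bulk`.
#' @export
bulk_solution <- function(c_antigen = 0, c_antibody = 0, c_complex1 = 0,
                          c_complex2 = 0, kd = 1e-9, avidity_ratio = 100,
                          kd_biotin = 1e-14, g_stat = 2,
                          v_antigen = model_volume(toy_antigen()),
                          v_antibody = model_volume(toy_antibody()),
                          v_water = .WATER_VOLUME) {
  stopifnot(c_antigen >= 0, c_antibody >= 0, c_complex1 >= 0,
            c_complex2 >= 0, kd > 0, avidity_ratio > 0, kd_biotin > 0,
            g_stat %in% c(1, 2), v_antigen >= 0, v_antibody >= 0,
            v_water > 0)
  conc <- c(a = c_antigen, A = c_antibody, Aa = c_complex1, Aaa = c_complex2)
  vols <- c(
    a = v_antigen, A = v_antibody,
    Aa = v_antibody + v_antigen, Aaa = v_antibody + 2 * v_antigen
  )
  rho <- molar_to_density(conc)
  phi <- rho * vols
  if (sum(phi) >= 1) stop("solution species volume fractions exceed unity")
  structure(
    list(
      conc = conc, vols = vols, rho = rho, phi = phi,
      kd = kd, avidity_ratio = avidity_ratio, kd_biotin = kd_biotin,
      g_stat = g_stat, v_water = v_water,
      rho_water = (1 - sum(phi)) / v_water
    ),
    class = "acnp_bulk"
  )
}

#' @export
print.acnp_bulk <- function(x, ...) {
  cat("<acnp_bulk>\n")
  cat(sprintf("  c(a)   = %.4g M    c(A)   = %.4g M\n", x$conc["a"], x$conc["A"]))
  cat(sprintf("  c(Aa)  = %.4g M    c(Aaa) = %.4g M\n", x$conc["Aa"], x$conc["Aaa"]))
  cat(sprintf("  Kd = %.3g M, avidity ratio = %g, Kd(biotin) = %.3g M\n",
              x$kd, x$avidity_ratio, x$kd_biotin))
  invisible(x)
}

#' Homogeneous antibody-antigen solution equilibrium
#'
#' Solves the chemical equilibrium preceding the streptavidin-scheme surface
#' calculation: given total antibody and antigen concentrations, the per-site
#' dissociation constant and the avidity ratio, find the equilibrium
#' concentrations of free antigen (a), free antibody (A) and the one- and
#' two-antigen complexes (Aa, Aaa). With the default `g_stat = 2` the mass
#' action laws are `c_Aa = 2 c_A c_a / Kd` and
#' `c_Aaa = c_Aa c_a / (2 Kd rho_av)` (two equivalent, independent Fab sites
#' with the second ligation weakened by the avidity ratio).
#'
#' The solve is a safeguarded 1-D root-find on the free antigen
#' concentration, which brackets monotonically between 0 and the total.
#'
#' @param a_total total antigen concentration (M).
#' @param ab_total total antibody concentration (M).
#' @param kd per-site dissociation constant (M).
#' @param avidity_ratio second-site Kd ratio (dimensionless, may be Inf).
#' @param g_stat statistical factor mode (2 or 1), see [bulk_solution()].
#' @return a tibble with one row: `c_a`, `c_A`, `c_Aa`, `c_Aaa` (M), class
#'   `acnp_mixture`.
#' @examples
#' solve_bulk_equilibrium(200e-9, 100e-9, kd = 1e-9)
#' @export
solve_bulk_equilibrium <- function(a_total, ab_total, kd,
                                   avidity_ratio = 100, g_stat = 2) {
  stopifnot(a_total >= 0, ab_total >= 0, kd > 0, avidity_ratio > 0,
            g_stat %in% c(1, 2))
  spec <- list(a_total = a_total, ab_total = ab_total, kd = kd,
               avidity_ratio = avidity_ratio, g_stat = g_stat)
  split_species <- function(x) {
    # complex ratios at free antigen concentration x
    r1 <- g_stat * x / kd
    r2 <- if (is.finite(avidity_ratio)) x / (g_stat * kd * avidity_ratio) else 0
    c_A <- ab_total / (1 + r1 + r1 * r2)
    c_Aa <- c_A * r1
    c_Aaa <- c_Aa * r2
    tibble::tibble(c_a = x, c_A = c_A, c_Aa = c_Aa, c_Aaa = c_Aaa)
  }
  if (a_total == 0 || ab_total == 0) {
    out <- split_species(a_total)
  } else {
    antigen_excess <- function(x) {
      s <- split_species(x)
      (x + s$c_Aa + 2 * s$c_Aaa) - a_total
    }
    # monotone increasing in x; root brackets in [0, a_total]
    root <- stats::uniroot(
      antigen_excess,
      lower = 0, upper = a_total,
      tol = .Machine$double.eps * max(a_total, 1e-30), maxiter = 2000
    )$root
    # Newton polish: when complex formation is steep the Brent tolerance on x
    # alone does not guarantee a 1e-10 relative mass balance
    for (it in 1:4) {
      fx <- antigen_excess(root)
      if (abs(fx) <= 1e-14 * a_total) break
      h <- max(root, a_total * 1e-9) * 1e-7
      dfx <- (antigen_excess(root + h) - antigen_excess(root - h)) / (2 * h)
      step <- fx / dfx
      root <- min(max(root - step, 0), a_total)
    }
    out <- split_species(root)
  }
  attr(out, "spec") <- spec
  class(out) <- c("acnp_mixture", class(out))
  out
}

#' Mass-balance residuals of a mixture equilibrium
#'
#' @param eq result of [solve_bulk_equilibrium()].
#' @param spec optional list with `a_total` and `ab_total`; defaults to the
#'   spec stored on `eq`.
#' @return named numeric vector: relative antibody and antigen balance
#'   residuals (absolute residual when the corresponding total is zero).
#' @export
mass_balance <- function(eq, spec = attr(eq, "spec")) {
  stopifnot(!is.null(spec))
  ab_res <- eq$c_A + eq$c_Aa + eq$c_Aaa - spec$ab_total
  ag_res <- eq$c_a + eq$c_Aa + 2 * eq$c_Aaa - spec$a_total
  c(
    antibody = ab_res / max(spec$ab_total, .Machine$double.xmin),
    antigen = ag_res / max(spec$a_total, .Machine$double.xmin)
  )
}
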