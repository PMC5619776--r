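#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot binding curves
#'
#' Captured antigen against antibody (or streptavidin-site) surface
#' coverage, one line per dissociation constant, faceted over radius and
#' spacer length when those vary.
#'
#' @param object an `acnp_curves` tibble from [run_sweep()].
#' @param y observable column to plot (default "captured").
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.acnp_curves <- function(object, y = "captured", ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$coverage, y = .data[[y]],
      colour = factor(.data$kd), group = interaction(
        .data$kd, .data$c_antigen, .data$c_antibody
      )
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(paste("surface coverage ", sigma, " (nm"^-2, ")")),
      y = y, colour = "Kd (M)"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(object$r_np)) > 1 || length(unique(object$spacer)) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$spacer), cols = ggplot2::vars(.data$r_np),
      labeller = ggplot2::label_both
    )
  }
  p
}

#' Plot the surface-species breakdown of a binding curve
#'
#' Numbers of unbound antibodies, one- and two-antigen complexes (and total
#' bound antibodies) on the surface against coverage.
#'
#' @param curve one curve (single condition) from [run_sweep()].
#' @return a ggplot object.
#' @export
plot_species_breakdown <- function(curve) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(
      curve,
      `0 ant.` = .data$n_sites * .data$f_A,
      `1 ant.` = .data$n_sites * .data$f_Aa,
      `2 ant.` = .data$n_sites * .data$f_Aaa,
      total = .data$bound_antibodies
    ),
    cols = c("0 ant.", "1 ant.", "2 ant.", "total"),
    names_to = "species", values_to = "count"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$coverage, .data$count, colour = .data$species,
                 linetype = .data$species == "total")
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(
      x = expression(paste("surface coverage ", sigma, " (nm"^-2, ")")),
      y = "molecules on surface", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-shell structure of a converged state
#'
#' Osmotic field and species volume fractions against distance from the
#' particle center.
#'
#' @param object an `acnp_state`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.acnp_state <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("beta_pi", "phi_bound", "phi_water"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$r, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "r (nm)", y = NULL) +
    ggplot2::theme_minimal()
}
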