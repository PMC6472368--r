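#' Plot a thermodynamic feasibility window
#'
#' Raster of in-situ Gibbs energy over the two varied concentrations
#' (log-log axes), with the dG = 0 feasibility boundary overlaid. The
#' exergonic region (dG < 0) is where the reaction can proceed.
#'
#' @param object A `seep_feasibility` grid from [feasibility_window()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seep_feasibility
#' @export
autoplot.seep_feasibility <- function(object, ...) {
  contour <- zero_contour(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x_conc, .data$y_conc)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dG_kJ)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = paste(object$x_species[1], "(mol/L)"),
                  y = paste(object$y_species[1], "(mol/L)"),
                  fill = "dG (kJ)",
                  title = unique(object$reaction_id))
  if (nrow(contour) > 0) {
    p <- p + ggplot2::geom_line(data = contour,
                                ggplot2::aes(.data$x_conc, .data$y_conc_zero),
                                linewidth = 0.8)
  }
  p
}

#' Plot a pathway presence matrix
#'
#' Genome-by-pathway tile plot in the style of MAG functional-potential
#' figures: filled tiles mark pathways called present under the gene-count
#' rules.
#'
#' @param presence A long presence tibble from [call_pathways()].
#' @return A ggplot.
#' @export
plot_presence_matrix <- function(presence) {
  ggplot2::ggplot(presence,
                  ggplot2::aes(.data$pathway, .data$genome_id,
                               fill = .data$present)) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#e08214",
                                          `FALSE` = "white")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present")
}

#' Plot a metabolite heatmap
#'
#' Pathway-grouped compound-by-sample heatmap of log fractional
#' abundances.
#'
#' @param long A long table from [pathway_ordered_matrix()] applied to a
#'   [log_fractional()] table (column `value` = log10 fraction).
#' @return A ggplot.
#' @export
plot_metabolite_heatmap <- function(long) {
  long <- long %>%
    mutate(compound = factor(.data$compound,
                             levels = rev(unique(.data$compound))))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$compound,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(.data$pathway ~ ., scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   strip.text.y = ggplot2::element_text(angle = 0)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 fraction")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a feasibility grid
#'
#' `tidy()` returns the grid as a plain tibble (one row per concentration
#' pair); `glance()` summarizes it in one row: grid size, the fraction of
#' the grid that is exergonic, and the dG range.
#'
#' @param x A `seep_feasibility` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy seep_feasibility
#' @export
tidy.seep_feasibility <- function(x, ...) {
  as_tibble(unclass_feasibility(x))
}

#' @rdname tidy.seep_feasibility
#' @method glance seep_feasibility
#' @export
glance.seep_feasibility <- function(x, ...) {
  tibble(reaction_id = x$reaction_id[1],
         n_grid = nrow(x),
         frac_exergonic = mean(x$dG_kJ < 0),
         dG_min_kJ = min(x$dG_kJ),
         dG_max_kJ = max(x$dG_kJ),
         n_contour_points = nrow(zero_contour(x)))
}

unclass_feasibility <- function(x) {
  attr(x, "contour") <- NULL
  class(x) <- setdiff(class(x), "seep_feasibility")
  x
}
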