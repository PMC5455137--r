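# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a robustness scan
#'
#' Growth rate (and any tracked secretion fluxes) against substrate uptake.
#'
#' @param object tibble returned by [robustness_scan()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot robustness_scan
#' @export
autoplot.robustness_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = -c("uptake", "status"),
                              names_to = "quantity", values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$uptake, y = .data$flux,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "substrate uptake flux (mmol/gDW/h)", y = "flux",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot flux or yield ranges
#'
#' Point estimates with FVA intervals.
#'
#' @param object tibble from [fva()] (columns `reaction`, `vmin`, `vmax`,
#'   `flux`) or [yield_ranges()] (columns `product`, `y_min`, `y_max`,
#'   `y_point`).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_flux_ranges <- function(object, ...) {
  if ("product" %in% names(object)) {
    object <- dplyr::rename(object, reaction = "product", vmin = "y_min",
                            vmax = "y_max", flux = "y_point")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$reaction, y = .data$flux)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$vmin, ymax = .data$vmax)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (point estimate with feasible range)") +
    ggplot2::theme_minimal()
}

#' Plot perturbation-screen correlations
#'
#' Pearson correlation of each biomass precursor's multiplier against the
#' biomass and PDO yields.
#'
#' @param object a `perturbation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$correlations, cols = c("r_yx", "r_ypdo"),
                              names_to = "yield", values_to = "r")
  long$yield <- c(r_yx = "biomass yield", r_ypdo = "PDO yield")[long$yield]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metabolite_id, y = .data$r,
                                     fill = .data$yield)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "biomass precursor", y = "Pearson r", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a co-fermentation yield surface
#'
#' Maximum PDO yield on glycerol over the glucose x glycerol uptake grid.
#'
#' @param object tibble from [cofermentation_surface()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_cofermentation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$glucose, y = .data$glycerol,
                                       fill = .data$y_pdo_max)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "glucose uptake flux", y = "glycerol uptake flux",
                  fill = "max Y_PDO/S") +
    ggplot2::theme_minimal()
}
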