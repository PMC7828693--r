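# ggplot2 views of flux solutions.

#' Plot the end-product profile of a flux solution
#'
#' Bar chart of mol product per mol glucose read from the exchange fluxes.
#'
#' @param solution A `flux_solution`.
#' @return A ggplot object.
#' @export
plot_yields <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  df <- solution$yields
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$product, -.data$yield),
                                   y = .data$yield)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mol per mol glucose",
                  title = paste0("End products",
                                 if (!is.null(solution$preset))
                                   paste0(" (", solution$preset, ")") else "")) +
    ggplot2::theme_minimal()
}

#' Plot non-zero fluxes by subsystem
#'
#' @param solution A `flux_solution`.
#' @param min_flux Smallest absolute flux to display.
#' @return A ggplot object.
#' @export
plot_fluxes <- function(solution, min_flux = 1e-6) {
  stopifnot(inherits(solution, "flux_solution"))
  df <- dplyr::filter(solution$fluxes, abs(.data$flux) > min_flux)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux,
                                   y = stats::reorder(.data$reaction, .data$flux),
                                   fill = .data$subsystem)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "flux (mol per mol glucose)", y = NULL,
                  fill = "subsystem") +
    ggplot2::theme_minimal()
}

#' @rdname plot_yields
#' @param object A `flux_solution`.
#' @param ... Unused.
#' @export
autoplot.flux_solution <- function(object, ...) plot_yields(object)
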