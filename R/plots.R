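#' Plot a leave-one-system-out result
#'
#' Mutations are ordered by the width of their error bound; the bound is drawn
#' as a line and each mutation's Error as a point, colored by whether it was
#' captured. At the 95% level roughly 5% of points should sit above the line.
#'
#' @param object A `loso_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loso_result
#' @export
autoplot.loso_result <- function(object, ...) {
  d <- object$predictions |>
    dplyr::arrange(.data$width) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$error_abs,
                                     colour = .data$captured), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bound), colour = "blue") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey40",
                                            `FALSE` = "red")) +
    ggplot2::labs(x = "mutations, sorted by bound width",
                  y = "Error and bound (kcal/mol)",
                  colour = "captured") +
    ggplot2::theme_minimal()
}

#' Per-system coverage plot
#'
#' Bar chart of leave-one-system-out coverage per protein system with the
#' nominal level marked.
#'
#' @param result A `loso_result`.
#' @return A ggplot object.
#' @export
plot_system_coverage <- function(result) {
  stopifnot(inherits(result, "loso_result"))
  ggplot2::ggplot(result$per_system,
                  ggplot2::aes(x = .data$system_id, y = 100 * .data$coverage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100 * result$overall$level,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "coverage (%)") +
    ggplot2::theme_minimal()
}

#' Stacked class-frequency plot across ddG bins
#'
#' Visualizes the output of [bin_frequencies()]: relative class frequencies
#' per ddG bin, the binned view of classification reliability.
#'
#' @param freqs Tibble from [bin_frequencies()].
#' @return A ggplot object.
#' @export
plot_bin_frequencies <- function(freqs) {
  ggplot2::ggplot(dplyr::filter(freqs, .data$n_bin > 0),
                  ggplot2::aes(x = .data$bin, y = .data$freq,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "ddG bin (kcal/mol)", y = "relative frequency",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
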