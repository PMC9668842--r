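# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a unique-barcode draw curve
#'
#' Mean unique barcodes against draws, with the theoretical-limit line
#' y = n on which every sampled barcode is unique.
#'
#' @param object A `diversity_curve` from [uniqueness_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diversity_curve <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$draws, y = .data$mean_unique)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "VBC draws", y = "Unique VBCs",
      caption = "dotted: theoretical limit (every draw unique)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative counts by abundance group
#'
#' @param object An `abundance_groups` tibble.
#' @param ... Unused.
#' @return A ggplot of the cumulative count fraction by abundance group.
#' @export
autoplot.abundance_groups <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ag, y = .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "VBC abundance group (UMI count)",
      y = "Cumulative fraction of counts"
    ) +
    ggplot2::theme_minimal()
}

#' Plot inferred network sizes
#'
#' @param object A `vbc_networks` tibble.
#' @param ... Unused.
#' @return A ggplot histogram of member counts, filled by size category.
#' @export
autoplot.vbc_networks <- function(object, ...) {
  df <- tibble::tibble(
    size = object$size,
    category = object$size_category
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "Cells per network", y = "Networks",
      fill = "Presynaptic size"
    ) +
    ggplot2::theme_minimal()
}

#' Plot starter-call evidence
#'
#' Recombined-TVA fraction of rAAV UMIs against rAAV fraction of total
#' UMIs, coloured by the starter call.
#'
#' @param object A `starter_call`.
#' @param profiles The profiles tibble the call was made on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.starter_call <- function(object, profiles, ...) {
  df <- dplyr::inner_join(object$cells, profiles, by = "cell_barcode") |>
    dplyr::mutate(
      tva_frac = ifelse(.data$raav_umis > 0,
        .data$recombined_tva_umis / .data$raav_umis, 0
      ),
      raav_frac = .data$raav_umis / .data$total_umis
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$raav_frac, y = .data$tva_frac, colour = .data$starter
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "#b2182b")
    ) +
    ggplot2::labs(
      x = "rAAV fraction of total UMIs",
      y = "Recombined-TVA fraction of rAAV UMIs",
      colour = "Starter"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an infectivity screen
#'
#' Infected-cell fraction per pseudotime bin.
#'
#' @param object An `infectivity_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.infectivity_screen <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(
    x = .data$bin, y = .data$infected_fraction
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::scale_x_continuous(breaks = object$bins$bin) +
    ggplot2::labs(
      x = "Pseudotime bin", y = "Infected cell fraction"
    ) +
    ggplot2::theme_minimal()
}
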