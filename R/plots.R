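#' Plot best-fraction histograms per motif class
#'
#' Histograms of the per-realization share of system reactivity contributed
#' by the most reactive instance of each motif class.
#'
#' @param object an `ensemble_records` tibble.
#' @param bins number of bins on `[0, 1]`.
#' @param classes motif classes to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ensemble_records
#' @export
autoplot.ensemble_records <- function(object, bins = 50,
                                      classes = c("PP", "AC", "EC", "TTC"),
                                      ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$motif_class %in% classes, !is.na(.data$fraction))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(
      breaks = seq(0, 1, length.out = bins + 1),
      fill = "steelblue", colour = NA
    ) +
    ggplot2::facet_wrap(~motif_class, scales = "free_y") +
    ggplot2::labs(
      x = "share of system reactivity in most reactive instance",
      y = "realizations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot node participation in winning motifs
#'
#' Bar chart of the probability that each node belongs to the most reactive
#' instance of a motif class across a fixed-topology ensemble.
#'
#' @param records an `ensemble_records` tibble from [run_set2()].
#' @param motif_class motif class (default `"AC"`).
#' @return A ggplot object.
#' @export
plot_node_participation <- function(records, motif_class = "AC") {
  dat <- node_participation(records, motif_class)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$node), y = .data$participation
  )) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "species (ascending niche value)",
      y = sprintf("P(node in most reactive %s motif)", motif_class)
    ) +
    ggplot2::theme_minimal()
}
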