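#' Plot an NMDS ordination
#'
#' Scatter of the first two ordination axes. When the sample labels follow
#' the `group|category|start-end` cell convention, points are coloured by
#' disease group and sized by year-pair recency, echoing the usual
#' ordination view of a literature search grid.
#'
#' @param object An `nmds_ord`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmds_ord <- function(object, ...) {
  df <- tidy(object)
  cellish <- all(grepl("^[^|]+\\|[^|]+\\|\\d{4}-\\d{4}$", df$sample))
  if (cellish) {
    parts <- stringr::str_split_fixed(df$sample, stringr::fixed("|"), 3)
    df$disease_group <- parts[, 1]
    df$start_year <- as.integer(sub("-.*", "", parts[, 3]))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                          colour = .data$disease_group,
                                          size = .data$start_year)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_size_continuous(range = c(1, 4)) +
      ggplot2::labs(colour = "Disease group", size = "Start year")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(
    title = "NMDS ordination (Bray-Curtis)",
    subtitle = sprintf("stress = %.4f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Plot LCBD time series per disease group
#'
#' Per-group profiles of local contributions to beta diversity against the
#' year pair, with a smoother indicating the temporal trend; a falling
#' profile marks convergence of a group's literature onto a common set of
#' terms.
#'
#' @param series Tibble from [lcbd_series()].
#' @return A ggplot object.
#' @export
plot_lcbd <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$start_year, .data$lcbd)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~disease_group) +
    ggplot2::labs(x = "Year pair (start year)", y = "LCBD",
                  title = "Local contributions to beta diversity over time") +
    ggplot2::theme_minimal()
}

#' Plot the most frequent terms of a group
#'
#' @param ranking Tibble from [top_terms()].
#' @param group Optional label for the title.
#' @return A ggplot object.
#' @export
plot_top_terms <- function(ranking, group = NULL) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(.data$frequency,
                               stats::reorder(.data$term_id, .data$frequency))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Aggregate normalised frequency", y = NULL,
                  title = if (is.null(group)) "Most frequent terms"
                          else paste("Most frequent terms:", group)) +
    ggplot2::theme_minimal()
}
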