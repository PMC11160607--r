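#' Plot the component-time correlation screen
#'
#' Scatter of per-dataset time correlations for two domains against each
#' other (the selection view used to pick shared vs refractory
#' components): each point is a component, axes are its r with time in two
#' domains.
#'
#' @param object An `eldar_screen` tibble.
#' @param x_domain,y_domain Domains to place on the axes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eldar_screen <- function(object, x_domain = "tissue_age",
                                  y_domain = "reprogramming", ...) {
  wide <- object |>
    dplyr::group_by(.data$component, .data$domain) |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "r")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[x_domain]], y = .data[[y_domain]],
                                     label = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = paste("r with time,", x_domain),
                  y = paste("r with time,", y_domain)) +
    ggplot2::theme_minimal()
}

#' Score-versus-time scatter for projected cohorts
#'
#' @param scores Score tibble from [project_cohort()] (optionally with a
#'   `dataset` column from the pipeline).
#' @param sheet Sample sheet for the scored samples.
#' @param component Component to plot (e.g. `"PC1"`).
#' @return A ggplot object, faceted by dataset.
#' @export
plot_score_time <- function(scores, sheet, component = "PC1") {
  df <- dplyr::inner_join(
    dplyr::select(scores, "sample_id", dplyr::all_of(component)),
    sheet, by = "sample_id") |>
    dplyr::filter(!is.na(.data$time_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_value,
                                   y = .data[[component]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~dataset, scales = "free_x") +
    ggplot2::labs(x = "time (per-dataset units)", y = paste(component, "score")) +
    ggplot2::theme_minimal()
}

#' Fold-enrichment bar chart for a composition report
#'
#' @param report Tibble from [composition_report()].
#' @param track Annotation track to display.
#' @return A ggplot object, faceted by CpG set.
#' @export
plot_enrichment <- function(report, track = "island_relation") {
  df <- dplyr::filter(report, .data$track == !!track)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = NULL, y = "fold enrichment vs background") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
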