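#' Plots for rankings and evaluation reports
#'
#' `autoplot()` methods give quick diagnostic figures: per-topic metric bars
#' for a `metrics_report`, and the feature decomposition of the top of a
#' `triage_ranking`. `plot_axis_counts()` shows per-axis annotation volume
#' for a collection-statistics row.
#'
#' @name plots
NULL

#' @param object A `metrics_report` or `triage_ranking`.
#' @param ... Unused.
#' @rdname plots
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("p_at_k", "ap"), names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(
      .data$metric,
      p_at_k = paste0("P@", attr(object, "k")), ap = "AP"
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$topic_id, .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "topic", y = "metric value",
      title = paste0("Retrieval effectiveness (", attr(object, "tag"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @param n_top Number of top-ranked documents to show.
#' @rdname plots
#' @method autoplot triage_ranking
#' @export
autoplot.triage_ranking <- function(object, n_top = 20L, ...) {
  top <- utils::head(tidy(object), n_top)
  long <- top |>
    dplyr::mutate(doc_id = factor(.data$doc_id, levels = rev(top$doc_id))) |>
    tidyr::pivot_longer(c("base_score", "specificity", "density"),
      names_to = "feature", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$doc_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(
      x = "feature value", y = NULL,
      title = "Triage features of top-ranked documents"
    ) +
    ggplot2::theme_minimal()
}

#' @param stats A one-row tibble from [aggregate_stats()].
#' @rdname plots
#' @export
plot_axis_counts <- function(stats) {
  long <- stats |>
    tidyr::pivot_longer(dplyr::all_of(AXES), names_to = "axis", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$axis, .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "axis", y = "annotations",
      title = paste0("Annotations per axis (", stats$collection[[1L]], ")")
    ) +
    ggplot2::theme_minimal()
}
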