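#' Plot MRR against context size
#'
#' One line per method (solid for the rule-based recommender, dotted for the
#' context-free baseline), MRR aggregated over fields on the y axis, number of
#' populated context fields on the x axis.
#'
#' @param object A `recommender_eval` from [evaluate_recommender()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommender_eval <- function(object, ...) {
  df <- mrr_by_context(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context_size, y = .data$mrr,
                                   colour = .data$method,
                                   linetype = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_linetype_manual(
      values = c(baseline = "dotted", recommender = "solid")) +
    ggplot2::scale_x_continuous(breaks = unique(df$context_size)) +
    ggplot2::labs(x = "populated context fields", y = "mean reciprocal rank",
                  colour = NULL, linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot MRR per target field
#'
#' Bar chart of the field-level MRR (aggregated over context sizes) for both
#' methods, highlighting where context helps most.
#'
#' @param x A `recommender_eval` object.
#' @return A ggplot object.
#' @export
plot_mrr_by_field <- function(x) {
  df <- x$cells %>%
    group_by(.data$method, .data$field) %>%
    summarise(mrr = sum(.data$mrr * .data$n) / sum(.data$n),
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$field, y = .data$mrr,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean reciprocal rank", fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a recommendation list
#'
#' Horizontal bars of recommendation scores, best value on top, labelled with
#' the percentage form shown to users.
#'
#' @param object A `recommendation_tbl` from [recommend_values()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommendation_tbl <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(value_label = factor(.data$value_label,
                                levels = rev(.data$value_label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recommendation_score,
                                   y = .data$value_label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = percent_score(.data$recommendation_score)), hjust = -0.1) +
    ggplot2::xlim(0, 1.1) +
    ggplot2::labs(x = "recommendation score", y = NULL) +
    ggplot2::theme_minimal()
}
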