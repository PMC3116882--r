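#' Plot a p-value histogram with its uniform reference
#'
#' @param object A `pvalue_histogram` (see [pvalue_histogram()]).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pvalue_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    xmin = .data$bin_low, xmax = .data$bin_high, ymin = 0, ymax = .data$count
  )) +
    ggplot2::geom_rect(fill = "grey70", colour = "white") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected),
                        linetype = "dashed") +
    ggplot2::labs(x = "p-value", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot per-sample vote fractions of a subtype assignment
#'
#' Samples ordered by vote fraction, colored by the final majority-vote call.
#'
#' @param object A `subtype_assignment` (see [assign_subtypes()]).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.subtype_assignment <- function(object, ...) {
  thr <- attr(object, "vote_threshold") / attr(object, "n_repeats")
  df <- dplyr::arrange(tibble::as_tibble(object), .data$vote_fraction)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$vote_fraction,
                                   fill = factor(.data$awa))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey60", `1` = "firebrick"),
                               name = "AWA profile") +
    ggplot2::labs(x = "sample (ordered)", y = "vote fraction") +
    ggplot2::theme_minimal()
}

#' Plot association strength across signature sizes
#'
#' @param object A `k_sweep` (see [sweep_k()]).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$odds_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "best_k"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "number of genes (k)", y = "odds ratio") +
    ggplot2::theme_minimal()
}

#' Scatter of cross-study fold changes
#'
#' @param object A `concordance_result` (see [concordance()]).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(.data$fc_a, .data$fc_b,
                               colour = .data$significant_both)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick"),
                                 name = "p < alpha in both") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "log2 fold change, study A",
                  y = "log2 fold change, study B") +
    ggplot2::theme_minimal()
}
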