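# ggplot2 helpers for the main result types.

#' ROC curves of an ensemble fit
#'
#' One curve per fitted family plus the ensemble score, pooled over all
#' test-set predictions.
#'
#' @param fit a `sno_ensemble_fit`.
#' @return a ggplot object.
#' @export
plot_roc <- function(fit) {
  pr <- fit$predictions
  curves <- purrr::map_dfr(c(fit$families, "ensemble"), function(fam) {
    roc_points(pr[[paste0(fam, "_score")]], pr$truth) |>
      mutate(model = fam)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sno_ensemble_fit <- function(object, ...) plot_roc(object)

#' Predictive-rank distribution per feature
#'
#' Boxplots of the per-(model, iteration) predictive ranks, features
#' ordered by median rank (most predictive at the top).
#'
#' @param rank_table tibble from [rank_features()].
#' @return a ggplot object.
#' @export
plot_rank_distribution <- function(rank_table) {
  ord <- summarise_ranks(rank_table)$feature
  rank_table |>
    mutate(feature = factor(.data$feature, levels = rev(ord))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rank, y = .data$feature)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = "Predictive rank (1 = most predictive)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sequence-logo frequencies of a motif
#'
#' Stacked per-position nucleotide frequencies with the cumulative Shannon
#' entropy in the subtitle — the plot-ready form of a frequency logo.
#'
#' @param logo result of [motif_logo_stats()].
#' @return a ggplot object.
#' @export
plot_motif_logo <- function(logo) {
  df <- as_tibble(logo$pfm, rownames = "nucleotide") |>
    tidyr::pivot_longer(-"nucleotide", names_to = "position",
                        values_to = "freq") |>
    mutate(position = as.integer(sub("^V", "", .data$position)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$freq,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Motif position", y = "Frequency", fill = NULL,
                  subtitle = sprintf("Cumulative Shannon entropy: %.2f bits (found in %.1f%%)",
                                     logo$cumulative_entropy,
                                     100 * logo$proportion_found)) +
    ggplot2::theme_minimal()
}
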