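#' Kaplan-Meier step curves per group
#'
#' @param object A [km_logrank()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Overall survival",
                  color = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-set enrichment correlations with a score
#'
#' @param cor_table A [correlate_with_score()] result.
#' @param top_n Number of sets shown (largest |r| first).
#' @return A ggplot.
#' @export
plot_enrichment_correlation <- function(cor_table, top_n = 20) {
  df <- cor_table |>
    dplyr::filter(!.data$degenerate) |>
    dplyr::slice_max(abs(.data$r), n = top_n) |>
    dplyr::mutate(set_name = stats::reorder(.data$set_name, .data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$set_name,
                                   fill = .data$r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Pearson r with score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two biomarker scores with an OLS line
#'
#' @param x_score,y_score Score tibbles (raw or adjusted; adjusted values
#'   used where available).
#' @return A ggplot annotated with the Pearson correlation.
#' @export
plot_score_scatter <- function(x_score, y_score) {
  pick <- function(s) {
    if (inherits(s, "adjusted_score")) s$score_adjusted else s$score
  }
  df <- dplyr::inner_join(
    tibble::tibble(sample_id = x_score$sample_id, x = pick(x_score)),
    tibble::tibble(sample_id = y_score$sample_id, y = pick(y_score)),
    by = "sample_id")
  r <- stats::cor(df$x, df$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = attr(x_score, "score_name") %||% "x",
                  y = attr(y_score, "score_name") %||% "y",
                  subtitle = sprintf("Pearson r = %.2f", r)) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a per-gene Cox screen
#'
#' @param ranking A [rank_emt_genes()] result.
#' @param p_cutoff Dashed significance line.
#' @return A ggplot of beta vs -log10 Wald p, colored by direction.
#' @export
plot_gene_ranking <- function(ranking, p_cutoff = 0.05) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$beta, y = -log10(.data$wald_p),
                               color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = "dashed") +
    ggplot2::labs(x = "log hazard ratio (per log2 expression unit)",
                  y = expression(-log[10] ~ "Wald p"), color = NULL) +
    ggplot2::theme_minimal()
}
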