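#' Single-sample gene-set enrichment score (ssGSEA) for one sample
#'
#' Genes are ranked by expression (average ranks for ties; the top gene has
#' rank N). Walking down the ranking, the running sum increases by the gene's
#' rank weight `rank^alpha` (normalized over in-set genes) at set members and
#' decreases by `1/(N - |G|)` at non-members; the enrichment score is the sum
#' of the running sum over all positions (the ssGSEA convention, as opposed
#' to the max-deviation GSEA statistic). Ties in expression are walked in a
#' deterministic order (decreasing expression, then gene id), which together
#' with average-rank weights makes the score invariant to gene order and to
#' any strictly monotone transform of the expression values.
#'
#' @param expr_values Named numeric vector: one sample's expression.
#' @param gene_set Character vector of gene ids; must overlap `expr_values`
#'   and must not cover all genes.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return A single numeric enrichment score.
#' @export
ssgsea_sample <- function(expr_values, gene_set, alpha = 0.25) {
  if (is.null(names(expr_values))) abort_itaemt("expr_values must be named by gene")
  n <- length(expr_values)
  in_set <- names(expr_values) %in% gene_set
  n_hit <- sum(in_set)
  if (n_hit == 0) abort_itaemt("gene set has no overlap with the expression profile")
  if (n_hit == n) abort_itaemt("gene set covers every gene: miss penalty undefined")
  r <- rank(expr_values, ties.method = "average")
  ord <- order(-expr_values, names(expr_values), method = "radix")
  w <- r[ord]^alpha
  hit <- in_set[ord]
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  sum(cumsum(inc - dec))
}

#' Enrichment scores for every gene set in every sample
#'
#' Applies [ssgsea_sample()] to each sample column for each set in the
#' collection. Sets with no overlap (or covering all genes) are skipped with
#' a warning.
#'
#' @param expr Genes x samples expression matrix.
#' @param collection A [gene_set_collection()] (or named list of gene ids).
#' @param alpha Rank-weight exponent.
#' @return A long tibble (class `enrichment_tbl`) with columns `set_name`,
#'   `sample_id`, `es`, and attributes `method_tag = "ssgsea_rank_sum"`,
#'   `alpha`.
#' @export
enrich_all <- function(expr, collection, alpha = 0.25) {
  n <- nrow(expr)
  usable <- vapply(collection, function(g) {
    k <- sum(rownames(expr) %in% g)
    k > 0 && k < n
  }, logical(1))
  if (!any(usable)) abort_itaemt("no usable gene set (all empty overlap or full coverage)")
  if (any(!usable)) {
    rlang::warn(sprintf("skipping %d gene set(s) with empty overlap or full coverage: %s",
                        sum(!usable),
                        paste(utils::head(names(collection)[!usable], 5), collapse = ", ")))
  }
  sets <- collection[usable]
  gene_ids <- rownames(expr)
  member <- vapply(sets, function(g) gene_ids %in% g, logical(n))
  # one ranking per sample, shared across sets; identical to per-set
  # ssgsea_sample() calls
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, gene_ids, method = "radix")
    w <- r[ord]^alpha
    vapply(seq_along(sets), function(s) {
      hit <- member[ord, s]
      n_hit <- sum(hit)
      inc <- ifelse(hit, w / sum(w[hit]), 0)
      dec <- ifelse(hit, 0, 1 / (n - n_hit))
      sum(cumsum(inc - dec))
    }, numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), colnames(expr)))
  out <- tidyr::pivot_longer(
    tibble::as_tibble(scores, rownames = "set_name"),
    cols = -"set_name", names_to = "sample_id", values_to = "es")
  structure(out, method_tag = "ssgsea_rank_sum", alpha = alpha,
            class = c("enrichment_tbl", class(tibble::tibble())))
}

#' Correlate per-set enrichment with a biomarker score across samples
#'
#' Pearson (default) or Spearman correlation of each set's enrichment scores
#' with the score over shared samples; two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom (the
#' `cor.test` statistic). Sets whose enrichment has zero variance are flagged
#' (`degenerate = TRUE`, `r = NA`) rather than dropped. No multiplicity
#' correction is applied.
#'
#' @param es An [enrich_all()] result (long tibble `set_name`, `sample_id`,
#'   `es`).
#' @param score An `itaemt_score` tibble (`sample_id`, `score`).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble (`set_name`, `r`, `p`, `n`, `degenerate`), sorted by `r`
#'   descending (degenerate rows last).
#' @export
correlate_with_score <- function(es, score, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  merged <- dplyr::inner_join(tibble::as_tibble(es),
                              tibble::as_tibble(score)[, c("sample_id", "score")],
                              by = "sample_id")
  if (length(unique(merged$sample_id)) < 3) {
    abort_itaemt("need at least 3 shared samples to correlate")
  }
  out <- merged |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(res = list({
      if (stats::sd(.data$es) == 0 || stats::sd(.data$score) == 0) {
        tibble::tibble(r = NA_real_, p = NA_real_,
                       n = dplyr::n(), degenerate = TRUE)
      } else {
        ct <- suppressWarnings(stats::cor.test(.data$es, .data$score, method = method))
        tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                       n = dplyr::n(), degenerate = FALSE)
      }
    }), .groups = "drop") |>
    tidyr::unnest("res") |>
    dplyr::arrange(.data$degenerate, dplyr::desc(.data$r))
  out
}
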