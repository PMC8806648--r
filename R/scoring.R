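#' Select T-cell marker genes from an immune signature matrix
#'
#' Each signature row is normalized by its mean across all cell-type columns
#' (so values are fold-changes relative to the gene's average level), and a
#' gene is selected as a T-cell marker iff the mean normalized value over the
#' T-lineage columns is strictly greater than `threshold`. With the default
#' threshold of 2 this reads "at least two-fold above the gene's average
#' across cell types in T cells". Rows that are all zero are excluded with a
#' warning (their normalization is undefined).
#'
#' @param sig Genes x cell-types numeric matrix (e.g. an LM22-style matrix
#'   read with [read_signature_matrix()], or [simulate_signature_matrix()]).
#' @param t_cell_labels Columns of `sig` treated as the T-cell lineage;
#'   defaults to the matrix's `t_cell_labels` attribute when present.
#' @param threshold Selection threshold on the normalized T-cell mean.
#' @return A list of class `marker_selection` with `marker_genes` (in `sig`
#'   gene order), `threshold`, `t_cell_labels`, `normalization_tag`
#'   (`"row_mean"`), and `table` (a per-gene tibble of normalized T-cell
#'   means and selection flags).
#' @export
select_t_cell_markers <- function(sig, t_cell_labels = NULL, threshold = 2) {
  t_cell_labels <- t_cell_labels %||% attr(sig, "t_cell_labels")
  if (is.null(t_cell_labels) || length(t_cell_labels) == 0) {
    abort_itaemt("t_cell_labels must be supplied (or carried by the signature matrix)")
  }
  unknown <- setdiff(t_cell_labels, colnames(sig))
  if (length(unknown) > 0) {
    abort_itaemt(sprintf("unknown T-cell column(s): %s", paste(unknown, collapse = ", ")))
  }
  assert_scalar_number(threshold, "threshold")
  row_means <- rowMeans(sig)
  zero_rows <- row_means == 0
  if (any(zero_rows)) {
    rlang::warn(sprintf("excluding %d all-zero signature row(s): normalization undefined",
                        sum(zero_rows)))
  }
  t_mean <- rowMeans(sig[, t_cell_labels, drop = FALSE])
  norm_t_mean <- ifelse(zero_rows, NA_real_, t_mean / row_means)
  selected <- !zero_rows & norm_t_mean > threshold
  table <- tibble::tibble(
    gene = rownames(sig),
    norm_t_mean = unname(norm_t_mean),
    selected = unname(selected)
  )
  structure(list(
    marker_genes = rownames(sig)[selected],
    threshold = threshold,
    t_cell_labels = t_cell_labels,
    normalization_tag = "row_mean",
    table = table
  ), class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("<marker_selection> %d gene(s) with %s-normalized T-cell mean > %g over %d T-cell column(s)\n",
              length(x$marker_genes), x$normalization_tag, x$threshold,
              length(x$t_cell_labels)))
  invisible(x)
}

#' Mean log2 expression score over a gene set
#'
#' The per-sample score is the arithmetic mean of `log2(x + pseudocount)`
#' over the listed genes found in the matrix. Listed genes absent from the
#' matrix are dropped from the mean (not imputed) and counted in
#' `n_genes_missing`; a warning reports the count.
#'
#' @param expr Linear-scale genes x samples [expression_matrix()].
#' @param genes Character vector of gene ids.
#' @param pseudocount Added before the log; default 1.
#' @param name Score label (`"ITA"`, `"EMT"`, ...).
#' @return A tibble (class `itaemt_score`) with columns `sample_id`, `score`,
#'   and attributes `score_name`, `adjusted = FALSE`, `n_genes_used`,
#'   `n_genes_missing`, `pseudocount`.
#' @export
mean_log_score <- function(expr, genes, pseudocount = 1, name = "score") {
  if (scale_tag(expr) != "linear") {
    abort_itaemt("expression matrix is already log-scale; refusing to log again")
  }
  if (length(genes) == 0) abort_itaemt("empty gene list")
  if (anyDuplicated(genes)) genes <- unique(genes)
  found <- genes[genes %in% rownames(expr)]
  n_missing <- length(genes) - length(found)
  if (length(found) == 0) {
    abort_itaemt(sprintf("none of the %d listed gene(s) are present in the expression matrix",
                         length(genes)))
  }
  if (n_missing > 0) {
    rlang::warn(sprintf("%s score: %d of %d listed gene(s) absent from the matrix; using %d",
                        name, n_missing, length(genes), length(found)))
  }
  vals <- colMeans(log2(expr[found, , drop = FALSE] + pseudocount))
  out <- tibble::tibble(sample_id = colnames(expr), score = unname(vals))
  new_score(out, name = name, adjusted = FALSE,
            n_genes_used = length(found), n_genes_missing = n_missing,
            pseudocount = pseudocount)
}

new_score <- function(tbl, name, adjusted, n_genes_used = NA_integer_,
                      n_genes_missing = NA_integer_, pseudocount = NA_real_) {
  structure(tbl,
            score_name = name, adjusted = adjusted,
            n_genes_used = n_genes_used, n_genes_missing = n_genes_missing,
            pseudocount = pseudocount,
            class = c("itaemt_score", class(tibble::tibble())))
}

#' Infiltrating T-cell abundance (ITA) score
#'
#' Mean log2 expression of the selected T-cell marker genes per sample.
#'
#' @param expr Linear-scale expression matrix.
#' @param markers A [select_t_cell_markers()] result, or a character vector
#'   of marker gene ids.
#' @param pseudocount Added before the log.
#' @return An `itaemt_score` tibble named `"ITA"`.
#' @export
ita_score <- function(expr, markers, pseudocount = 1) {
  genes <- if (inherits(markers, "marker_selection")) markers$marker_genes else markers
  mean_log_score(expr, genes, pseudocount = pseudocount, name = "ITA")
}

#' EMT gene-expression score
#'
#' Mean log2 expression of the EMT gene set (200 hallmark
#' epithelial-mesenchymal-transition genes in the reference collection).
#'
#' @param expr Linear-scale expression matrix.
#' @param emt_set Character vector of EMT gene ids.
#' @param pseudocount Added before the log.
#' @return An `itaemt_score` tibble named `"EMT"`.
#' @export
emt_score <- function(expr, emt_set, pseudocount = 1) {
  mean_log_score(expr, emt_set, pseudocount = pseudocount, name = "EMT")
}

#' Per-sample ITA and EMT scores as one tibble
#'
#' Convenience wrapper running [ita_score()] and [emt_score()] on the same
#' matrix and joining the results.
#'
#' @inheritParams ita_score
#' @inheritParams emt_score
#' @return Tibble with columns `sample_id`, `ita`, `emt`.
#' @export
compute_scores <- function(expr, markers, emt_set, pseudocount = 1) {
  ita <- ita_score(expr, markers, pseudocount)
  emt <- emt_score(expr, emt_set, pseudocount)
  tibble::tibble(sample_id = ita$sample_id, ita = ita$score, emt = emt$score)
}
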