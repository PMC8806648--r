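#' Construct and validate an expression matrix
#'
#' The package's expression container is a plain numeric matrix with genes in
#' rows (unique rownames) and samples in columns (unique colnames), carrying a
#' `scale_tag` attribute that records whether the values are linear-scale
#' abundances (TPM/RSEM-like) or already `log2(x + 1)` transformed. Scoring
#' functions refuse to re-log an already-logged matrix.
#'
#' @param values Numeric matrix, genes x samples, with rownames and colnames.
#' @param scale_tag `"linear"` (all values must be finite and non-negative)
#'   or `"log2p1"`.
#' @return The validated matrix with the `scale_tag` attribute set.
#' @export
expression_matrix <- function(values, scale_tag = c("linear", "log2p1")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_itaemt("`values` must be a numeric matrix")
  }
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || is.null(sn)) {
    abort_itaemt("expression matrix needs rownames (genes) and colnames (samples)")
  }
  if (anyDuplicated(gn)) {
    abort_itaemt(sprintf("duplicate gene ids: %s",
                         paste(unique(gn[duplicated(gn)])[1:3], collapse = ", ")))
  }
  if (anyDuplicated(sn)) abort_itaemt("duplicate sample ids")
  if (any(!is.finite(values))) abort_itaemt("expression values must all be finite")
  if (scale_tag == "linear" && any(values < 0)) {
    abort_itaemt("linear-scale expression values must be non-negative")
  }
  attr(values, "scale_tag") <- scale_tag
  values
}

scale_tag <- function(expr) attr(expr, "scale_tag") %||% "linear"

#' Read a delimited expression table
#'
#' Reads a TSV/CSV with one header line and identifier first column into a
#' genes x samples [expression_matrix()], whichever way the file is oriented.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (default; TCGA/GEO convention) or
#'   `"samples_in_rows"`.
#' @param delim `"tab"` (default) or `"comma"`.
#' @return A genes x samples expression matrix, `scale_tag = "linear"`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   delim = c("tab", "comma")) {
  orientation <- match.arg(orientation)
  delim <- switch(match.arg(delim), tab = "\t", comma = ",")
  if (!file.exists(path)) abort_itaemt(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort_itaemt("expression table needs an id column plus data")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort_itaemt(sprintf("duplicate row ids in %s: %s", path,
                         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(df[-1], function(x) as.numeric(x), numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_itaemt(sprintf(
      "non-numeric or missing cell at row '%s', column '%s'",
      rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)
    abort_itaemt(sprintf("negative expression value at row '%s', column '%s'",
                         rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals, "linear")
}

#' Write an expression matrix as a delimited table
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param delim `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delim = c("tab", "comma")) {
  delim <- switch(match.arg(delim), tab = "\t", comma = ",")
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a signature matrix (genes x cell types)
#'
#' Same format rules as [read_expression_matrix()]; cell types are columns.
#' The LM22-style matrices this mirrors carry 22 immune cell types/states.
#'
#' @inheritParams read_expression_matrix
#' @return A genes x cell-types numeric matrix.
#' @export
read_signature_matrix <- function(path, delim = c("tab", "comma")) {
  read_expression_matrix(path, orientation = "genes_in_rows", delim = delim)
}
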