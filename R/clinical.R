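#' Read a clinical table with overall-survival columns
#'
#' Maps arbitrary column names onto the package's clinical schema
#' (`sample_id`, `os_time` in days, `os_event` with 1 = death observed,
#' 0 = censored, optional `cohort`). Rows with missing time or event are
#' dropped with a message reporting the count.
#'
#' @param path File path.
#' @param column_map Named list/character vector mapping schema names
#'   (`sample_id`, `os_time`, `os_event`, optionally `cohort`) to the file's
#'   column names.
#' @param event_aliases Named numeric vector translating textual event codes
#'   to 0/1 (case-insensitive); defaults cover dead/deceased/alive/living.
#' @param delim `"tab"` or `"comma"`.
#' @return A tibble with columns `sample_id`, `os_time`, `os_event`, `cohort`.
#' @export
read_clinical_table <- function(path,
                                column_map = c(sample_id = "sample_id",
                                               os_time = "os_time",
                                               os_event = "os_event"),
                                event_aliases = c(dead = 1, deceased = 1,
                                                  alive = 0, living = 0),
                                delim = c("tab", "comma")) {
  delim <- switch(match.arg(delim), tab = "\t", comma = ",")
  if (!file.exists(path)) abort_itaemt(sprintf("file not found: %s", path))
  column_map <- as.list(column_map)
  for (f in c("sample_id", "os_time", "os_event")) {
    if (is.null(column_map[[f]])) {
      abort_itaemt(sprintf("column_map must name a column for '%s'", f))
    }
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  missing_cols <- setdiff(unlist(column_map), colnames(df))
  if (length(missing_cols) > 0) {
    abort_itaemt(sprintf("clinical table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = df[[column_map$sample_id]],
    os_time = suppressWarnings(as.numeric(df[[column_map$os_time]])),
    os_event_raw = df[[column_map$os_event]],
    cohort = if (!is.null(column_map$cohort)) df[[column_map$cohort]] else "cohort1"
  )
  n0 <- nrow(out)
  out <- dplyr::filter(out, !is.na(.data$os_time),
                       !is.na(.data$os_event_raw), nzchar(.data$os_event_raw))
  if (nrow(out) < n0) {
    rlang::inform(sprintf("read_clinical_table: dropped %d row(s) with missing time or event",
                          n0 - nrow(out)))
  }
  ev <- out$os_event_raw
  num <- suppressWarnings(as.numeric(ev))
  alias <- unname(event_aliases[tolower(ev)])
  os_event <- ifelse(!is.na(num), num, alias)
  if (any(is.na(os_event)) || !all(os_event %in% c(0, 1))) {
    bad <- unique(ev[is.na(os_event) | !(os_event %in% c(0, 1))])[1]
    abort_itaemt(sprintf("unrecognized event code: '%s' (expected 0/1 or a mapped alias)", bad))
  }
  out$os_event <- as.integer(os_event)
  out$os_event_raw <- NULL
  if (any(out$os_time < 0)) abort_itaemt("negative survival time in clinical table")
  if (anyDuplicated(out$sample_id)) abort_itaemt("duplicate sample ids in clinical table")
  dplyr::select(out, "sample_id", "os_time", "os_event", "cohort")
}

#' Restrict an expression matrix and clinical table to shared samples
#'
#' Both outputs are restricted to the intersection of sample ids, in the
#' same (expression-matrix) order. The intersection size is reported.
#'
#' @param expr Genes x samples expression matrix.
#' @param clin Clinical tibble with a `sample_id` column.
#' @return A list with elements `expr` and `clin`.
#' @export
align_cohort <- function(expr, clin) {
  shared <- intersect(colnames(expr), clin$sample_id)
  if (length(shared) == 0) abort_itaemt("no samples shared between expression and clinical data")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  tag <- scale_tag(expr)
  expr2 <- expr[, shared, drop = FALSE]
  attr(expr2, "scale_tag") <- tag
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rlang::inform(sprintf("align_cohort: %d shared sample(s)", length(shared)))
  list(expr = expr2, clin = clin2)
}
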