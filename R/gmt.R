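#' Read gene sets from a GMT file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene ids. Gene order within a set is kept;
#' duplicated genes within a line are dropped with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @param source_tag Free-text provenance label stored on the result.
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with attribute `source_tag`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) abort_itaemt(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort_itaemt(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      rlang::warn(sprintf("GMT set '%s': dropping %d duplicate gene(s)",
                          fields[1], sum(duplicated(genes))))
      genes <- genes[!duplicated(genes)]
    }
    if (length(genes) == 0) {
      abort_itaemt(sprintf("GMT set '%s' (line %d) is empty", fields[1], i))
    }
    nms[i] <- fields[1]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    abort_itaemt(sprintf("duplicate gene-set name: %s", nms[duplicated(nms)][1]))
  }
  names(sets) <- nms
  gene_set_collection(sets, source_tag)
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors; names unique, sets non-empty,
#'   no duplicate genes within a set.
#' @param source_tag Provenance label.
#' @return The validated collection (class `gene_set_collection`).
#' @export
gene_set_collection <- function(sets, source_tag = "in-memory") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_itaemt("`sets` must be a fully named list")
  }
  if (anyDuplicated(names(sets))) abort_itaemt("duplicate gene-set names")
  ok <- vapply(sets, function(g) is.character(g) && length(g) > 0 && !anyDuplicated(g),
               logical(1))
  if (!all(ok)) {
    abort_itaemt(sprintf("gene set '%s' is empty or has duplicate genes",
                         names(sets)[!ok][1]))
  }
  structure(sets, source_tag = source_tag, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_set_collection` (or plain named list of character
#'   vectors).
#' @param path Output path.
#' @param descriptions Optional character vector of per-set description
#'   fields; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
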