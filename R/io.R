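#' Read and write trioscape tables
#'
#' Plain-TSV readers/writers for the four cohort tables used throughout the
#' package: the gene universe (symbol, transcript length, rare-variant count,
#' class), gene lists (GMT or one-symbol-per-line), proband metadata, and
#' damaged-genotype calls. Gene symbols are upper-cased and trimmed on load;
#' duplicated symbols within a list are dropped with a warning.
#'
#' @param path File path.
#' @param x Tibble (writers) or ignored.
#' @return Readers return tibbles; `read_gene_lists()` returns a named list of
#'   character vectors.
#' @name trioscape_io
NULL

#' @rdname trioscape_io
#' @export
read_universe <- function(path) {
  u <- readr::read_tsv(path, show_col_types = FALSE)
  u$gene <- norm_symbols(u$gene)
  validate_universe(u)
  u
}

#' @rdname trioscape_io
#' @export
write_universe <- function(x, path) readr::write_tsv(x, path)

#' @rdname trioscape_io
#' @export
read_probands <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname trioscape_io
#' @export
write_probands <- function(x, path) readr::write_tsv(x, path)

#' @rdname trioscape_io
#' @export
read_calls <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  calls$gene <- norm_symbols(calls$gene)
  calls
}

#' @rdname trioscape_io
#' @export
write_calls <- function(x, path) readr::write_tsv(x, path)

#' @rdname trioscape_io
#' @export
read_gene_lists <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (all(!grepl("\t", lines))) {
    # one-symbol-per-line file: a single unnamed list
    members <- dedup_list(norm_symbols(lines), "list")
    return(setNames(list(members), tools::file_path_sans_ext(basename(path))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, character(1), 1L)
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3L) character(0) else dedup_list(norm_symbols(p[-(1:2)]), nms[i])
  })
  setNames(out, nms)
}

#' @rdname trioscape_io
#' @param lists Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector of GMT description fields.
#' @export
write_gene_lists <- function(lists, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("trioscape", length(lists))
  lines <- vapply(seq_along(lists), function(i) {
    paste(c(names(lists)[i], descriptions[i], lists[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

dedup_list <- function(members, name) {
  if (anyDuplicated(members)) {
    rlang::warn(sprintf("gene list '%s': dropping %d duplicated symbol(s)",
                        name, sum(duplicated(members))))
    members <- unique(members)
  }
  members
}

validate_universe <- function(universe) {
  stopifnot(all(c("gene", "transcript_length", "rare_variant_count") %in% names(universe)))
  if (anyDuplicated(universe$gene)) {
    ts_abort("duplicate gene symbols in universe", "validation_error")
  }
  if (any(universe$transcript_length <= 0)) {
    ts_abort("transcript lengths must be positive", "validation_error")
  }
  if (any(universe$rare_variant_count < 0)) {
    ts_abort("rare-variant counts must be non-negative", "validation_error")
  }
  invisible(universe)
}

# internal: restrict a gene list to universe symbols, warning about outsiders
restrict_to_universe <- function(members, universe, name = "list") {
  members <- unique(norm_symbols(members))
  outside <- setdiff(members, universe$gene)
  if (length(outside) > 0) {
    rlang::warn(sprintf("gene list '%s': dropping %d symbol(s) not in universe",
                        name, length(outside)))
    members <- setdiff(members, outside)
  }
  if (length(members) == 0) ts_abort("gene list is empty after restriction", "validation_error")
  members
}
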