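#' Carrier-by-phenotype contingency table
#'
#' Builds the 2x2 table relating carriage of a retained damaged recessive
#' genotype in a gene list (rows: carrier yes/no) to a phenotype class
#' (columns: e.g. heterotaxy yes/no).
#'
#' @param probands Proband metadata tibble (`proband_id`, `phenotype`).
#' @param retained Retained-call tibble.
#' @param members Character vector of list gene symbols.
#' @param phenotype Phenotype class defining the positive column (default
#'   `"HTX"`).
#' @param mode Inheritance mode defining carriage.
#' @return One-row tibble `a`, `b`, `c`, `d`: carrier/phenotype, carrier/other,
#'   non-carrier/phenotype, non-carrier/other.
#' @export
build_table <- function(probands, retained, members, phenotype = "HTX",
                        mode = c("recessive", "de_novo")) {
  mode <- match.arg(mode)
  modes <- if (mode == "recessive") c("recessive_hom", "compound_het") else "de_novo"
  unknown <- setdiff(unique(retained$proband_id), probands$proband_id)
  if (length(unknown) > 0) {
    ts_abort(sprintf("calls reference probands missing from metadata: %s",
                     paste(head(unknown), collapse = ", ")), "validation_error")
  }
  carriers <- unique(retained$proband_id[retained$mode %in% modes &
                                           retained$gene %in% members])
  is_carrier <- probands$proband_id %in% carriers
  is_pheno <- probands$phenotype == phenotype
  tibble::tibble(
    a = sum(is_carrier & is_pheno), b = sum(is_carrier & !is_pheno),
    c = sum(!is_carrier & is_pheno), d = sum(!is_carrier & !is_pheno)
  )
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one, with a small relative tolerance for ties. A table with a zero
#' row or column margin has p = 1.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d), or `a` may be a
#'   one-row tibble / 2x2 matrix holding all four.
#' @return Two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (is.data.frame(a)) { b <- a$b; c <- a$c; d <- a$d; a <- a$a }
  if (is.matrix(a)) { m <- a; a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2] }
  if (any(c(a, b, c, d) < 0)) ts_abort("counts must be non-negative", "validation_error")
  if (a + b + c + d == 0) ts_abort("empty table", "validation_error")
  min(1, fisher.test(matrix(c(a, c, b, d), 2))$p.value)
}

#' Benjamini-Hochberg significance flags
#'
#' Standard step-up false-discovery-rate procedure: with `m` p-values sorted
#' ascending, find the largest rank `i` with `p_(i) <= i * fdr / m` and flag
#' all p-values of rank `<= i`. Adjusted p-values are reported alongside the
#' flags.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param fdr Target false discovery rate.
#' @return Tibble: `p`, `p_adjusted`, `significant`, in input order.
#' @export
bh_adjust <- function(p_values, fdr = 0.1) {
  if (any(p_values <= 0 | p_values > 1)) {
    ts_abort("p-values must be in (0, 1]", "validation_error")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adjusted = adj, significant = adj <= fdr)
}

#' Phenotype association across gene lists
#'
#' For each gene list, builds the carrier-by-phenotype 2x2 table, computes the
#' two-sided Fisher exact p-value, and applies Benjamini-Hochberg control
#' across lists.
#'
#' @inheritParams build_table
#' @param lists Named list of character vectors.
#' @param fdr Target false discovery rate for the BH flags.
#' @return Tibble: `list`, `a`, `b`, `c`, `d`, `fisher_p`, `p_adjusted`,
#'   `bh_flag`, `q`.
#' @export
test_phenotype_assoc <- function(probands, retained, lists, phenotype = "HTX",
                                 mode = "recessive", fdr = 0.1) {
  rows <- purrr::imap(lists, function(members, nm) {
    tab <- build_table(probands, retained, members, phenotype, mode)
    dplyr::mutate(tab, list = nm,
                  fisher_p = fisher_exact_two_sided(.data$a, .data$b, .data$c, .data$d),
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  bh <- bh_adjust(out$fisher_p, fdr)
  dplyr::mutate(out, p_adjusted = bh$p_adjusted, bh_flag = bh$significant, q = fdr) |>
    dplyr::relocate("list")
}
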