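#' Filter damaged-genotype calls
#'
#' Applies the damaging-genotype criteria to a call table: retain calls with a
#' per-gene burden-test p-value at or below `p_threshold`; drop all calls in
#' genes whose carrier fraction (distinct probands with a retained call in the
#' gene, over `n_probands`) reaches `par_threshold` (such genes reflect
#' systematic artifacts like incorrect read mapping); drop mucin and
#' olfactory-receptor family genes; drop recessive calls in which either
#' allele is a common polymorphism (`maf >= common_maf`). De novo and
#' recessive calls pass through identical scoring thresholds, so their
#' retained sets are directly comparable. The gene-level carrier-fraction
#' filter is computed across all modes.
#'
#' @param calls Call tibble with columns `proband_id`, `gene`, `mode`
#'   (`de_novo`, `recessive_hom`, `compound_het`), `vaast_p`, `af1`, `af2`,
#'   and optionally `gene_family_flag`; when the flag column is missing, genes
#'   whose symbols match `^MUC\\d` / `^OR\\d` are flagged.
#' @param p_threshold Burden-test p-value cutoff (retain `vaast_p <=`).
#' @param par_threshold Carrier-fraction cutoff (drop genes with fraction `>=`).
#' @param common_maf Common-polymorphism allele-frequency cutoff (drop `>=`).
#' @param n_probands Cohort size used for the carrier fraction.
#' @return Tibble of retained calls, with a `filter_log` attribute: a tibble
#'   (`row`, `proband_id`, `gene`, `reason`) of dropped rows. Retrieve it with
#'   [filter_log()].
#' @export
classify_damaged <- function(calls, p_threshold = 0.005, par_threshold = 0.005,
                             common_maf = 0.05, n_probands) {
  if (missing(n_probands) || n_probands <= 0) {
    ts_abort("n_probands must be positive", "validation_error")
  }
  validate_calls(calls)
  if (!"gene_family_flag" %in% names(calls)) {
    calls$gene_family_flag <- dplyr::case_when(
      grepl("^MUC\\d", calls$gene) ~ "mucin",
      grepl("^OR\\d", calls$gene) ~ "olfactory_receptor",
      TRUE ~ "none"
    )
  }
  reason <- rep(NA_character_, nrow(calls))
  is_rec <- calls$mode %in% c("recessive_hom", "compound_het")
  common <- is_rec & ((!is.na(calls$af1) & calls$af1 >= common_maf) |
                        (!is.na(calls$af2) & calls$af2 >= common_maf))
  reason[is.na(reason) & calls$vaast_p > p_threshold] <- "burden p above threshold"
  reason[is.na(reason) & calls$gene_family_flag != "none"] <- "excluded gene family"
  reason[is.na(reason) & common] <- "common polymorphism allele"

  # gene-level carrier-fraction (PAR) filter on the calls that survive so far
  keep <- is.na(reason)
  carrier_frac <- calls[keep, c("gene", "proband_id")] |>
    dplyr::distinct() |>
    dplyr::count(.data$gene, name = "carriers") |>
    dplyr::mutate(frac = .data$carriers / n_probands)
  bad_genes <- carrier_frac$gene[carrier_frac$frac >= par_threshold]
  reason[keep & calls$gene %in% bad_genes] <- "carrier fraction at or above PAR threshold"

  retained <- calls[is.na(reason), , drop = FALSE]
  log <- tibble::tibble(
    row = which(!is.na(reason)),
    proband_id = calls$proband_id[!is.na(reason)],
    gene = calls$gene[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  attr(retained, "filter_log") <- log
  retained
}

#' @rdname classify_damaged
#' @param retained A tibble returned by [classify_damaged()].
#' @export
filter_log <- function(retained) {
  attr(retained, "filter_log") %||%
    tibble::tibble(row = integer(), proband_id = character(),
                   gene = character(), reason = character())
}

validate_calls <- function(calls) {
  need <- c("proband_id", "gene", "mode", "vaast_p", "af1", "af2")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    ts_abort(paste("calls table missing columns:", paste(miss, collapse = ", ")),
             "validation_error")
  }
  bad_mode <- !calls$mode %in% c("de_novo", "recessive_hom", "compound_het")
  if (any(bad_mode)) {
    ts_abort(sprintf("invalid mode at row(s) %s",
                     paste(head(which(bad_mode)), collapse = ", ")),
             "validation_error")
  }
  bad_p <- !is.finite(calls$vaast_p) | calls$vaast_p <= 0 | calls$vaast_p > 1
  if (any(bad_p)) {
    ts_abort(sprintf("vaast_p must be in (0, 1]; bad row(s) %s",
                     paste(head(which(bad_p)), collapse = ", ")),
             "validation_error")
  }
  # af1/af2 may be NA for alleles absent from the population; the structural
  # rule is that only compound hets carry a second allele slot
  bad_comb <- calls$mode != "compound_het" & !is.na(calls$af2)
  if (any(bad_comb)) {
    ts_abort(sprintf("malformed mode/allele combination at row(s) %s",
                     paste(head(which(bad_comb)), collapse = ", ")),
             "validation_error")
  }
  invisible(calls)
}

#' Cohort population attributable risk for a gene list
#'
#' Percent of probands carrying at least one retained damaged genotype of the
#' given mode in a gene of the list.
#'
#' @param retained Retained-call tibble (see [classify_damaged()]).
#' @param members Character vector of list gene symbols.
#' @param mode `"recessive"` (pools homozygous and compound-het calls) or
#'   `"de_novo"`.
#' @param n_probands Cohort size.
#' @return Percent (0-100).
#' @export
cohort_par <- function(retained, members, mode = c("recessive", "de_novo"),
                       n_probands) {
  mode <- match.arg(mode)
  if (length(members) == 0) ts_abort("empty gene list", "validation_error")
  if (n_probands <= 0) ts_abort("n_probands must be positive", "validation_error")
  modes <- if (mode == "recessive") c("recessive_hom", "compound_het") else "de_novo"
  carriers <- unique(retained$proband_id[retained$mode %in% modes &
                                           retained$gene %in% members])
  100 * length(carriers) / n_probands
}

#' Per-gene population attributable risk
#'
#' Normalizes a cohort-level PAR percentage by gene-list size, enabling
#' comparison between lists of different sizes.
#'
#' @param cohort_par_percent Percent from [cohort_par()].
#' @param list_size Number of genes in the list.
#' @return Percent per gene.
#' @export
per_gene_par <- function(cohort_par_percent, list_size) {
  if (any(list_size <= 0)) ts_abort("list_size must be positive", "validation_error")
  cohort_par_percent / list_size
}

#' Expected population genotype frequency
#'
#' Expected frequency of a recessive genotype in the general population:
#' `q^2` for a simple recessive (homozygous) genotype, `2 q1 q2` for a
#' compound heterozygote in trans. Alleles absent from the population
#' reference are assigned the conservative floor frequency (1/100,000 by
#' default).
#'
#' @param calls Tibble of recessive-mode calls (`mode`, `af1`, `af2`).
#' @param absent_allele_floor Frequency assigned to missing alleles.
#' @return The input with columns `genotype_class` (`simple_recessive` or
#'   `compound_het`) and `expected_frequency` added.
#' @export
expected_genotype_frequency <- function(calls, absent_allele_floor = 1e-5) {
  if (any(calls$mode == "de_novo")) {
    ts_abort("expected genotype frequency is not applicable to de novo calls",
             "not_applicable")
  }
  q1 <- ifelse(is.na(calls$af1), absent_allele_floor, calls$af1)
  q2 <- ifelse(is.na(calls$af2), absent_allele_floor, calls$af2)
  dplyr::mutate(
    calls,
    genotype_class = ifelse(.data$mode == "compound_het",
                            "compound_het", "simple_recessive"),
    expected_frequency = ifelse(.data$mode == "compound_het", 2 * q1 * q2, q1^2)
  )
}

#' Summarize expected genotype frequencies
#'
#' Median expected population frequency per genotype class and the overall
#' fraction of genotypes expected in fewer than 1 in 100,000 individuals.
#'
#' @param retained_recessive Tibble of retained recessive-mode calls.
#' @param absent_allele_floor Passed to [expected_genotype_frequency()].
#' @return Tibble: `genotype_class`, `n`, `median_frequency`, plus attribute
#'   `fraction_below_1e5` (also returned as a `rare_fraction` column repeated
#'   per row for convenience).
#' @export
genotype_frequency_summary <- function(retained_recessive,
                                       absent_allele_floor = 1e-5) {
  if (nrow(retained_recessive) == 0) {
    ts_abort("need at least one recessive call", "validation_error")
  }
  freq <- expected_genotype_frequency(retained_recessive, absent_allele_floor)
  out <- freq |>
    dplyr::group_by(.data$genotype_class) |>
    dplyr::summarise(n = dplyr::n(),
                     median_frequency = median(.data$expected_frequency),
                     .groups = "drop") |>
    dplyr::mutate(rare_fraction = mean(freq$expected_frequency < 1e-5))
  attr(out, "fraction_below_1e5") <- mean(freq$expected_frequency < 1e-5)
  out
}
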