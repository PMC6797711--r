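#' Trio-level quality control
#'
#' Applies the trio QC filters to a proband metadata table, in a fixed order,
#' logging the first triggering reason per removed trio:
#' \enumerate{
#'   \item parent-offspring kinship below `unrelated_cutoff` (adoptions,
#'     sample swaps, non-paternity);
#'   \item any pairwise kinship above `excess_cutoff` (likely sample switch);
#'   \item syndromic probands (Down syndrome, DiGeorge, 22q micro-del/dup);
#'   \item more than `max_dn` exonic de novo mutations;
#'   \item fewer than `min_rec` recessive genotypes.
#' }
#' Parental kinship (`kin_mo_fa`) never triggers the unrelatedness filter —
#' parents are expected to be unrelated, and trios with first-cousin parents
#' (kinship near 0.0625-0.125) are retained.
#'
#' @param records Proband tibble with `proband_id`, `kin_mo_fa`, `kin_pb_mo`,
#'   `kin_pb_fa`, `n_dn_exonic`, `n_recessive`, `syndrome_flag`.
#' @param unrelated_cutoff Proband-parent kinship below this removes the trio.
#' @param excess_cutoff Any pairwise kinship above this removes the trio.
#' @param max_dn Maximum exonic de novo count (exclusive).
#' @param min_rec Minimum recessive genotype count (exclusive lower bound:
#'   trios with fewer than this are removed).
#' @return List: `kept` (tibble) and `removed` (tibble `proband_id`, `reason`).
#' @export
apply_trio_qc <- function(records, unrelated_cutoff = 0.0884,
                          excess_cutoff = 0.35, max_dn = 10, min_rec = 30) {
  need <- c("proband_id", "kin_mo_fa", "kin_pb_mo", "kin_pb_fa",
            "n_dn_exonic", "n_recessive", "syndrome_flag")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    ts_abort(paste("records missing columns:", paste(miss, collapse = ", ")),
             "validation_error")
  }
  bad <- !stats::complete.cases(records[, need])
  if (any(bad)) {
    ts_abort(sprintf("missing QC fields at row(s) %s",
                     paste(head(which(bad)), collapse = ", ")), "validation_error")
  }
  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  flag(records$kin_pb_mo < unrelated_cutoff | records$kin_pb_fa < unrelated_cutoff,
       "unrelated parent-offspring")
  flag(records$kin_pb_mo > excess_cutoff | records$kin_pb_fa > excess_cutoff |
         records$kin_mo_fa > excess_cutoff, "excess kinship")
  flag(records$syndrome_flag != "none", "syndromic proband")
  flag(records$n_dn_exonic > max_dn, "excess de novo")
  flag(records$n_recessive < min_rec, "too few recessive genotypes")
  list(
    kept = records[is.na(reason), , drop = FALSE],
    removed = tibble::tibble(proband_id = records$proband_id[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  )
}
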