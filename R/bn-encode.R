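#' Encode cohort features as discrete belief-network nodes
#'
#' Builds the discrete data matrix for the belief-network analyses: binary
#' genotype nodes `Recessive` and `DeNovo` (any retained call of that mode),
#' one binary damage indicator per supplied gene list (any retained call of
#' any mode in a list gene), composite nodes `R_Cilia` (recessive call in a
#' Cilia-list gene) and `D_Chromatin` (de novo call in a Chromatin-list gene)
#' when those lists are present, a 4-state `Phenotype` node (HTX / CTD / LVO /
#' OTH) and the multistate covariates `Gender`, `Ancestry`, `Capture`.
#' Binary nodes use factor levels `0` < `1` so state `"1"` is the positive
#' state.
#'
#' @param probands Proband metadata tibble (`proband_id`, `phenotype`, `sex`,
#'   `ancestry`, `capture`).
#' @param retained Retained-call tibble (see [classify_damaged()]).
#' @param lists Named list of character vectors of gene symbols.
#' @return Data frame of factors, one row per proband, ready for
#'   [learn_structure_exact()], [fit_cpts()] and [infer()].
#' @export
encode_features <- function(probands, retained, lists) {
  known <- c("CTD", "LVO", "HTX", "OTH")
  bad <- setdiff(unique(probands$phenotype), known)
  if (length(bad) > 0) {
    ts_abort(paste("unknown phenotype label(s):", paste(bad, collapse = ", ")),
             "validation_error")
  }
  ids <- probands$proband_id
  rec_modes <- c("recessive_hom", "compound_het")
  ind <- function(pids) factor(as.integer(ids %in% pids), levels = c(0, 1))

  out <- data.frame(row.names = seq_along(ids))
  out$Recessive <- ind(retained$proband_id[retained$mode %in% rec_modes])
  out$DeNovo <- ind(retained$proband_id[retained$mode == "de_novo"])
  for (nm in names(lists)) {
    out[[nm]] <- ind(retained$proband_id[retained$gene %in% lists[[nm]]])
  }
  if ("Cilia" %in% names(lists)) {
    out$R_Cilia <- ind(retained$proband_id[retained$mode %in% rec_modes &
                                             retained$gene %in% lists$Cilia])
  }
  if ("Chromatin" %in% names(lists)) {
    out$D_Chromatin <- ind(retained$proband_id[retained$mode == "de_novo" &
                                                 retained$gene %in% lists$Chromatin])
  }
  out$Phenotype <- factor(probands$phenotype, levels = known)
  out$Gender <- factor(probands$sex)
  out$Ancestry <- factor(probands$ancestry)
  out$Capture <- factor(probands$capture)
  out
}
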