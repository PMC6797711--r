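# fixtures built in code; all tests run from these, no data files

tiny_universe <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene = sprintf("T%04d", seq_len(n)),
    transcript_length = round(runif(n, 500, 9000)),
    rare_variant_count = runif(n, 5, 400),
    class = "background"
  )
}

make_calls <- function(proband_id, gene, mode = "de_novo", vaast_p = 0.001,
                       af1 = NA_real_, af2 = NA_real_,
                       gene_family_flag = "none") {
  tibble::tibble(proband_id = proband_id, gene = gene, mode = mode,
                 vaast_p = vaast_p, af1 = af1, af2 = af2,
                 gene_family_flag = gene_family_flag)
}

make_probands <- function(n, phenotype = "OTH", sex = "F", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    proband_id = sprintf("PB%05d", seq_len(n)),
    phenotype = rep_len(phenotype, n), sex = rep_len(sex, n),
    ancestry = "EUR", capture = "Agilent",
    kin_mo_fa = 0.01, kin_pb_mo = 0.25, kin_pb_fa = 0.25,
    n_dn_exonic = 1L, n_recessive = 60L, syndrome_flag = "none"
  )
}

# one default study shared across test files (generation is fast but not free)
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 20260101))
    cache
  }
})

null_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(
        seed = 20260102, enrichment_multipliers = null_multipliers(),
        htx_rr_given_recessive_cilia = 1, lvo_male_rr = 1))
    }
    cache
  }
})
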