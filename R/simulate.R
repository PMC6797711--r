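#' Simulation configuration for a synthetic CHD trio cohort
#'
#' Builds the full parameter set for the synthetic-data generator. Defaults
#' emulate the statistical structure of a large congenital heart disease (CHD)
#' trio study: a universe of 18,876 genes whose rare-variant burden grows with
#' transcript length at class-specific rates, five overlapping candidate gene
#' lists plus a housekeeping control list, 2391 probands in four phenotype
#' classes, per-proband damaged-genotype calls totalling about 3083 recessive
#' and 1351 de novo genotypes, planted per-list enrichment multipliers, a
#' heterotaxy phenotype conditionally dependent on recessive cilia genotypes,
#' and ancestry-by-capture confounding.
#'
#' @param seed Integer seed; fully determines all generator output via a
#'   hierarchical schedule (separate derived seeds for universe, lists, cohort).
#' @param n_genes Number of genes in the universe.
#' @param n_probands Number of probands (trios passing QC).
#' @param list_specs Tibble with columns `name`, `size`, `class`, `subset_of`
#'   (NA or the name of an earlier list to draw a subset from) and `overlaps`
#'   (list-column of tibbles `other`/`count` giving exact overlap quotas with
#'   earlier lists). Lists are otherwise pairwise disjoint.
#' @param mode_rates Named vector: expected damaged-call count per proband for
#'   `recessive` and `de_novo` modes.
#' @param enrichment_multipliers Tibble `list`/`mode`/`fold`: per-gene call-rate
#'   multiplier applied multiplicatively to member genes of each list for the
#'   given mode (`recessive` covers homozygous and compound-het calls). All
#'   folds must be >= 0; a fold of 1 is the null.
#' @param phenotype_mix Named probabilities over the four phenotype classes
#'   CTD, LVO, HTX, OTH (must sum to 1).
#' @param htx_rr_given_recessive_cilia Relative risk of the HTX phenotype for
#'   carriers of a damaged recessive cilia genotype (planted exactly as
#'   P(HTX|carrier)/P(HTX|non-carrier)).
#' @param lvo_male_rr Relative risk of the LVO phenotype for males, planted
#'   within the non-HTX probability mass.
#' @param ancestry_mix Named probabilities over ancestries.
#' @param capture_given_ancestry Row-stochastic matrix, rows = ancestries,
#'   columns = capture platforms: the planted confounding table.
#' @param burden_model Named list (one entry per gene class) of
#'   `list(intercept, slope, sdlog)`: expected burden ratio (rare variants per
#'   base) is `intercept + slope * transcript_length`, with multiplicative
#'   log-normal noise of scale `sdlog` (`sdlog = 0` is the exact linear model).
#' @param comphet_frac Fraction of recessive calls that are compound
#'   heterozygous.
#' @param af_absent_frac Fraction of recessive alleles absent from the
#'   population reference (frequency missing).
#' @param rec_af_range Log-uniform range for observed compound-het allele
#'   frequencies.
#' @param hom_af_range Log-uniform range for homozygous-recessive allele
#'   frequencies (higher than `rec_af_range`: rare homozygotes are only
#'   ascertained for relatively more common alleles).
#' @param length_meanlog,length_sdlog Log-normal parameters for transcript
#'   lengths (bases).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 18876L,
                       n_probands = 2391L,
                       list_specs = default_list_specs(),
                       mode_rates = c(recessive = 3083 / 2391, de_novo = 1351 / 2391),
                       enrichment_multipliers = default_multipliers(),
                       phenotype_mix = c(CTD = 0.30, LVO = 0.27, HTX = 0.10, OTH = 0.33),
                       htx_rr_given_recessive_cilia = 1.4,
                       lvo_male_rr = 1.4,
                       ancestry_mix = c(EUR = 0.65, AFR = 0.15, ASN = 0.10, OTH = 0.10),
                       capture_given_ancestry = default_capture_table(),
                       burden_model = default_burden_model(),
                       comphet_frac = 0.88,
                       af_absent_frac = 0.18,
                       rec_af_range = c(1e-5, 5e-3),
                       hom_af_range = c(2e-4, 5e-3),
                       length_meanlog = 7.9,
                       length_sdlog = 0.55) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_probands = as.integer(n_probands), list_specs = list_specs,
    mode_rates = mode_rates, enrichment_multipliers = enrichment_multipliers,
    phenotype_mix = phenotype_mix,
    htx_rr_given_recessive_cilia = htx_rr_given_recessive_cilia,
    lvo_male_rr = lvo_male_rr, ancestry_mix = ancestry_mix,
    capture_given_ancestry = capture_given_ancestry,
    burden_model = burden_model, comphet_frac = comphet_frac,
    af_absent_frac = af_absent_frac, rec_af_range = rec_af_range,
    hom_af_range = hom_af_range,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_list_specs <- function() {
  tibble::tibble(
    name = c("Cilia", "SysCilia", "FoxJ1", "Chromatin", "CHD", "Housekeeping"),
    size = c(669L, 302L, 116L, 163L, 402L, 669L),
    class = c("cilia", "cilia", "foxj1", "chromatin", "chd", "housekeeping"),
    subset_of = c(NA, "Cilia", NA, NA, NA, NA),
    overlaps = list(
      NULL, NULL, NULL,
      tibble::tibble(other = "Cilia", count = 5L),
      tibble::tibble(other = c("Cilia", "Chromatin"), count = c(0L, 35L)),
      NULL
    )
  )
}

#' @rdname sim_config
#' @export
default_multipliers <- function() {
  tibble::tribble(
    ~list,          ~mode,       ~fold,
    "Cilia",        "recessive", 2.5,
    "SysCilia",     "recessive", 1.4,
    "Cilia",        "de_novo",   1.3,
    "FoxJ1",        "recessive", 1.5,
    "Chromatin",    "de_novo",   4.0,
    "Chromatin",    "recessive", 1.5,
    "CHD",          "de_novo",   2.5,
    "CHD",          "recessive", 1.3,
    "Housekeeping", "recessive", 0.4
  )
}

#' @rdname sim_config
#' @export
null_multipliers <- function() {
  tibble::tibble(list = character(), mode = character(), fold = numeric())
}

#' @rdname sim_config
#' @export
default_capture_table <- function() {
  m <- rbind(
    EUR = c(Agilent = 0.44, NimbleGen = 0.35, xGEN_IDT = 0.21),
    AFR = c(Agilent = 0.25, NimbleGen = 0.25, xGEN_IDT = 0.50),
    ASN = c(Agilent = 0.44, NimbleGen = 0.35, xGEN_IDT = 0.21),
    OTH = c(Agilent = 0.44, NimbleGen = 0.35, xGEN_IDT = 0.21)
  )
  m
}

#' @rdname sim_config
#' @export
default_burden_model <- function() {
  list(
    background   = list(intercept = 0.030, slope = 3.0e-6, sdlog = 0.45),
    cilia        = list(intercept = 0.035, slope = 8.0e-6, sdlog = 0.45),
    foxj1        = list(intercept = 0.035, slope = 7.0e-6, sdlog = 0.45),
    chromatin    = list(intercept = 0.030, slope = 3.5e-6, sdlog = 0.45),
    chd          = list(intercept = 0.030, slope = 3.5e-6, sdlog = 0.45),
    housekeeping = list(intercept = 0.015, slope = 1.5e-6, sdlog = 0.45)
  )
}

validate_sim_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      ts_abort(sprintf("%s must be non-negative and sum to 1", what), "config_error")
    }
  }
  check_probs(cfg$phenotype_mix, "phenotype_mix")
  check_probs(cfg$ancestry_mix, "ancestry_mix")
  apply(cfg$capture_given_ancestry, 1, check_probs, what = "capture_given_ancestry rows")
  if (any(cfg$enrichment_multipliers$fold < 0)) {
    ts_abort("enrichment multipliers must be >= 0", "config_error")
  }
  if (cfg$htx_rr_given_recessive_cilia < 0 || cfg$lvo_male_rr < 0) {
    ts_abort("relative risks must be >= 0", "config_error")
  }
  if (any(cfg$list_specs$size > cfg$n_genes)) {
    ts_abort("list sizes must not exceed n_genes", "config_error")
  }
  if (any(cfg$mode_rates < 0)) ts_abort("mode_rates must be >= 0", "config_error")
  invisible(cfg)
}

# hierarchical seed schedule: universe / lists / cohort get independent streams
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Generate a synthetic gene universe
#'
#' Draws `n_genes` genes with log-normal transcript lengths and rare-variant
#' counts following a class-specific linear burden model: the expected burden
#' ratio (rare variants per base) of a gene of class `c` and length `L` is
#' `intercept_c + slope_c * L`, perturbed by mean-one log-normal noise.
#' Housekeeping-class genes get systematically lower burden under the default
#' model. Counts are expected counts and may be non-integer; with `sdlog = 0`
#' the linear model holds exactly. A small set of background genes is named
#' with `MUC`/`OR` prefixes to stand in for the mucin and olfactory-receptor
#' gene families excluded by the damaged-genotype filter.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `gene`, `transcript_length`,
#'   `rare_variant_count`, `class`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (bm in config$burden_model) {
    if (bm$intercept < 0 || bm$slope < 0) {
      ts_abort("burden model implies negative expected counts", "config_error")
    }
  }
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes

  symbols <- sprintf("G%05d", seq_len(n))
  # allocate burden classes; lists are later drawn from matching class pools
  specs <- config$list_specs
  quota <- integer(0)
  for (i in seq_len(nrow(specs))) {
    if (!is.na(specs$subset_of[i])) next
    need <- specs$size[i] - sum(specs$overlaps[[i]]$count %||% 0L)
    prev <- quota[specs$class[i]]
    quota[specs$class[i]] <- need + if (is.na(prev)) 0L else prev
  }
  quota <- quota[names(quota) != "background"]
  if (sum(quota) > n) ts_abort("class quotas exceed n_genes", "config_error")
  class <- rep("background", n)
  idx <- sample.int(n, sum(quota))
  class[idx] <- rep(names(quota), quota)

  # name a few background genes after excluded gene families
  bg <- which(class == "background")
  fam <- sample(bg, 60L)
  symbols[fam[1:30]] <- sprintf("MUC%d", 1:30)
  symbols[fam[31:60]] <- sprintf("OR%dA1", 1:30)

  len <- round(rlnorm(n, config$length_meanlog, config$length_sdlog)) + 200
  bm <- config$burden_model
  miss <- setdiff(unique(class), names(bm))
  if (length(miss) > 0) {
    ts_abort(paste("burden model missing classes:", paste(miss, collapse = ", ")),
             "config_error")
  }
  intercept <- vapply(class, function(cl) bm[[cl]]$intercept, numeric(1),
                      USE.NAMES = FALSE)
  slope <- vapply(class, function(cl) bm[[cl]]$slope, numeric(1),
                  USE.NAMES = FALSE)
  sdlog <- vapply(class, function(cl) bm[[cl]]$sdlog, numeric(1),
                  USE.NAMES = FALSE)
  ratio <- (intercept + slope * len) * exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
  tibble::tibble(
    gene = symbols,
    transcript_length = as.numeric(len),
    rare_variant_count = ratio * len,
    class = class
  )
}

#' Generate overlapping candidate gene lists
#'
#' Samples the configured gene lists from the universe. Each list draws its
#' exact overlap quotas from earlier lists (a `count` of 0 enforces an empty
#' intersection), takes the remainder from unused genes of its own burden
#' class, and subset lists (`subset_of`) are drawn entirely from their parent.
#' Under the defaults: SysCilia (302) is a subset of Cilia (669), the Chromatin
#' list (163) shares exactly 5 genes with Cilia, the CHD list (402) shares none
#' with Cilia and 35 with Chromatin, and the housekeeping control list is
#' disjoint from all candidate lists.
#'
#' @param config A [sim_config()].
#' @param universe Tibble from [generate_universe()].
#' @return Named list of character vectors of gene symbols.
#' @export
generate_gene_lists <- function(config, universe) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  specs <- config$list_specs
  lists <- list()
  used <- character(0)
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    size <- specs$size[i]
    if (!is.na(specs$subset_of[i])) {
      parent <- lists[[specs$subset_of[i]]]
      if (is.null(parent) || length(parent) < size) {
        ts_abort(sprintf("list '%s': infeasible subset constraint", nm), "config_error")
      }
      lists[[nm]] <- sort(sample(parent, size))
      next
    }
    chosen <- character(0)
    ov <- specs$overlaps[[i]]
    # genes of lists with an explicit zero quota are banned from every pool
    banned <- character(0)
    if (!is.null(ov) && any(ov$count == 0)) {
      banned <- unique(unlist(lists[ov$other[ov$count == 0]]))
    }
    if (!is.null(ov)) {
      for (j in seq_len(nrow(ov))) {
        if (ov$count[j] == 0) next
        pool <- setdiff(lists[[ov$other[j]]], c(chosen, banned))
        if (length(pool) < ov$count[j]) {
          ts_abort(sprintf("list '%s': infeasible overlap with '%s'", nm, ov$other[j]),
                   "config_error")
        }
        chosen <- c(chosen, sample(pool, ov$count[j]))
      }
    }
    pool <- setdiff(universe$gene[universe$class == specs$class[i]], c(used, banned))
    need <- size - length(chosen)
    if (length(pool) < need) {
      ts_abort(sprintf("list '%s': class pool too small", nm), "config_error")
    }
    members <- c(chosen, sample(pool, need))
    lists[[nm]] <- sort(members)
    used <- union(used, members)
  }
  lists
}

#' Generate a synthetic proband cohort with damaged-genotype calls
#'
#' Samples proband metadata (phenotype class, sex, ancestry, capture platform
#' with the configured ancestry-by-capture confounding, trio kinship estimates
#' and per-trio variant counts), then damaged-genotype calls per inheritance
#' mode. Call counts per proband are Poisson with the configured per-mode
#' rates; the gene of each call is drawn with probability proportional to the
#' product of the enrichment multipliers of the lists containing it (all-ones
#' multipliers give an exchangeable null). Recessive calls are compound
#' heterozygous with probability `comphet_frac` and carry log-uniform allele
#' frequencies with a configurable fraction absent from the population; de novo
#' calls carry no population allele frequency. Every call carries a burden-test
#' p-value <= 0.005. The heterotaxy phenotype probability is raised exactly
#' `htx_rr_given_recessive_cilia`-fold for carriers of a recessive cilia
#' genotype, and the LVO probability `lvo_male_rr`-fold for males within the
#' non-HTX mass, so both planted relative risks are exact conditional ratios.
#'
#' @param config A [sim_config()].
#' @param universe Tibble from [generate_universe()].
#' @param lists Named list from [generate_gene_lists()].
#' @return List with elements `probands` (tibble), `calls` (tibble), and
#'   `truth` (ground-truth record: planted multipliers, per-proband carrier
#'   status, planted relative risks, and the generative dependency graph).
#' @export
generate_cohort <- function(config, universe, lists) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_probands
  ids <- sprintf("PB%05d", seq_len(n))

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
  ancestry <- sample(names(config$ancestry_mix), n, replace = TRUE,
                     prob = config$ancestry_mix)
  cap_tab <- config$capture_given_ancestry
  capture <- vapply(ancestry, function(a) {
    sample(colnames(cap_tab), 1L, prob = cap_tab[a, ])
  }, character(1))

  kin_mo_fa <- pmax(0, rnorm(n, 0, 0.008))
  # a few first-cousin parent pairs are planted (and must survive QC)
  kin_mo_fa[sample.int(n, min(4L, n))] <- 0.09
  kin_pb_mo <- pmin(0.33, pmax(0.17, rnorm(n, 0.25, 0.02)))
  kin_pb_fa <- pmin(0.33, pmax(0.17, rnorm(n, 0.25, 0.02)))
  n_dn_exonic <- pmin(10L, rpois(n, 1.3))
  n_recessive <- 35L + rpois(n, 30)

  calls <- sample_calls(config, universe, lists, ids)

  cilia_genes <- lists[["Cilia"]] %||% character(0)
  rec_cilia_carrier <- ids %in% calls$proband_id[
    calls$mode %in% c("recessive_hom", "compound_het") & calls$gene %in% cilia_genes
  ]

  phenotype <- sample_phenotype(config, rec_cilia_carrier, sex)

  probands <- tibble::tibble(
    proband_id = ids, phenotype = phenotype, sex = sex, ancestry = ancestry,
    capture = capture, kin_mo_fa = kin_mo_fa, kin_pb_mo = kin_pb_mo,
    kin_pb_fa = kin_pb_fa, n_dn_exonic = n_dn_exonic,
    n_recessive = n_recessive, syndrome_flag = "none"
  )

  truth <- list(
    multipliers = config$enrichment_multipliers,
    mode_rates = config$mode_rates,
    rec_cilia_carrier = tibble::tibble(proband_id = ids,
                                       rec_cilia_carrier = rec_cilia_carrier),
    htx_rr = config$htx_rr_given_recessive_cilia,
    lvo_male_rr = config$lvo_male_rr,
    phenotype_mix = config$phenotype_mix,
    dependency_graph = list(
      Phenotype = c("RecessiveCiliaCarrier", "Sex"),
      Capture = "Ancestry"
    )
  )
  list(probands = probands, calls = calls, truth = truth)
}

sample_calls <- function(config, universe, lists, ids) {
  n <- length(ids)
  genes <- universe$gene
  out <- list()
  for (mode in c("recessive", "de_novo")) {
    w <- rep(1, length(genes))
    mult <- config$enrichment_multipliers
    mult <- mult[mult$mode == mode, , drop = FALSE]
    if (nrow(mult) > 0) {
      for (j in seq_len(nrow(mult))) {
        hit <- genes %in% (lists[[mult$list[j]]] %||% character(0))
        w[hit] <- w[hit] * mult$fold[j]
      }
    }
    k <- rpois(n, config$mode_rates[[mode]])
    total <- sum(k)
    if (total == 0) next
    g <- sample(genes, total, replace = TRUE, prob = w)
    pid <- rep(ids, k)
    tab <- tibble::tibble(proband_id = pid, gene = g)
    tab <- dplyr::distinct(tab)
    m <- nrow(tab)
    if (mode == "recessive") {
      comphet <- runif(m) < config$comphet_frac
      tab$mode <- ifelse(comphet, "compound_het", "recessive_hom")
      # homozygotes are only ascertained for relatively more common alleles;
      # compound hets can pair two ultra-rare (often population-absent) ones
      af_ch <- draw_af(m, config$rec_af_range, config$af_absent_frac)
      af_hom <- draw_af(m, config$hom_af_range, 0.02)
      tab$af1 <- ifelse(comphet, af_ch, af_hom)
      tab$af2 <- ifelse(comphet, draw_af(m, config$rec_af_range,
                                         config$af_absent_frac), NA_real_)
    } else {
      tab$mode <- "de_novo"
      tab$af1 <- NA_real_
      tab$af2 <- NA_real_
    }
    tab$vaast_p <- 10^runif(m, log10(1e-6), log10(0.005))
    out[[mode]] <- tab
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    return(tibble::tibble(proband_id = character(), gene = character(),
                          mode = character(), vaast_p = numeric(),
                          af1 = numeric(), af2 = numeric(),
                          gene_family_flag = character()))
  }
  calls$gene_family_flag <- dplyr::case_when(
    grepl("^MUC", calls$gene) ~ "mucin",
    grepl("^OR\\d", calls$gene) ~ "olfactory_receptor",
    TRUE ~ "none"
  )
  calls <- dplyr::arrange(calls, .data$proband_id, .data$mode, .data$gene)
  dplyr::select(calls, "proband_id", "gene", "mode", "vaast_p", "af1", "af2",
                "gene_family_flag")
}

draw_af <- function(m, range, absent_frac) {
  af <- 10^runif(m, log10(range[1]), log10(range[2]))
  af[runif(m) < absent_frac] <- NA_real_
  af
}

# phenotype sampling: HTX relative risk planted exactly for recessive cilia
# carriers, then the male LVO ratio applied within the remaining mass
sample_phenotype <- function(config, carrier, male_or_sex) {
  male <- if (is.logical(male_or_sex)) male_or_sex else male_or_sex == "M"
  base <- config$phenotype_mix[c("CTD", "LVO", "HTX", "OTH")]
  r <- config$htx_rr_given_recessive_cilia
  l <- config$lvo_male_rr
  n <- length(carrier)
  vapply(seq_len(n), function(i) {
    p <- base
    if (carrier[i]) {
      htx <- min(r * p[["HTX"]], 0.95)
      scale <- (1 - htx) / (1 - p[["HTX"]])
      p <- c(CTD = p[["CTD"]] * scale, LVO = p[["LVO"]] * scale,
             HTX = htx, OTH = p[["OTH"]] * scale)
    }
    if (male[i]) {
      lvo <- min(l * p[["LVO"]], 0.95 - p[["HTX"]])
      rest <- (1 - p[["HTX"]] - lvo) / (1 - p[["HTX"]] - p[["LVO"]])
      p <- c(CTD = p[["CTD"]] * rest, LVO = lvo, HTX = p[["HTX"]],
             OTH = p[["OTH"]] * rest)
    }
    sample(names(p), 1L, prob = p)
  }, character(1))
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: universe, gene lists and cohort from one config.
#'
#' @param config A [sim_config()].
#' @return List with `universe`, `lists`, `probands`, `calls`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  universe <- generate_universe(config)
  lists <- generate_gene_lists(config, universe)
  cohort <- generate_cohort(config, universe, lists)
  c(list(universe = universe, lists = lists), cohort)
}
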