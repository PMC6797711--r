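test_that("damaging-genotype thresholds retain and drop the right calls", {
  calls <- dplyr::bind_rows(
    make_calls("P1", "GENE1", "de_novo", vaast_p = 0.004),
    make_calls("P2", "GENE2", "de_novo", vaast_p = 0.006),
    make_calls("P3", "GENE3", "recessive_hom", vaast_p = 0.001, af1 = 0.06),
    make_calls("P4", "GENE4", "compound_het", vaast_p = 0.001,
               af1 = 0.001, af2 = 0.06),
    make_calls("P5", "GENE5", "recessive_hom", vaast_p = 0.001, af1 = 0.001),
    make_calls("P6", "MUC1", "de_novo", vaast_p = 0.001,
               gene_family_flag = "mucin"),
    make_calls("P7", "OR1A1", "de_novo", vaast_p = 0.001,
               gene_family_flag = "olfactory_receptor")
  )
  ret <- classify_damaged(calls, n_probands = 2391)
  expect_setequal(ret$gene, c("GENE1", "GENE5"))
  log <- filter_log(ret)
  expect_equal(nrow(log), 5)
  expect_setequal(log$reason[log$gene %in% c("GENE3", "GENE4")],
                  "common polymorphism allele")
  expect_equal(log$reason[log$gene == "GENE2"], "burden p above threshold")
  expect_setequal(log$reason[log$gene %in% c("MUC1", "OR1A1")],
                  "excluded gene family")
})

test_that("the carrier-fraction (PAR) filter drops over-called genes", {
  # 13 of 2391 probands -> fraction 0.00544 >= 0.005: the whole gene goes
  calls <- dplyr::bind_rows(
    make_calls(sprintf("P%03d", 1:13), "HOTGENE", "de_novo"),
    make_calls("P900", "OKGENE", "de_novo")
  )
  ret <- classify_damaged(calls, n_probands = 2391)
  expect_identical(unique(ret$gene), "OKGENE")
  expect_true(all(filter_log(ret)$reason[filter_log(ret)$gene == "HOTGENE"] ==
                    "carrier fraction at or above PAR threshold"))
  # 11 carriers (0.0046) stay
  calls2 <- make_calls(sprintf("P%03d", 1:11), "HOTGENE", "de_novo")
  expect_equal(nrow(classify_damaged(calls2, n_probands = 2391)), 11)
})

test_that("filtering is idempotent and monotone in its thresholds", {
  s <- default_study()
  strip <- function(x) { attr(x, "filter_log") <- NULL; as.data.frame(x) }
  ret1 <- classify_damaged(s$calls, n_probands = 2391)
  ret2 <- classify_damaged(ret1, n_probands = 2391)
  expect_equal(strip(ret1), strip(ret2))

  set.seed(31)
  calls <- make_calls(sprintf("P%03d", sample(300, 400, replace = TRUE)),
                      gene = sprintf("G%02d", sample(60, 400, replace = TRUE)),
                      mode = sample(c("de_novo", "recessive_hom"), 400, TRUE),
                      vaast_p = 10^runif(400, -5, 0))
  calls$af1 <- ifelse(calls$mode == "recessive_hom", 10^runif(400, -5, -0.5), NA)
  n_ret <- function(p = 0.005, par = 0.005, maf = 0.05) {
    nrow(classify_damaged(calls, p_threshold = p, par_threshold = par,
                          common_maf = maf, n_probands = 300))
  }
  # each threshold is monotone on its own (the carrier-fraction filter is held
  # open when varying the row-level thresholds: admitting more calls can
  # otherwise push a gene over the carrier-fraction cutoff by design)
  expect_gte(n_ret(par = 0.02), n_ret())
  expect_gte(n_ret(par = 1.1), n_ret(par = 0.02))
  expect_gte(n_ret(maf = 0.5, par = 1.1), n_ret(maf = 0.05, par = 1.1))
  expect_gte(n_ret(p = 0.05, par = 1.1), n_ret(p = 0.005, par = 1.1))
})

test_that("malformed rows raise row-level validation errors", {
  bad <- make_calls("P1", "G1", "weird_mode")
  expect_error(classify_damaged(bad, n_probands = 10),
               class = "trioscape_validation_error")
  bad2 <- make_calls("P1", "G1", "de_novo", af2 = 0.001)
  expect_error(classify_damaged(bad2, n_probands = 10),
               class = "trioscape_validation_error")
  expect_error(classify_damaged(make_calls("P1", "G1", vaast_p = 0)),
               class = "trioscape_validation_error")
})

test_that("cohort and per-gene PAR reproduce the printed arithmetic", {
  calls <- make_calls(sprintf("P%04d", 1:213), "CILGENE1", "compound_het",
                      af1 = 1e-4, af2 = 1e-4)
  par_rec <- cohort_par(calls, "CILGENE1", "recessive", n_probands = 2391)
  expect_equal(round(par_rec, 1), 8.9)
  expect_equal(round(per_gene_par(par_rec, 669), 3), 0.013)

  calls_dn <- make_calls(sprintf("P%04d", 1:76), "CHRGENE1", "de_novo")
  par_dn <- cohort_par(calls_dn, "CHRGENE1", "de_novo", n_probands = 2391)
  expect_equal(round(par_dn, 1), 3.2)
  expect_equal(round(per_gene_par(par_dn, 163), 3), 0.020)

  expect_equal(cohort_par(calls_dn, "OTHERGENE", "de_novo", n_probands = 2391), 0)
  expect_equal(per_gene_par(5.5, 1), 5.5)
  expect_error(cohort_par(calls, character(0), "recessive", 10),
               class = "trioscape_validation_error")
})

test_that("expected genotype frequency follows q^2 / 2q1q2 with the floor", {
  calls <- dplyr::bind_rows(
    make_calls("P1", "G1", "recessive_hom", af1 = 0.003),
    make_calls("P2", "G2", "compound_het", af1 = 0.001, af2 = 0.002),
    make_calls("P3", "G3", "recessive_hom", af1 = NA_real_)
  )
  f <- expected_genotype_frequency(calls)
  expect_equal(f$expected_frequency, c(9e-6, 4e-6, 1e-10))
  expect_equal(f$genotype_class,
               c("simple_recessive", "compound_het", "simple_recessive"))
  # symmetry in the two alleles
  swapped <- make_calls("P2", "G2", "compound_het", af1 = 0.002, af2 = 0.001)
  expect_equal(expected_genotype_frequency(swapped)$expected_frequency, 4e-6)
  expect_error(expected_genotype_frequency(make_calls("P1", "G1", "de_novo")),
               class = "trioscape_not_applicable")
})

test_that("genotype frequency summary matches a sort-based median oracle", {
  one <- make_calls("P1", "G1", "recessive_hom", af1 = 0.002)
  s1 <- genotype_frequency_summary(one)
  expect_equal(s1$median_frequency, 4e-6)

  s <- default_study()
  rec <- s$calls[s$calls$mode != "de_novo", ]
  summ <- genotype_frequency_summary(rec)
  freqs <- expected_genotype_frequency(rec)
  med_oracle <- function(x) { # midpoint of sorted values
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  for (cl in unique(summ$genotype_class)) {
    expect_equal(summ$median_frequency[summ$genotype_class == cl],
                 med_oracle(freqs$expected_frequency[freqs$genotype_class == cl]))
  }
  # on the generator's log-uniform allele range, compound hets are rarer
  expect_lt(summ$median_frequency[summ$genotype_class == "compound_het"],
            summ$median_frequency[summ$genotype_class == "simple_recessive"])
  expect_gte(attr(summ, "fraction_below_1e5"), 0)
})
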