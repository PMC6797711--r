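test_that("feature encoding produces the documented nodes and marginals", {
  probands <- make_probands(3, phenotype = c("HTX", "CTD", "LVO"),
                            sex = c("M", "F", "F"))
  lists <- list(Cilia = c("CIL1", "CIL2"), Chromatin = c("CHR1"))
  calls <- make_calls("PB00001", "CIL1", "compound_het", af1 = 1e-3, af2 = 1e-4)
  x <- encode_features(probands, calls, lists)
  expect_setequal(names(x), c("Recessive", "DeNovo", "Cilia", "Chromatin",
                              "R_Cilia", "D_Chromatin", "Phenotype", "Gender",
                              "Ancestry", "Capture"))
  expect_equal(as.character(x$Recessive), c("1", "0", "0"))
  expect_equal(as.character(x$DeNovo), c("0", "0", "0"))
  expect_equal(as.character(x$Cilia), c("1", "0", "0"))
  expect_equal(as.character(x$R_Cilia), c("1", "0", "0"))
  expect_equal(as.character(x$D_Chromatin), c("0", "0", "0"))

  # empty call table -> all genotype nodes zero
  x0 <- encode_features(probands, make_calls(character(0), character(0)), lists)
  expect_true(all(x0$Recessive == "0" & x0$DeNovo == "0" & x0$Cilia == "0"))

  bad <- probands
  bad$phenotype[1] <- "ASD"
  expect_error(encode_features(bad, calls, lists),
               class = "trioscape_validation_error")

  # marginals match direct recounts on the synthetic cohort
  s <- default_study()
  ret <- classify_damaged(s$calls, n_probands = 2391)
  xc <- encode_features(s$probands, ret, s$lists["Cilia"])
  rec_ids <- unique(ret$proband_id[ret$mode != "de_novo"])
  expect_equal(sum(xc$Recessive == "1"),
               sum(s$probands$proband_id %in% rec_ids))
  rc_ids <- unique(ret$proband_id[ret$mode != "de_novo" &
                                    ret$gene %in% s$lists$Cilia])
  expect_equal(sum(xc$R_Cilia == "1"), sum(s$probands$proband_id %in% rc_ids))
})

test_that("family scores equal a count-and-log oracle and penalize noise parents", {
  set.seed(3)
  df <- data.frame(
    A = factor(sample(0:1, 400, TRUE)),
    B = factor(sample(0:2, 400, TRUE)),
    C = factor(sample(0:1, 400, TRUE))
  )
  for (ps in list(character(0), "A", c("A", "B"))) {
    fs <- family_score("C", ps, df)
    o <- family_score_oracle("C", ps, df)
    expect_equal(fs$logL, o$logL, tolerance = 1e-10)
    expect_equal(fs$k, o$k)
  }
  # deterministic copy: conditional likelihood 1, logL contribution 0
  df$D <- df$A
  expect_equal(family_score("D", "A", df)$logL, 0)
  # independent parent: logL gain below the AIC parameter penalty
  s0 <- family_score("C", character(0), df)
  s1 <- family_score("C", "A", df)
  expect_lt(s1$logL - s1$k, s0$logL - s0$k)
  expect_error(family_score("A", "A", df), class = "trioscape_validation_error")
})

test_that("exact search finds the empty graph for independent nodes", {
  set.seed(10)
  df <- data.frame(A = factor(sample(0:1, 5000, TRUE)),
                   B = factor(sample(0:1, 5000, TRUE)))
  m <- learn_structure_exact(df)
  expect_equal(sum(lengths(m$parents)), 0)
})

test_that("exact search recovers the chain's Markov equivalence class", {
  set.seed(11)
  n <- 5000
  A <- rbinom(n, 1, 0.5)
  B <- ifelse(rbinom(n, 1, 0.9) == 1, A, 1 - A)
  C <- ifelse(rbinom(n, 1, 0.9) == 1, B, 1 - B)
  df <- data.frame(A = factor(A), B = factor(B), C = factor(C))
  m <- learn_structure_exact(df)
  skel <- tidy(m)
  und <- sort(paste(pmin(skel$from, skel$to), pmax(skel$from, skel$to), sep = "~"))
  expect_equal(und, c("A~B", "B~C"))
  # no v-structure A -> B <- C (that would leave the equivalence class)
  expect_false(setequal(m$parents$B, c("A", "C")))
})

test_that("exact search equals exhaustive enumeration over all 4-node DAGs", {
  dags <- enumerate_dags(c("A", "B", "C", "D"))
  expect_length(dags, 543)
  for (k in 1:5) {
    set.seed(200 + k)
    n <- 150
    A <- rbinom(n, 1, 0.5)
    B <- rbinom(n, 1, 0.3 + 0.4 * A)
    C <- rbinom(n, 1, runif(1))
    D <- rbinom(n, 1, 0.2 + 0.3 * B + 0.3 * C)
    df <- data.frame(A = factor(A), B = factor(B), C = factor(C), D = factor(D))
    m <- learn_structure_exact(df)
    got <- -m$aic / 2 # logL - k
    best <- max(vapply(dags, dag_score_oracle, numeric(1), data = df))
    expect_equal(got, best, tolerance = 1e-8)
  }
  big <- as.data.frame(lapply(1:15, function(i) factor(rbinom(20, 1, 0.5))))
  expect_error(learn_structure_exact(big), class = "trioscape_capacity_error")
})

test_that("CPT fitting gives exact frequencies, uniform fallbacks and recovery", {
  df <- data.frame(A = factor(c(0, 0, 1, 1, 1)), B = factor(c(0, 1, 1, 1, 0)))
  m <- fit_cpts(list(B = "A"), df, pseudocount = 0)
  expect_equal(unname(c(m$cpts$A)), c(2 / 5, 3 / 5))
  expect_equal(unname(m$cpts$B[, "0"]), c(1 / 2, 1 / 2))
  expect_equal(unname(m$cpts$B[, "1"]), c(1 / 3, 2 / 3))
  expect_equal(m$k, 1 + 2)
  expect_error(fit_cpts(list(A = "B", B = "A"), df),
               class = "trioscape_validation_error") # cycle

  # zero-support parent configuration -> uniform row
  df2 <- data.frame(A = factor(c(0, 0), levels = c(0, 1)),
                    B = factor(c(0, 1), levels = c(0, 1)))
  m2 <- fit_cpts(list(B = "A"), df2)
  expect_equal(unname(m2$cpts$B[, "1"]), c(0.5, 0.5))

  # refitting data sampled from known CPTs recovers entries within 0.02
  truth <- fit_cpts(list(B = "A", C = "B"),
                    data.frame(A = factor(c(0, 1)), B = factor(c(0, 1)),
                               C = factor(c(0, 1))), pseudocount = 1)
  sampled <- sample_bn(truth, 50000, seed = 5)
  refit <- fit_cpts(truth$parents, sampled, pseudocount = 0)
  for (v in c("A", "B", "C")) {
    expect_lt(max(abs(refit$cpts[[v]] - truth$cpts[[v]])), 0.02)
  }
})

test_that("variable-elimination inference equals joint enumeration", {
  for (k in 1:5) {
    bn <- random_bn(6, seed = 300 + k)
    nms <- bn$nodes$name
    # marginal sums to one
    marg <- infer(bn, nms[3])
    expect_equal(sum(marg), 1, tolerance = 1e-12)
    expect_equal(unname(marg), joint_infer_oracle(bn, nms[3]), tolerance = 1e-10)
    # random evidence including a negated state
    ev <- setNames(list(1L, bn_not(1L)), sample(nms[-3], 2))
    expect_equal(unname(infer(bn, nms[3], ev)),
                 joint_infer_oracle(bn, nms[3], ev), tolerance = 1e-10)
  }
  # full assignment -> indicator
  bn <- random_bn(4, seed = 9)
  nms <- bn$nodes$name
  ev <- setNames(as.list(rep(1L, 3)), nms[1:3])
  post <- infer(bn, nms[4], c(ev, setNames(list(2L), nms[4])))
  expect_equal(unname(post), c(0, 1, rep(0, length(post) - 2))[seq_along(post)])

  # zero-probability evidence
  df <- data.frame(A = factor(c(0, 0, 1, 1)), B = factor(c(0, 0, 1, 1)))
  m <- fit_cpts(list(B = "A"), df)
  expect_error(infer(m, "A", list(A = "0", B = "1")),
               class = "trioscape_undefined_conditional")
})

test_that("risk ratios follow constructed CPTs and recover the planted HTX risk", {
  df <- data.frame(D = factor(c(0, 1)), C = factor(c(0, 1)))
  m <- fit_cpts(list(C = "D"), df)
  m$cpts$D <- array(c(0.5, 0.5), dim = 2, dimnames = list(c("0", "1")))
  m$cpts$C <- array(c(0.9, 0.1, 0.7, 0.3), dim = c(2, 2),
                    dimnames = list(c("0", "1"), c("0", "1")))
  # P(C=1) = 0.2, P(C=1|D=1) = 0.3
  expect_equal(risk_ratio(m, "C", "1", list(D = "1")), 1.5, tolerance = 1e-12)
  expect_equal(risk_ratio(m, "C", "1", list(D = "1"), list(D = "1")), 1)

  # planted heterotaxy relative risk recovered from a fitted net at n = 2391
  cfg <- sim_config(seed = 13, htx_rr_given_recessive_cilia = 2)
  s <- simulate_study(cfg)
  ret <- classify_damaged(s$calls, n_probands = 2391)
  x <- encode_features(s$probands, ret, s$lists["Cilia"])
  m2 <- fit_cpts(list(Phenotype = c("R_Cilia", "Gender")),
                 x[, c("R_Cilia", "Gender", "Phenotype")])
  rr <- risk_ratio(m2, "Phenotype", "HTX", list(R_Cilia = "1"), list(R_Cilia = "0"))
  expect_lt(abs(rr - 2) / 2, 0.35) # single-cohort Monte-Carlo noise
})

test_that("dependency ratios match direct count arithmetic", {
  set.seed(15)
  x <- factor(rbinom(2000, 1, 0.4))
  df <- data.frame(X = x, Y = x)
  dr <- dependency_ratio(df, "X", "Y")
  expect_equal(dr$ratio, 1 / mean(x == "1"), tolerance = 1e-12)
  expect_lt(dr$p_value, 1e-10)

  df2 <- data.frame(X = factor(rbinom(4000, 1, 0.5)),
                    Y = factor(rbinom(4000, 1, 0.5)))
  dr2 <- dependency_ratio(df2, "X", "Y")
  pj <- mean(df2$X == "1" & df2$Y == "1")
  expect_equal(dr2$ratio, pj / (mean(df2$X == "1") * mean(df2$Y == "1")),
               tolerance = 1e-12)
  expect_lt(abs(dr2$ratio - 1), 0.1)
  expect_error(dependency_ratio(data.frame(X = factor(rep(1, 5)),
                                           Y = factor(c(0, 1, 0, 1, 0))), "X", "Y"),
               class = "trioscape_validation_error")
})

test_that("bootstrap edge support is reproducible and finds strong edges", {
  set.seed(16)
  A <- factor(rbinom(200, 1, 0.5))
  df <- data.frame(A = A, B = A) # deterministic copy
  b1 <- bootstrap_edges(df, B = 1, seed = 3)
  expect_true(all(b1$frequency %in% c(0, 1)))
  b200 <- bootstrap_edges(df, B = 200, seed = 4)
  expect_gte(b200$undirected_frequency[b200$from == "A" & b200$to == "B"], 0.95)
  b200b <- bootstrap_edges(df, B = 200, seed = 4)
  expect_identical(b200, b200b)
})

test_that("nested LRT has the right statistic, errors and null calibration", {
  set.seed(17)
  df <- data.frame(A = factor(rbinom(500, 1, 0.5)))
  df$B <- factor(ifelse(rbinom(500, 1, 0.8) == 1, as.integer(df$A) - 1L,
                        rbinom(500, 1, 0.5)))
  full <- list(B = "A")
  reduced <- list()
  res <- lrt_nested(full, reduced, df)
  # independent logL-difference oracle
  o_full <- family_score_oracle("A", character(0), df)$logL +
    family_score_oracle("B", "A", df)$logL
  o_red <- family_score_oracle("A", character(0), df)$logL +
    family_score_oracle("B", character(0), df)$logL
  expect_equal(res$statistic, 2 * (o_full - o_red), tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 1e-6)

  same <- lrt_nested(full, full, df)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)
  expect_error(lrt_nested(reduced, full, df), class = "trioscape_validation_error")

  # under the reduced model the LRT p is roughly uniform
  ps <- vapply(1:50, function(k) {
    set.seed(600 + k)
    d <- data.frame(A = factor(rbinom(400, 1, 0.5)),
                    B = factor(rbinom(400, 1, 0.3)))
    lrt_nested(list(B = "A"), list(), d)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("moralization marries co-parents and matches the textbook oracle", {
  mor <- moralize(list(C = c("A", "B")))
  expect_equal(nrow(mor), 3)
  expect_true(mor$married[mor$node1 == "A" & mor$node2 == "B"])
  expect_false(any(mor$married[mor$node2 == "C"]))

  expect_equal(nrow(moralize(list(A = character(0), B = character(0)))), 0)

  set.seed(18)
  for (k in 1:10) {
    nms <- LETTERS[1:6]
    parents <- setNames(rep(list(character(0)), 6), nms)
    for (i in 2:6) {
      k_pa <- sample(0:min(3, i - 1), 1)
      if (k_pa > 0) parents[[nms[i]]] <- sample(nms[seq_len(i - 1)], k_pa)
    }
    mor <- moralize(parents)
    got <- sort(paste(mor$node1, mor$node2, sep = "~"))
    expect_equal(got, moralize_oracle(parents))
  }
})

test_that("annotated moral edges carry sensible sign and strength", {
  df <- data.frame(D = factor(rep(c(0, 1), each = 50)),
                   C = factor(c(rep(0, 45), rep(1, 5), rep(0, 25), rep(1, 25))))
  m <- fit_cpts(list(C = "D"), df)
  mor <- moralize(m)
  expect_equal(mor$sign, 1) # P(C=1|D=1) > P(C=1)
  expect_gt(mor$strength, 1)
  df$C <- factor(1 - as.integer(as.character(df$C)))
  m2 <- fit_cpts(list(C = "D"), df)
  expect_equal(moralize(m2)$sign, -1)
})
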