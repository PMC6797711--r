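#' Count distinct damaged genes of a list
#'
#' Number of distinct list genes carrying at least one retained damaged call
#' of the given inheritance mode; a gene damaged in many probands counts once.
#' `"recessive"` pools homozygous and compound-heterozygous calls.
#'
#' @param retained Retained-call tibble (see [classify_damaged()]).
#' @param members Character vector of gene symbols.
#' @param mode `"recessive"` or `"de_novo"`.
#' @return Integer count.
#' @export
count_damaged_genes <- function(retained, members, mode = c("recessive", "de_novo")) {
  mode <- match.arg(mode)
  if (length(members) == 0) ts_abort("empty gene list", "validation_error")
  length(intersect(members, damaged_genes(retained, mode)))
}

# internal: distinct damaged genes for a mode
damaged_genes <- function(retained, mode) {
  modes <- if (mode == "recessive") c("recessive_hom", "compound_het") else "de_novo"
  unique(retained$gene[retained$mode %in% modes])
}

#' Build a permutation null distribution of damaged-gene counts
#'
#' Draws `P` random gene lists of size `N` uniformly without replacement from
#' the whole universe (the test list is *not* excluded) and counts the
#' distinct damaged genes of the given mode in each draw. The resulting
#' empirical distribution is the null against which an observed damaged-gene
#' count is compared.
#'
#' @param retained Retained-call tibble.
#' @param universe Gene universe tibble.
#' @param N List size to emulate.
#' @param P Number of permutation draws (100,000 for production analyses).
#' @param seed Integer seed.
#' @param mode `"recessive"` or `"de_novo"`.
#' @return Object of class `perm_null`: list with `counts` (length `P`),
#'   `N`, `P`, `mean`, `sd`, `mode`, `seed`.
#' @export
build_null <- function(retained, universe, N, P = 100000L, seed = 1L,
                       mode = c("recessive", "de_novo")) {
  mode <- match.arg(mode)
  U <- nrow(universe)
  if (N > U) ts_abort("N exceeds universe size", "validation_error")
  if (N < 1) ts_abort("N must be positive", "validation_error")
  set.seed(seed)
  bitmap <- universe$gene %in% damaged_genes(retained, mode)
  counts <- vapply(seq_len(P), function(i) {
    sum(bitmap[sample.int(U, N)])
  }, numeric(1))
  structure(
    list(counts = counts, N = as.integer(N), P = as.integer(P),
         mean = mean(counts), sd = sd(counts), mode = mode,
         seed = as.integer(seed)),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> N = %d, P = %d, mode = %s: mean %.3f, sd %.3f\n",
              x$N, x$P, x$mode, x$mean, x$sd))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' `p = (d + 1) / (P + 1)` where `d` is the number of null draws whose
#' damaged-gene count reaches the observed count and `P` the number of draws.
#' With the default `exceedance = "ge"` ties count toward `d`, which is
#' conservative and makes `p = 1` attainable; the minimum attainable value is
#' `1/(P + 1)` (just under 1e-5 at `P` = 100,000, reported as "< 1e-5").
#'
#' @param observed Observed damaged-gene count.
#' @param null A `perm_null` object (or numeric vector of null counts).
#' @param exceedance `"ge"` (ties exceed) or `"gt"` (strict).
#' @return Empirical p-value in `[1/(P+1), 1]`.
#' @export
empirical_p <- function(observed, null, exceedance = c("ge", "gt")) {
  exceedance <- match.arg(exceedance)
  counts <- if (inherits(null, "perm_null")) null$counts else null
  d <- if (exceedance == "ge") sum(counts >= observed) else sum(counts > observed)
  (d + 1) / (length(counts) + 1)
}

#' Z-standardize an observed count against its permutation null
#'
#' `(observed - mean) / sd` of the null counts; Z-scores put lists of
#' different sizes and burden on a common scale so their enrichments can be
#' ranked. A companion p-value is computed by applying the empirical-p formula
#' to the standardized null counts (a rank-preserving transform, so it equals
#' the raw empirical p).
#'
#' @inheritParams empirical_p
#' @return One-row tibble: `z`, `p_z`.
#' @export
standardize <- function(observed, null, exceedance = c("ge", "gt")) {
  exceedance <- match.arg(exceedance)
  counts <- if (inherits(null, "perm_null")) null$counts else null
  m <- mean(counts)
  s <- sd(counts)
  if (!is.finite(s) || s == 0) ts_abort("degenerate null: sd = 0", "degenerate_null")
  z <- (observed - m) / s
  tibble::tibble(z = z, p_z = empirical_p(z, (counts - m) / s, exceedance))
}

#' Fold enrichment and cross-mode ratios
#'
#' `fold_enrichment()` is the observed damaged-gene count divided by the null
#' mean. `mode_ratio()` compares two folds (e.g. recessive vs de novo for the
#' same list), and `z_ratio()` divides the mean of one or more Z-scores by a
#' reference Z-score, the burden-adjusted analogue.
#'
#' @inheritParams empirical_p
#' @return A single numeric value.
#' @export
fold_enrichment <- function(observed, null) {
  m <- if (inherits(null, "perm_null")) null$mean else mean(null)
  if (!is.finite(m) || m <= 0) ts_abort("degenerate null: mean <= 0", "degenerate_null")
  observed / m
}

#' @rdname fold_enrichment
#' @param fold_a,fold_b Two fold-enrichment values.
#' @export
mode_ratio <- function(fold_a, fold_b) {
  if (fold_b == 0) ts_abort("zero denominator fold", "validation_error")
  fold_a / fold_b
}

#' @rdname fold_enrichment
#' @param z_values_numerator Numeric vector of Z-scores to average.
#' @param z_denominator Reference Z-score.
#' @export
z_ratio <- function(z_values_numerator, z_denominator) {
  if (z_denominator == 0) ts_abort("zero denominator Z-score", "validation_error")
  mean(z_values_numerator) / z_denominator
}

#' Gaussian-fit diagnostic for a permutation null
#'
#' Moments and Kolmogorov-Smirnov distance of the null counts against a
#' normal distribution with the same mean and sd. Z standardization assumes
#' the null is approximately Gaussian; distributions with `|skewness| > 0.5`
#' (or zero variance) are flagged.
#'
#' @param null A `perm_null` object or numeric vector.
#' @param skew_flag Absolute skewness beyond which the null is flagged.
#' @return One-row tibble: `mean`, `sd`, `skewness`, `excess_kurtosis`,
#'   `ks_statistic`, `flagged`, `degenerate`.
#' @export
gaussian_fit_check <- function(null, skew_flag = 0.5) {
  counts <- if (inherits(null, "perm_null")) null$counts else null
  if (length(counts) < 100) ts_abort("need >= 100 draws", "validation_error")
  m <- mean(counts)
  s <- sd(counts)
  if (!is.finite(s) || s == 0) {
    return(tibble::tibble(mean = m, sd = 0, skewness = NA_real_,
                          excess_kurtosis = NA_real_, ks_statistic = NA_real_,
                          flagged = TRUE, degenerate = TRUE))
  }
  zc <- (counts - m) / s
  skew <- mean(zc^3)
  kurt <- mean(zc^4) - 3
  ks <- suppressWarnings(ks.test(counts, "pnorm", mean = m, sd = s))$statistic
  tibble::tibble(mean = m, sd = s, skewness = skew, excess_kurtosis = kurt,
                 ks_statistic = unname(ks), flagged = abs(skew) > skew_flag,
                 degenerate = FALSE)
}

#' Permutation enrichment test across gene lists and modes
#'
#' The package's core analysis: for every gene list and inheritance mode,
#' counts the distinct damaged genes, builds (or reuses) a permutation null of
#' random equal-sized gene lists, and reports the empirical p-value, Z-score,
#' and fold enrichment.
#'
#' @param retained Retained-call tibble (see [classify_damaged()]).
#' @param universe Gene universe tibble.
#' @param lists Named list of character vectors of gene symbols.
#' @param modes Character vector of modes to test.
#' @param P Permutation draws per null.
#' @param seed Integer seed.
#' @param exceedance Tie handling for the empirical p (see [empirical_p()]).
#' @param keep_nulls If `TRUE`, attach the `perm_null` objects as an attribute
#'   `nulls` (named `list:mode`).
#' @return Tibble: `list`, `mode`, `N`, `observed`, `null_mean`, `null_sd`,
#'   `empirical_p`, `z`, `p_z`, `fold`, `P`, `seed`.
#' @export
test_enrichment <- function(retained, universe, lists,
                            modes = c("recessive", "de_novo"),
                            P = 100000L, seed = 1L,
                            exceedance = c("ge", "gt"), keep_nulls = FALSE) {
  exceedance <- match.arg(exceedance)
  grid <- tidyr::expand_grid(list = names(lists), mode = modes)
  nulls <- list()
  rows <- purrr::pmap(grid, function(list, mode) {
    members <- restrict_to_universe(lists[[list]], universe, list)
    null <- build_null(retained, universe, N = length(members), P = P,
                       seed = derive_seed(seed, match(list, names(lists)) * 10L +
                                            match(mode, modes)),
                       mode = mode)
    if (keep_nulls) nulls[[paste(list, mode, sep = ":")]] <<- null
    obs <- count_damaged_genes(retained, members, mode)
    zt <- standardize(obs, null, exceedance)
    tibble::tibble(
      list = list, mode = mode, N = length(members), observed = obs,
      null_mean = null$mean, null_sd = null$sd,
      empirical_p = empirical_p(obs, null, exceedance),
      z = zt$z, p_z = zt$p_z,
      fold = fold_enrichment(obs, null), P = as.integer(P),
      seed = null$seed
    )
  })
  out <- dplyr::bind_rows(rows)
  if (keep_nulls) attr(out, "nulls") <- nulls
  out
}
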