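#' Per-gene rare-variant burden ratio
#'
#' The burden ratio of a gene is its count of rare variants (minor allele
#' frequency <= 0.005, summed over the largest coding transcript) divided by
#' the transcript length, i.e. rare variants per base. It is the matching
#' quantity used to build burden-matched control gene lists.
#'
#' @param rare_variant_count Non-negative count(s).
#' @param transcript_length Positive length(s) in bases.
#' @return Numeric vector of per-base burden ratios.
#' @export
#' @examples
#' compute_burden_ratio(50, 10000) # 0.005
compute_burden_ratio <- function(rare_variant_count, transcript_length) {
  if (any(transcript_length <= 0)) {
    ts_abort("transcript_length must be positive", "validation_error")
  }
  if (any(rare_variant_count < 0)) {
    ts_abort("rare_variant_count must be non-negative", "validation_error")
  }
  rare_variant_count / transcript_length
}

# internal: universe with a burden_ratio column added
with_burden_ratio <- function(universe) {
  dplyr::mutate(universe, burden_ratio = compute_burden_ratio(
    .data$rare_variant_count, .data$transcript_length))
}

ols_fit <- function(df, formula) {
  fit <- lm(formula, data = df)
  s <- summary(fit)
  if (any(is.na(fit$coefficients))) {
    ts_abort("degenerate fit: constant predictor", "degenerate_fit")
  }
  fstat <- s$fstatistic
  tibble::tibble(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r2_adj = s$adj.r.squared,
    f_p = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  )
}

#' Regress burden ratio on transcript length
#'
#' Ordinary least squares of per-gene burden ratio on transcript length for a
#' set of genes, as used to compare the background mutation tolerance of gene
#' classes (e.g. cilia vs housekeeping genes). Positive slopes mean larger
#' genes carry proportionally more rare variation per base.
#'
#' @param genes Tibble with `transcript_length` and `rare_variant_count`
#'   columns (a universe or a subset of one).
#' @return One-row tibble: `slope`, `intercept`, `r2_adj` (adjusted R-squared),
#'   `f_p` (linear-model F-test p-value).
#' @export
burden_length_regression <- function(genes) {
  if (nrow(genes) < 3) ts_abort("need >= 3 genes", "validation_error")
  if (length(unique(genes$transcript_length)) < 2) {
    ts_abort("degenerate fit: constant predictor", "degenerate_fit")
  }
  df <- with_burden_ratio(genes)
  ols_fit(df, burden_ratio ~ transcript_length)
}

#' Regress damaged-call p-values on gene burden
#'
#' Checks whether burden-test p-values of damaged genotypes depend on the
#' per-base burden of the gene they fall in; a near-zero adjusted R-squared and
#' non-significant F-test indicate the burden test is not biased towards
#' high-burden genes.
#'
#' @param calls Damaged-call tibble with `gene` and `vaast_p`.
#' @param universe Gene universe tibble.
#' @return One-row tibble as [burden_length_regression()].
#' @export
damage_burden_regression <- function(calls, universe) {
  if (nrow(calls) == 0) ts_abort("calls table is empty", "validation_error")
  df <- dplyr::inner_join(calls, with_burden_ratio(universe), by = "gene")
  if (length(unique(df$burden_ratio)) < 2) {
    ts_abort("degenerate fit: constant predictor", "degenerate_fit")
  }
  ols_fit(df, vaast_p ~ burden_ratio)
}

#' Decile burden profile of a gene list
#'
#' Splits the list's own burden-ratio distribution into ten deciles (by rank,
#' lowest to highest) and reports each decile's mean and standard deviation.
#' This is the profile a burden-matched control list must reproduce.
#'
#' @param members Character vector of gene symbols.
#' @param universe Gene universe tibble.
#' @return Tibble with `decile` (1-10), `n`, `mean`, `sd` (sd is 0 for
#'   single-gene deciles).
#' @export
decile_burden_profile <- function(members, universe) {
  members <- restrict_to_universe(members, universe)
  if (length(members) < 10) ts_abort("need >= 10 genes for deciles", "validation_error")
  u <- with_burden_ratio(universe)
  ratios <- sort(u$burden_ratio[match(members, u$gene)])
  bins <- decile_bins(length(ratios))
  tibble::tibble(
    decile = 1:10,
    n = as.integer(tabulate(bins, 10)),
    mean = vapply(1:10, function(d) mean(ratios[bins == d]), numeric(1)),
    sd = vapply(1:10, function(d) {
      x <- ratios[bins == d]
      if (length(x) < 2) 0 else sd(x)
    }, numeric(1))
  )
}

# rank-based decile assignment for n sorted values
decile_bins <- function(n) {
  as.integer(ceiling(seq_len(n) / n * 10))
}

# one stratum draw: for each target ratio pick one of its k nearest unused
# candidates (cand sorted ascending); returns candidate indices
draw_nearest <- function(targets, cand, used, k) {
  picked <- integer(length(targets))
  taken <- used
  n <- length(cand)
  for (i in sample(seq_along(targets))) {
    pos <- findInterval(targets[i], cand)
    lo <- pos
    hi <- pos + 1L
    found <- integer(0)
    while (length(found) < k && (lo >= 1L || hi <= n)) {
      dl <- if (lo >= 1L && !taken[lo]) abs(cand[lo] - targets[i]) else Inf
      dh <- if (hi <= n && !taken[hi]) abs(cand[hi] - targets[i]) else Inf
      if (is.infinite(dl) && is.infinite(dh)) {
        if (lo >= 1L) lo <- lo - 1L
        if (hi <= n) hi <- hi + 1L
        next
      }
      if (dl <= dh) { found <- c(found, lo); lo <- lo - 1L }
      else { found <- c(found, hi); hi <- hi + 1L }
    }
    if (length(found) == 0) ts_abort("candidate pool exhausted", "matching_error")
    pick <- found[sample.int(length(found), 1L)]
    picked[i] <- pick
    taken[pick] <- TRUE
  }
  picked
}

#' Sample a burden-matched control gene list
#'
#' Draws a random gene list of the same size as the test list, disjoint from
#' it, whose burden-ratio profile matches the test list decile by decile.
#' Stratified rejection sampling: within each decile, every test gene is
#' matched by a random draw from its nearest still-unused non-test candidates
#' (by burden ratio), and the stratum draw is rejected and redrawn until the
#' decile mean is within `tolerance` of the test decile mean and the decile sd
#' within `sd_factor` times the test sd. The default tolerance is a quarter of
#' the test decile's sd (with a small floor), tight enough that control lists
#' behave as unbiased nulls.
#'
#' @param members Character vector: the test list.
#' @param universe Gene universe tibble.
#' @param seed Integer seed.
#' @param tolerance Per-decile mean tolerance (per-base ratio). Default
#'   `NULL` means 0.25 x test-decile sd, floored at 1e-5; `Inf` degenerates to
#'   plain disjoint random sampling.
#' @param sd_factor Allowed ratio between control and test decile sd.
#' @param max_iter Resampling attempts per decile before failing.
#' @return Character vector of control gene symbols, with attributes
#'   `profile_distance` (max standardized decile-mean discrepancy),
#'   `achieved_profile` (the control strata's per-decile mean/sd, aligned to
#'   the test-list strata) and `decile_source = "test list"`.
#' @export
sample_burden_matched <- function(members, universe, seed = 1L,
                                  tolerance = NULL, sd_factor = 2,
                                  max_iter = 1000L) {
  members <- restrict_to_universe(members, universe)
  set.seed(seed)
  u <- with_burden_ratio(universe)
  candidates <- u[!(u$gene %in% members), ]
  if (nrow(candidates) < length(members)) {
    ts_abort("universe too small to supply a disjoint control list", "matching_error")
  }

  if (!is.null(tolerance) && is.infinite(tolerance)) {
    ctrl <- sample(candidates$gene, length(members))
    attr(ctrl, "profile_distance") <- NA_real_
    attr(ctrl, "decile_source") <- "test list"
    return(ctrl)
  }

  prof <- decile_burden_profile(members, universe)
  ratios <- sort(u$burden_ratio[match(members, u$gene)])
  bins <- decile_bins(length(ratios))
  lo <- vapply(1:10, function(d) min(ratios[bins == d]), numeric(1))
  hi <- vapply(1:10, function(d) max(ratios[bins == d]), numeric(1))
  tol <- tolerance %||% pmax(0.25 * prof$sd, 1e-5)
  tol <- rep_len(tol, 10)

  # candidates sorted by burden ratio; each stratum draws, per test gene, one
  # of the `k_near` nearest still-unused candidates, and the whole stratum draw
  # is rejected until its mean and sd meet the tolerances
  ord <- order(candidates$burden_ratio)
  cand_ratio <- candidates$burden_ratio[ord]
  cand_gene <- candidates$gene[ord]
  used <- rep(FALSE, length(cand_gene))
  k_near <- 8L
  control <- character(0)
  achieved <- prof
  worst <- 0
  for (d in 1:10) {
    nd <- prof$n[d]
    targets <- ratios[bins == d]
    if (sum(!used) < nd) {
      ts_abort(sprintf("decile %d: candidate pool exhausted", d), "matching_error")
    }
    ok <- FALSE
    best <- Inf
    for (it in seq_len(max_iter)) {
      pick <- draw_nearest(targets, cand_ratio, used, k_near)
      vals <- cand_ratio[pick]
      m <- mean(vals)
      s <- if (nd < 2) 0 else sd(vals)
      dist <- abs(m - prof$mean[d])
      best <- min(best, dist)
      sd_ok <- prof$sd[d] == 0 || (s <= sd_factor * prof$sd[d])
      if (dist <= tol[d] && sd_ok) {
        control <- c(control, cand_gene[pick])
        used[pick] <- TRUE
        achieved$mean[d] <- m
        achieved$sd[d] <- s
        worst <- max(worst, dist / max(tol[d], 1e-12))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      ts_abort(sprintf(
        "decile %d: matching failed after %d iterations (best |mean diff| %.3g > tol %.3g)",
        d, max_iter, best, tol[d]), "matching_error")
    }
  }
  control <- sample(control) # drop stratum ordering
  attr(control, "profile_distance") <- worst
  attr(control, "achieved_profile") <- achieved
  attr(control, "decile_source") <- "test list"
  control
}
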