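#' Exact posterior inference in a belief network
#'
#' Computes `P(target | evidence)` exactly by sum-product variable elimination
#' over the model's CPT factors; on the discrete networks this package targets
#' (up to 14 nodes) this equals full joint-table summation. Evidence is a
#' named list mapping nodes to an observed state, a set of allowed states, or
#' a negated state built with [bn_not()] (state exclusion).
#'
#' @param model A `bn_model` (see [fit_cpts()], [learn_structure_exact()]).
#' @param target Node name.
#' @param evidence Named list, e.g.
#'   `list(Recessive = "1", DeNovo = bn_not("1"))`.
#' @return Named numeric vector of posterior probabilities over the target's
#'   states (sums to 1).
#' @export
infer <- function(model, target, evidence = list()) {
  stopifnot(inherits(model, "bn_model"))
  nms <- model$nodes$name
  ti <- match(target, nms)
  if (is.na(ti)) ts_abort("unknown target node", "validation_error")
  factors <- model_factors(model)
  factors <- c(factors, evidence_factors(model, evidence))
  post <- eliminate_all_but(factors, ti, model$nodes$arity)
  z <- sum(post)
  if (z <= 0) ts_abort("evidence has probability zero", "undefined_conditional")
  setNames(post / z, model$nodes$states[[ti]])
}

#' @rdname infer
#' @param state A state label (or integer index) to exclude.
#' @export
bn_not <- function(state) structure(list(state = state), class = "bn_not")

# CPTs as factors: vars = (child, parents) integer ids
model_factors <- function(model) {
  nms <- model$nodes$name
  lapply(nms, function(v) {
    pa <- model$parents[[v]]
    list(vars = c(match(v, nms), match(pa, nms)),
         table = as.vector(model$cpts[[v]]))
  })
}

evidence_factors <- function(model, evidence) {
  if (length(evidence) == 0) return(list())
  nms <- model$nodes$name
  purrr::imap(evidence, function(val, node) {
    vi <- match(node, nms)
    if (is.na(vi)) ts_abort(paste("unknown evidence node:", node), "validation_error")
    states <- model$nodes$states[[vi]]
    ind <- rep(0, length(states))
    if (inherits(val, "bn_not")) {
      excl <- state_index(val$state, states, node)
      ind[-excl] <- 1
    } else {
      ind[state_index(val, states, node)] <- 1
    }
    if (sum(ind) == 0) ts_abort("evidence excludes all states", "validation_error")
    list(vars = vi, table = ind)
  }) |> unname()
}

state_index <- function(val, states, node) {
  idx <- if (is.numeric(val)) as.integer(val) else match(as.character(val), states)
  if (anyNA(idx) || any(idx < 1) || any(idx > length(states))) {
    ts_abort(sprintf("state not in node '%s' state space", node), "validation_error")
  }
  idx
}

# index vector mapping a grid over `vars` (first varies fastest) into f's table
expand_index <- function(f, vars, arity) {
  dims <- arity[vars]
  total <- prod(dims)
  idx <- rep(1L, total)
  stride_f <- 1L
  for (v in f$vars) {
    pos <- match(v, vars)
    before <- if (pos == 1) 1 else prod(dims[seq_len(pos - 1)])
    after <- total / (before * dims[pos])
    gv <- rep(rep(seq_len(dims[pos]), each = before), times = after)
    idx <- idx + (gv - 1L) * stride_f
    stride_f <- stride_f * dims[pos]
  }
  idx
}

factor_product <- function(f1, f2, arity) {
  vars <- union(f1$vars, f2$vars)
  list(vars = vars,
       table = f1$table[expand_index(f1, vars, arity)] *
         f2$table[expand_index(f2, vars, arity)])
}

factor_marginalize <- function(f, var, arity) {
  pos <- match(var, f$vars)
  dims <- arity[f$vars]
  perm <- c(seq_along(dims)[-pos], pos)
  a <- aperm(array(f$table, dims), perm)
  m <- matrix(a, ncol = dims[pos])
  list(vars = f$vars[-pos], table = as.vector(rowSums(m)))
}

eliminate_all_but <- function(factors, target, arity) {
  vars_all <- sort(unique(unlist(lapply(factors, `[[`, "vars"))))
  for (v in setdiff(vars_all, target)) {
    touching <- vapply(factors, function(f) v %in% f$vars, logical(1))
    combined <- Reduce(function(a, b) factor_product(a, b, arity), factors[touching])
    factors <- c(factors[!touching], list(factor_marginalize(combined, v, arity)))
  }
  out <- Reduce(function(a, b) factor_product(a, b, arity), factors)
  # any remaining factor is over the target only
  stopifnot(all(out$vars == target))
  out$table
}

#' Conditional risk ratio
#'
#' `P(target = state | evidence_num) / P(target = state | evidence_den)`,
#' the belief-network analogue of a relative risk. With `evidence_den = NULL`
#' the denominator is the unconditional marginal, e.g.
#' `P(HTX | R_Cilia = 1) / P(HTX)`. Negated evidence ([bn_not()]) expresses
#' queries such as `P(cilia | recessive, not de novo) / P(cilia)`.
#'
#' @inheritParams infer
#' @param state Target state whose risk is compared.
#' @param evidence_num,evidence_den Evidence lists; `evidence_den = NULL`
#'   means the unconditional marginal.
#' @return A single fold value.
#' @export
risk_ratio <- function(model, target, state, evidence_num, evidence_den = NULL) {
  p_num <- infer(model, target, evidence_num)
  p_den <- infer(model, target, evidence_den %||% list())
  si <- state_index(state, model$nodes$states[[match(target, model$nodes$name)]], target)
  if (p_den[si] <= 0) ts_abort("undefined denominator risk", "undefined_conditional")
  unname(p_num[si] / p_den[si])
}

#' Observed-over-expected co-occurrence of two binary nodes
#'
#' `P(X = x1, Y = y1) / (P(X = x1) * P(Y = y1))` estimated directly from the
#' data (positive state = the highest factor level, e.g. `1` for 0/1
#' indicators), with an independence-test p-value from the chi-square test on
#' the 2x2 table (or Fisher's exact test).
#'
#' @param data Data frame of discrete variables.
#' @param x,y Names of two binary columns.
#' @param test `"chisq"` (default, without continuity correction) or
#'   `"fisher"`.
#' @return One-row tibble: `ratio`, `p_value`, `n`.
#' @export
dependency_ratio <- function(data, x, y, test = c("chisq", "fisher")) {
  test <- match.arg(test)
  bd <- bn_data(data)
  xi <- match(x, bd$nodes$name)
  yi <- match(y, bd$nodes$name)
  if (anyNA(c(xi, yi))) ts_abort("unknown node name", "validation_error")
  if (bd$nodes$arity[xi] != 2 || bd$nodes$arity[yi] != 2) {
    ts_abort("dependency_ratio requires binary nodes", "validation_error")
  }
  ok <- !is.na(bd$x[, xi]) & !is.na(bd$x[, yi])
  xv <- bd$x[ok, xi] == 2L
  yv <- bd$x[ok, yi] == 2L
  n <- sum(ok)
  px <- mean(xv)
  py <- mean(yv)
  if (px %in% c(0, 1) || py %in% c(0, 1)) {
    ts_abort("zero marginal for a binary node", "validation_error")
  }
  ratio <- mean(xv & yv) / (px * py)
  tab <- table(factor(xv, c(FALSE, TRUE)), factor(yv, c(FALSE, TRUE)))
  p <- if (test == "chisq") {
    suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
  } else {
    fisher.test(tab)$p.value
  }
  tibble::tibble(ratio = ratio, p_value = p, n = n)
}

#' Likelihood-ratio test between nested belief networks
#'
#' Compares a full model against a reduced one obtained by deleting edges:
#' statistic `2 (logL_full - logL_reduced)`, degrees of freedom
#' `k_full - k_reduced`, chi-square upper-tail p-value. Both models are
#' re-scored on the supplied data.
#'
#' @param model_full,model_reduced `bn_model` objects or named parent lists;
#'   the reduced edge set must be a subset of the full one.
#' @param data Data frame of discrete variables.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `logL_full`,
#'   `logL_reduced`.
#' @export
lrt_nested <- function(model_full, model_reduced, data) {
  pf_ <- if (inherits(model_full, "bn_model")) model_full$parents else model_full
  pr_ <- if (inherits(model_reduced, "bn_model")) model_reduced$parents else model_reduced
  bd <- bn_data(data)
  pf_ <- complete_parents(pf_, bd$nodes$name)
  pr_ <- complete_parents(pr_, bd$nodes$name)
  edges <- function(p) {
    unlist(purrr::imap(p, function(pa, ch) if (length(pa)) paste(pa, ch, sep = "->")))
  }
  if (!all(edges(pr_) %in% edges(pf_))) {
    ts_abort("reduced model is not nested in the full model", "validation_error")
  }
  score <- function(parents) {
    tot <- list(logL = 0, k = 0)
    for (v in bd$nodes$name) {
      fs <- family_score_int(bd$x, bd$nodes$arity, match(v, bd$nodes$name),
                             match(parents[[v]], bd$nodes$name))
      tot$logL <- tot$logL + fs$logL
      tot$k <- tot$k + fs$k
    }
    tot
  }
  sf <- score(pf_)
  sr <- score(pr_)
  stat <- 2 * (sf$logL - sr$logL)
  df <- sf$k - sr$k
  p <- if (df <= 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  if (df <= 0 && abs(stat) < 1e-9) p <- 1
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 logL_full = sf$logL, logL_reduced = sr$logL)
}
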