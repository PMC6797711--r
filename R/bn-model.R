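#' Discrete data matrix helpers
#'
#' The belief-network layer works on a data frame of discrete variables
#' (probands in rows, nodes in columns). `bn_data()` validates and encodes it:
#' every column is coerced to a factor, and the integer codes 1..arity are
#' used internally. Missing entries are allowed and handled complete-case per
#' family (rows missing any of a node's family variables are dropped when that
#' family is scored).
#'
#' @param data Data frame of factors / character / logical / integer columns.
#' @return List with `x` (integer matrix, NA for missing), `nodes` (tibble
#'   `name`, `arity`, `states` list-column).
#' @keywords internal
bn_data <- function(data) {
  data <- as.data.frame(data)
  if (anyDuplicated(names(data))) ts_abort("duplicate column names", "validation_error")
  if (ncol(data) < 1) ts_abort("no columns", "validation_error")
  cols <- lapply(data, function(col) {
    f <- if (is.factor(col)) col else factor(col)
    if (nlevels(f) < 1) ts_abort("column with no observed states", "validation_error")
    f
  })
  x <- vapply(cols, as.integer, integer(nrow(data)))
  if (!is.matrix(x)) x <- matrix(x, nrow = nrow(data), dimnames = list(NULL, names(data)))
  nodes <- tibble::tibble(
    name = names(data),
    arity = unname(vapply(cols, nlevels, integer(1))),
    states = unname(lapply(cols, levels))
  )
  list(x = x, nodes = nodes)
}

#' Log-likelihood and parameter count of one node family
#'
#' Multinomial maximum-likelihood contribution of a node given a parent set:
#' `logL = sum_jk n_jk log(n_jk / n_j)` over parent configurations `j` and node
#' states `k`, with parameter count `k = (arity - 1) * prod(parent arities)`.
#' Scores are decomposable: a DAG's total log-likelihood is the sum of its
#' family contributions. Rows missing any family variable are dropped
#' (complete-case per family).
#'
#' @param node Column name of the child node.
#' @param parent_set Character vector of parent column names (possibly empty).
#' @param data Data frame of discrete variables.
#' @return List: `logL`, `k`, `n` (rows used).
#' @export
family_score <- function(node, parent_set, data) {
  if (node %in% parent_set) ts_abort("node cannot be its own parent", "validation_error")
  bd <- bn_data(data)
  v <- match(node, bd$nodes$name)
  p <- match(parent_set, bd$nodes$name)
  if (anyNA(c(v, p))) ts_abort("unknown node name", "validation_error")
  family_score_int(bd$x, bd$nodes$arity, v, p)
}

# internal: integer-coded family score
family_score_int <- function(x, arity, v, parents) {
  cols <- c(v, parents)
  sub <- x[, cols, drop = FALSE]
  ok <- !rowSums(is.na(sub)) > 0
  sub <- sub[ok, , drop = FALSE]
  n <- nrow(sub)
  r <- arity[v]
  Q <- if (length(parents) == 0) 1L else prod(arity[parents])
  if (n == 0) return(list(logL = 0, k = (r - 1) * Q, n = 0L))
  code_p <- rep(1L, n)
  stride <- 1L
  for (j in seq_along(parents)) {
    code_p <- code_p + (sub[, j + 1L] - 1L) * stride
    stride <- stride * arity[parents[j]]
  }
  counts <- tabulate((code_p - 1L) * r + sub[, 1L], nbins = r * Q)
  cm <- matrix(counts, nrow = r)
  nj <- colSums(cm)
  pos <- cm > 0
  logL <- sum(cm[pos] * log(cm[pos] / rep(nj, each = r)[pos]))
  list(logL = logL, k = (r - 1) * Q, n = as.integer(n))
}

#' Fit conditional probability tables on a fixed DAG
#'
#' Maximum-likelihood (optionally pseudocount-smoothed) conditional
#' frequencies for every node given its parents. Parent configurations with no
#' supporting rows get a uniform row.
#'
#' @param parents Named list: each node's character vector of parents (nodes
#'   absent from the list have no parents). Must be acyclic.
#' @param data Data frame of discrete variables (see [bn_data()]).
#' @param pseudocount Added to every cell before normalization.
#' @return Object of class `bn_model`: `nodes`, `parents`, `cpts` (list of
#'   arrays, child dimension first), `logL`, `k`, `aic`, `n`.
#' @export
fit_cpts <- function(parents, data, pseudocount = 0) {
  bd <- bn_data(data)
  nms <- bd$nodes$name
  parents <- complete_parents(parents, nms)
  check_acyclic(parents)
  arity <- bd$nodes$arity
  logL <- 0
  k <- 0
  cpts <- list()
  for (v in seq_along(nms)) {
    pa <- match(parents[[nms[v]]], nms)
    fs <- family_score_int(bd$x, arity, v, pa)
    logL <- logL + fs$logL
    k <- k + fs$k
    cpts[[nms[v]]] <- fit_one_cpt(bd$x, arity, v, pa, pseudocount, bd$nodes)
  }
  structure(
    list(nodes = bd$nodes, parents = parents, cpts = cpts,
         logL = logL, k = k, aic = -2 * logL + 2 * k, n = nrow(bd$x),
         pseudocount = pseudocount),
    class = "bn_model"
  )
}

fit_one_cpt <- function(x, arity, v, parents, pseudocount, nodes) {
  r <- arity[v]
  Q <- if (length(parents) == 0) 1L else prod(arity[parents])
  cols <- c(v, parents)
  sub <- x[, cols, drop = FALSE]
  sub <- sub[!rowSums(is.na(sub)) > 0, , drop = FALSE]
  code_p <- rep(1L, nrow(sub))
  stride <- 1L
  for (j in seq_along(parents)) {
    code_p <- code_p + (sub[, j + 1L] - 1L) * stride
    stride <- stride * arity[parents[j]]
  }
  counts <- tabulate((code_p - 1L) * r + sub[, 1L], nbins = r * Q) + pseudocount
  cm <- matrix(counts, nrow = r)
  nj <- colSums(cm)
  zero <- nj == 0
  cm[, zero] <- 1
  nj[zero] <- r
  tab <- sweep(cm, 2, nj, "/")
  dims <- c(r, if (length(parents) > 0) arity[parents])
  dn <- c(nodes$states[v], if (length(parents) > 0) nodes$states[parents])
  names(dn) <- c(nodes$name[v], nodes$name[parents])
  array(tab, dim = dims, dimnames = dn)
}

complete_parents <- function(parents, node_names) {
  parents <- parents %||% list()
  unknown <- setdiff(c(names(parents), unlist(parents)), node_names)
  if (length(unknown) > 0) {
    ts_abort(paste("unknown node(s):", paste(unknown, collapse = ", ")),
             "validation_error")
  }
  out <- setNames(vector("list", length(node_names)), node_names)
  for (nm in node_names) out[[nm]] <- as.character(parents[[nm]] %||% character(0))
  out
}

check_acyclic <- function(parents) {
  nms <- names(parents)
  state <- setNames(rep(0L, length(nms)), nms) # 0 unseen, 1 in stack, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) ts_abort("parent sets contain a cycle", "validation_error")
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (p in parents[[v]]) visit(p)
    state[[v]] <<- 2L
  }
  for (v in nms) visit(v)
  invisible(parents)
}

#' @export
print.bn_model <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("<bn_model> %d nodes, %d edges, n = %d\n  logL = %.3f, k = %d, AIC = %.3f\n",
              nrow(x$nodes), ne, x$n, x$logL, x$k, x$aic))
  invisible(x)
}

#' Sample observations from a fitted belief network
#'
#' Ancestral sampling from a `bn_model`; useful for parameter-recovery checks
#' and simulation-based calibration.
#'
#' @param model A `bn_model`.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Data frame of factors with the model's nodes as columns.
#' @export
sample_bn <- function(model, n, seed = 1L) {
  set.seed(seed)
  nms <- model$nodes$name
  order <- topo_order(model$parents)
  out <- matrix(NA_integer_, n, length(nms), dimnames = list(NULL, nms))
  for (v in order) {
    pa <- model$parents[[v]]
    cpt <- model$cpts[[v]]
    r <- model$nodes$arity[match(v, nms)]
    if (length(pa) == 0) {
      out[, v] <- sample.int(r, n, replace = TRUE, prob = as.vector(cpt))
    } else {
      arities <- model$nodes$arity[match(pa, nms)]
      code <- rep(1L, n)
      stride <- 1L
      for (j in seq_along(pa)) {
        code <- code + (out[, pa[j]] - 1L) * stride
        stride <- stride * arities[j]
      }
      m <- matrix(cpt, nrow = r)
      out[, v] <- vapply(code, function(cfg) {
        sample.int(r, 1L, prob = m[, cfg])
      }, integer(1))
    }
  }
  df <- as.data.frame(out)
  for (j in seq_along(nms)) {
    st <- model$nodes$states[[j]]
    df[[j]] <- factor(st[df[[j]]], levels = st)
  }
  df
}

topo_order <- function(parents) {
  nms <- names(parents)
  done <- character(0)
  while (length(done) < length(nms)) {
    ready <- nms[!nms %in% done &
                   vapply(parents, function(p) all(p %in% done), logical(1))]
    if (length(ready) == 0) ts_abort("parent sets contain a cycle", "validation_error")
    done <- c(done, ready)
  }
  done
}

#' @export
tidy.bn_model <- function(x, ...) {
  edges <- purrr::compact(purrr::imap(x$parents, function(pa, child) {
    if (length(pa) == 0) return(NULL)
    tibble::tibble(from = pa, to = child)
  }))
  if (length(edges) == 0) {
    return(tibble::tibble(from = character(), to = character()))
  }
  dplyr::bind_rows(edges)
}

#' @export
glance.bn_model <- function(x, ...) {
  tibble::tibble(logL = x$logL, k = x$k, AIC = x$aic,
                 nodes = nrow(x$nodes), edges = sum(lengths(x$parents)), n = x$n)
}
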