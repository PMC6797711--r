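#' Moralize a belief network
#'
#' Converts the DAG to its undirected moral graph: directed edges lose their
#' direction and co-parents of a common child are "married". This is the form
#' in which belief networks are best visualized, since every node is then
#' connected to its Markov blanket. When a fitted `bn_model` is supplied, each
#' edge is annotated with a dependency strength — the average over state pairs
#' `(x, y)` of `max(r, 1/r)` with `r = P(Y = y | X = x) / P(Y = y)` — and, for
#' binary-binary pairs, a sign taken from the direction of the (positive,
#' positive) cell (`r > 1` positive).
#'
#' @param x A `bn_model`, or a named parent list (in which case no annotation
#'   is computed).
#' @return Tibble `node1`, `node2` (node1 < node2 alphabetically), `married`
#'   (TRUE for co-parent marriages absent from the DAG), and for models `sign`
#'   (+1 / -1 / NA for multistate pairs) and `strength`.
#' @export
moralize <- function(x) {
  parents <- if (inherits(x, "bn_model")) {
    x$parents
  } else {
    complete_parents(x, union(names(x), unlist(x)))
  }
  check_acyclic(parents)
  edges <- list()
  add_edge <- function(a, b, married) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(edges[[key]])) {
      edges[[key]]$married <<- edges[[key]]$married && married
    } else {
      edges[[key]] <<- list(node1 = min(a, b), node2 = max(a, b), married = married)
    }
  }
  for (child in names(parents)) {
    pa <- parents[[child]]
    for (p in pa) add_edge(p, child, married = FALSE)
    if (length(pa) >= 2) {
      pairs <- utils::combn(sort(pa), 2)
      for (j in seq_len(ncol(pairs))) add_edge(pairs[1, j], pairs[2, j], married = TRUE)
    }
  }
  if (length(edges) == 0) {
    out <- tibble::tibble(node1 = character(), node2 = character(),
                          married = logical())
  } else {
    out <- dplyr::bind_rows(lapply(edges, tibble::as_tibble))
    out <- dplyr::arrange(out, .data$node1, .data$node2)
  }
  if (inherits(x, "bn_model") && nrow(out) > 0) {
    ann <- purrr::map2(out$node1, out$node2, function(a, b) edge_strength(x, a, b))
    out$sign <- vapply(ann, `[[`, numeric(1), "sign")
    out$strength <- vapply(ann, `[[`, numeric(1), "strength")
  }
  out
}

# average pairwise fold change in risk between two nodes
edge_strength <- function(model, a, b) {
  nms <- model$nodes$name
  sa <- model$nodes$states[[match(a, nms)]]
  sb <- model$nodes$states[[match(b, nms)]]
  marg_b <- infer(model, b)
  folds <- c()
  for (xs in seq_along(sa)) {
    cond <- tryCatch(infer(model, b, setNames(list(xs), a)),
                     trioscape_undefined_conditional = function(e) NULL)
    if (is.null(cond)) next
    for (ys in seq_along(sb)) {
      if (marg_b[ys] <= 0 || cond[ys] <= 0) next
      r <- cond[ys] / marg_b[ys]
      folds <- c(folds, max(r, 1 / r))
    }
  }
  sign <- NA_real_
  if (length(sa) == 2 && length(sb) == 2) {
    cond11 <- tryCatch(infer(model, b, setNames(list(2L), a))[2],
                       trioscape_undefined_conditional = function(e) NA_real_)
    if (is.finite(cond11) && marg_b[2] > 0) {
      sign <- if (cond11 >= marg_b[2]) 1 else -1
    }
  }
  list(sign = sign, strength = if (length(folds)) mean(folds) else NA_real_)
}
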