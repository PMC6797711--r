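#' Exact AIC-optimal structure learning
#'
#' Finds the globally AIC-minimal DAG by dynamic programming over node subsets
#' (the Silander-Myllymaki scheme): score every (node, candidate parent set)
#' family, propagate best parent sets over growing candidate sets, choose the
#' best sink for every node subset, and backtrack an optimal ordering and its
#' parent sets. Each family is scored by its maximum log-likelihood minus its
#' parameter count (equivalently, total AIC `-2 logL + 2 k` is minimized).
#' Ties are broken deterministically towards smaller parent sets, then
#' lexicographically smaller ones, then the smallest sink label.
#'
#' @param data Data frame of discrete variables (see [bn_data()]).
#' @param max_nodes Hard cap on the subset dynamic program (default 14).
#' @param pseudocount Passed to [fit_cpts()] for the returned model's CPTs.
#' @return A fitted `bn_model` with the optimal DAG.
#' @export
learn_structure_exact <- function(data, max_nodes = 14L, pseudocount = 0) {
  bd <- bn_data(data)
  n <- nrow(bd$nodes)
  if (n > max_nodes) {
    ts_abort(sprintf(
      "%d nodes exceeds the exact-search capacity (%d); use hill_climb_aic()",
      n, max_nodes), "capacity_error")
  }
  arity <- bd$nodes$arity
  nms <- bd$nodes$name
  full <- bitwShiftL(1L, n) - 1L
  nmask <- full + 1L

  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  mask_bits <- lapply(0:full, function(m) which(bitwAnd(m, bit) != 0L))

  # local scores: ls[[v]][mask + 1] for masks not containing v
  eps <- 1e-9
  ls <- vector("list", n)
  for (v in seq_len(n)) {
    sv <- rep(NA_real_, nmask)
    for (m in 0:full) {
      if (bitwAnd(m, bit[v]) != 0L) next
      fs <- family_score_int(bd$x, arity, v, mask_bits[[m + 1L]])
      sv[m + 1L] <- fs$logL - fs$k
    }
    ls[[v]] <- sv
  }

  # best parent set within each candidate set; prefer subsets on ties
  bps_score <- ls
  bps_set <- lapply(seq_len(n), function(v) {
    s <- rep(NA_integer_, nmask)
    s[!is.na(ls[[v]])] <- which(!is.na(ls[[v]])) - 1L
    s
  })
  ord <- order(vapply(0:full, function(m) length(mask_bits[[m + 1L]]), integer(1)))
  for (m1 in ord) {
    m <- m1 - 1L
    members <- mask_bits[[m1]]
    if (length(members) == 0) next
    for (v in seq_len(n)) {
      if (bitwAnd(m, bit[v]) != 0L) next
      best_s <- ls[[v]][m1]
      best_set <- m
      for (c in members) {
        sub <- bitwAnd(m, bitwNot(bit[c]))
        s <- bps_score[[v]][sub + 1L]
        if (s > best_s + eps ||
            (s >= best_s - eps && smaller_set(bps_set[[v]][sub + 1L], best_set))) {
          best_s <- s
          best_set <- bps_set[[v]][sub + 1L]
        }
      }
      bps_score[[v]][m1] <- best_s
      bps_set[[v]][m1] <- best_set
    }
  }

  # best sink per subset
  best <- rep(-Inf, nmask)
  sink <- rep(NA_integer_, nmask)
  best[1L] <- 0
  for (m1 in ord) {
    m <- m1 - 1L
    members <- mask_bits[[m1]]
    if (length(members) == 0) next
    for (s in members) {
      rest <- bitwAnd(m, bitwNot(bit[s]))
      val <- best[rest + 1L] + bps_score[[s]][rest + 1L]
      if (val > best[m1] + eps) {
        best[m1] <- val
        sink[m1] <- s
      }
    }
  }

  parents <- setNames(vector("list", n), nms)
  m <- full
  while (m > 0L) {
    s <- sink[m + 1L]
    rest <- bitwAnd(m, bitwNot(bit[s]))
    pset <- bps_set[[s]][rest + 1L]
    parents[[nms[s]]] <- nms[mask_bits[[pset + 1L]]]
    m <- rest
  }
  fit_cpts(parents, data, pseudocount = pseudocount)
}

# tie-break: fewer bits, then smaller mask
smaller_set <- function(a, b) {
  na <- bit_count(a)
  nb <- bit_count(b)
  na < nb || (na == nb && a < b)
}

bit_count <- function(m) {
  k <- 0L
  while (m > 0L) {
    k <- k + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  k
}

#' Hill-climbing AIC structure search
#'
#' Greedy first-improvement search over add / delete / reverse edge moves with
#' an AIC score, used for bootstrap replicates where the exact search would be
#' too slow. Parents per node are capped.
#'
#' @param data Data frame of discrete variables.
#' @param max_parents Parent-set size cap.
#' @param max_iter Maximum accepted moves.
#' @param restarts Number of random restarts beyond the empty start (the best
#'   scoring result is kept).
#' @param seed Integer seed (used for restart initialisation and move order).
#' @param pseudocount Passed to [fit_cpts()].
#' @return A fitted `bn_model`.
#' @export
hill_climb_aic <- function(data, max_parents = 4L, max_iter = 100L,
                           restarts = 1L, seed = 1L, pseudocount = 0) {
  bd <- bn_data(data)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    init <- if (r == 1) NULL else random_dag(bd$nodes$name, max_parents)
    cand <- hill_climb_once(bd, init, max_parents, max_iter)
    if (is.null(best) || cand$score > best$score + 1e-9) best <- cand
  }
  model <- fit_cpts(best$parents, data, pseudocount = pseudocount)
  model
}

hill_climb_once <- function(bd, init, max_parents, max_iter) {
  nms <- bd$nodes$name
  n <- length(nms)
  parents <- init %||% setNames(rep(list(character(0)), n), nms)
  fam <- function(v, pa) {
    fs <- family_score_int(bd$x, bd$nodes$arity, match(v, nms), match(pa, nms))
    fs$logL - fs$k
  }
  score_v <- vapply(nms, function(v) fam(v, parents[[v]]), numeric(1))
  would_cycle <- function(parents, from, to) {
    # edge from -> to creates a cycle iff `from` is reachable from `to`... via
    # parent links: cycle iff to is an ancestor of from
    seen <- character(0)
    stack <- from
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, parents[[v]])
    }
    FALSE
  }
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (to in nms) {
      for (from in nms) {
        if (from == to) next
        has <- from %in% parents[[to]]
        if (!has) {
          if (length(parents[[to]]) >= max_parents) next
          if (would_cycle(parents, from, to)) next
          new_s <- fam(to, c(parents[[to]], from))
          if (new_s > score_v[[to]] + 1e-9) {
            parents[[to]] <- sort(c(parents[[to]], from))
            score_v[[to]] <- fam(to, parents[[to]])
            improved <- TRUE
            break
          }
        } else {
          # delete
          new_pa <- setdiff(parents[[to]], from)
          new_s <- fam(to, new_pa)
          if (new_s > score_v[[to]] + 1e-9) {
            parents[[to]] <- new_pa
            score_v[[to]] <- new_s
            improved <- TRUE
            break
          }
          # reverse
          if (length(parents[[from]]) < max_parents) {
            tmp <- parents
            tmp[[to]] <- new_pa
            if (!would_cycle(tmp, to, from)) {
              s_to <- fam(to, new_pa)
              s_from <- fam(from, c(parents[[from]], to))
              if (s_to + s_from > score_v[[to]] + score_v[[from]] + 1e-9) {
                parents[[to]] <- new_pa
                parents[[from]] <- sort(c(parents[[from]], to))
                score_v[[to]] <- s_to
                score_v[[from]] <- s_from
                improved <- TRUE
                break
              }
            }
          }
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(parents = parents, score = sum(score_v))
}

random_dag <- function(nms, max_parents) {
  n <- length(nms)
  ord <- sample(nms)
  parents <- setNames(rep(list(character(0)), n), nms)
  for (i in seq_len(n)) {
    if (i == 1) next
    k <- min(sample(0:2, 1L), i - 1L, max_parents)
    if (k > 0) parents[[ord[i]]] <- sort(sample(ord[seq_len(i - 1L)], k))
  }
  parents
}

#' Bootstrap edge support
#'
#' Resamples the data rows with replacement `B` times, learns a structure per
#' replicate with the hill-climbing AIC search, and reports per-edge selection
#' frequencies.
#'
#' @param data Data frame of discrete variables.
#' @param B Bootstrap replicates (10,000 for production analyses).
#' @param seed Integer seed.
#' @param max_parents,max_iter,restarts Hill-climb settings.
#' @return Tibble `from`, `to`, `frequency` (directed-edge selection
#'   frequency), plus `undirected_frequency` (frequency with which the pair is
#'   connected in either direction).
#' @export
bootstrap_edges <- function(data, B = 10000L, seed = 1L, max_parents = 4L,
                            max_iter = 100L, restarts = 1L) {
  bd0 <- bn_data(data)
  if (nrow(bd0$x) == 0) ts_abort("data is empty", "validation_error")
  nms <- bd0$nodes$name
  n <- length(nms)
  counts <- matrix(0, n, n, dimnames = list(nms, nms))
  set.seed(seed)
  seeds <- sample.int(2147483629L, B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
    fit <- hill_climb_aic(data[idx, , drop = FALSE], max_parents = max_parents,
                          max_iter = max_iter, restarts = restarts,
                          seed = seeds[b])
    for (child in nms) {
      for (pa in fit$parents[[child]]) counts[pa, child] <- counts[pa, child] + 1
    }
  }
  grid <- tidyr::expand_grid(from = nms, to = nms) |>
    dplyr::filter(.data$from != .data$to)
  grid$frequency <- counts[cbind(grid$from, grid$to)] / B
  und <- (counts + t(counts)) / B
  grid$undirected_frequency <- und[cbind(grid$from, grid$to)]
  grid
}
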