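# Independent oracles used across the suite. These are deliberately naive
# (closed forms, brute-force enumeration) and share no code with the package
# implementations they check.

# closed-form ordinary least squares via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  f <- (tss - rss) / (rss / (n - 2))
  list(intercept = beta[1], slope = beta[2], r2_adj = r2_adj,
       f_p = pf(f, 1, n - 2, lower.tail = FALSE),
       slope_se = sqrt(rss / (n - 2) * solve(t(X) %*% X)[2, 2]))
}

# two-sided Fisher p by full enumeration of tables with fixed margins
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact posterior by brute-force joint enumeration over all state combinations
joint_infer_oracle <- function(model, target, evidence = list()) {
  nms <- model$nodes$name
  grid <- expand.grid(lapply(model$nodes$arity, seq_len))
  names(grid) <- nms
  probs <- rep(1, nrow(grid))
  for (v in nms) {
    pa <- model$parents[[v]]
    cpt <- model$cpts[[v]]
    idx <- as.matrix(grid[, c(v, pa), drop = FALSE])
    probs <- probs * apply(idx, 1, function(i) do.call(`[`, c(list(cpt), as.list(i))))
  }
  keep <- rep(TRUE, nrow(grid))
  for (nodename in names(evidence)) {
    val <- evidence[[nodename]]
    states <- model$nodes$states[[match(nodename, nms)]]
    to_idx <- function(v) if (is.numeric(v)) as.integer(v) else match(as.character(v), states)
    if (inherits(val, "bn_not")) {
      keep <- keep & !(grid[[nodename]] %in% to_idx(val$state))
    } else {
      keep <- keep & grid[[nodename]] %in% to_idx(val)
    }
  }
  probs[!keep] <- 0
  ti <- match(target, nms)
  post <- vapply(seq_len(model$nodes$arity[ti]),
                 function(s) sum(probs[grid[[target]] == s]), numeric(1))
  post / sum(post)
}

# all labeled DAGs on the given nodes, as named parent lists
enumerate_dags <- function(nms) {
  n <- length(nms)
  pairs <- which(diag(n) == 0, arr.ind = TRUE) # ordered (from, to) pairs
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    adj <- matrix(0L, n, n)
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(sel) > 0) adj[pairs[sel, , drop = FALSE]] <- 1L
    # acyclic iff nodes with in-degree 0 can be peeled until nothing is left
    a <- adj
    acyclic <- TRUE
    while (nrow(a) > 0) {
      src <- which(colSums(a) == 0)
      if (length(src) == 0) { acyclic <- FALSE; break }
      a <- a[-src, -src, drop = FALSE]
    }
    if (!acyclic) next
    parents <- setNames(lapply(seq_len(n), function(j) nms[adj[, j] == 1L]), nms)
    out[[length(out) + 1]] <- parents
  }
  out
}

# count-and-log family score oracle using table()
family_score_oracle <- function(node, parent_set, data) {
  df <- data[, c(node, parent_set), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  r <- nlevels(factor(data[[node]]))
  q <- if (length(parent_set) == 0) 1 else
    prod(vapply(parent_set, function(p) nlevels(factor(data[[p]])), numeric(1)))
  if (nrow(df) == 0) return(list(logL = 0, k = (r - 1) * q))
  if (length(parent_set) == 0) {
    tab <- table(df[[node]])
    n <- sum(tab)
    logL <- sum(tab[tab > 0] * log(tab[tab > 0] / n))
  } else {
    cfg <- interaction(df[, parent_set, drop = FALSE], drop = FALSE)
    tab <- table(df[[node]], cfg)
    nj <- colSums(tab)
    logL <- 0
    for (j in seq_len(ncol(tab))) {
      cj <- tab[, j]
      if (nj[j] > 0) logL <- logL + sum(cj[cj > 0] * log(cj[cj > 0] / nj[j]))
    }
  }
  list(logL = logL, k = (r - 1) * q)
}

# AIC-style total network score (logL - k), by summing oracle family scores
dag_score_oracle <- function(parents, data) {
  sum(vapply(names(parents), function(v) {
    fs <- family_score_oracle(v, parents[[v]], data)
    fs$logL - fs$k
  }, numeric(1)))
}

# textbook moralization on an adjacency matrix
moralize_oracle <- function(parents) {
  nms <- names(parents)
  n <- length(nms)
  adj <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (ch in nms) for (pa in parents[[ch]]) adj[pa, ch] <- 1L
  und <- adj + t(adj)
  for (ch in nms) {
    pa <- parents[[ch]]
    if (length(pa) >= 2) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i != j) und[pa[i], pa[j]] <- und[pa[i], pa[j]] + 1L
      }
    }
  }
  edges <- which(und > 0 & upper.tri(und), arr.ind = TRUE)
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(nms[edges[, 1]], nms[edges[, 2]]),
             pmax(nms[edges[, 1]], nms[edges[, 2]]), sep = "~"))
}

# a random belief network with dirichlet-ish CPTs, for inference oracles
random_bn <- function(n_nodes, seed, max_arity = 3, n_fit = 400) {
  set.seed(seed)
  nms <- LETTERS[seq_len(n_nodes)]
  arity <- sample(2:max_arity, n_nodes, replace = TRUE)
  parents <- setNames(rep(list(character(0)), n_nodes), nms)
  for (i in seq_len(n_nodes)) {
    if (i == 1) next
    k <- sample(0:min(2, i - 1), 1)
    if (k > 0) parents[[nms[i]]] <- sample(nms[seq_len(i - 1)], k)
  }
  # build via fit_cpts on random data, then perturb towards random CPTs by
  # refitting with a pseudocount; this keeps all rows strictly positive
  df <- as.data.frame(lapply(seq_len(n_nodes), function(j) {
    factor(sample(seq_len(arity[j]), n_fit, replace = TRUE))
  }))
  names(df) <- nms
  fit_cpts(parents, df, pseudocount = runif(1, 0.2, 2))
}
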