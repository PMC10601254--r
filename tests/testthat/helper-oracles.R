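# Independent oracles: every function here recomputes a quantity by brute
# force (full enumeration, exhaustive pair counting) without going through
# the code paths it is used to check.

# full-enumeration joint table of a network: data frame of all joint states
# with their probabilities, computed by naive per-row CPT products
oracle_joint_table <- function(net) {
  grid <- expand.grid(net$levels[net$dag$nodes], stringsAsFactors = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(r) {
    prod(vapply(net$dag$nodes, function(v) {
      cpt <- net$cpts[[v]]
      idx <- c(list(grid[r, v]),
               lapply(cpt$parents, function(pa) grid[r, pa]))
      do.call(`[`, c(list(cpt$prob), idx))
    }, 0))
  }, 0)
  grid$prob <- p
  grid
}

# exact marginal of one node by full-joint enumeration
oracle_marginal <- function(net, node) {
  jt <- oracle_joint_table(net)
  out <- tapply(jt$prob, jt[[node]], sum)
  as.numeric(out[net$levels[[node]]])
}

# class posterior by enumerating the full joint and conditioning on the
# evidence (all attributes fixed, class free)
oracle_posterior <- function(model, evidence) {
  jt <- oracle_joint_table(model)
  keep <- rep(TRUE, nrow(jt))
  for (a in model$attributes) {
    keep <- keep & jt[[a]] == as.character(evidence[[a]])
  }
  sub <- jt[keep, ]
  p <- tapply(sub$prob, sub[[model$class_var]], sum)
  p <- as.numeric(p[model$levels[[model$class_var]]])
  stats::setNames(p / sum(p), model$levels[[model$class_var]])
}

# all labeled spanning trees on n nodes via Pruefer sequences; returns the
# maximum total weight and the (first) maximising edge set
oracle_mwst <- function(w) {
  labels <- rownames(w)
  n <- length(labels)
  decode <- function(seq) { # Pruefer decoding, 1-based
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, 0, 2)
    for (s in seq) {
      leaf <- which(degree == 1L)[1]
      edges <- rbind(edges, c(leaf, s))
      degree[leaf] <- degree[leaf] - 1L
      degree[s] <- degree[s] - 1L
    }
    last <- which(degree == 1L)
    rbind(edges, last)
  }
  seqs <- if (n == 2) list(integer(0)) else {
    g <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  best <- -Inf; best_edges <- NULL
  for (s in seqs) {
    e <- decode(s)
    tw <- sum(w[e])
    if (tw > best + 1e-12) {
      best <- tw
      best_edges <- cbind(pmin(labels[e[, 1]], labels[e[, 2]]),
                          pmax(labels[e[, 1]], labels[e[, 2]]))
    }
  }
  list(weight = best, edges = best_edges[order(best_edges[, 1],
                                               best_edges[, 2]), ,
                                         drop = FALSE])
}

# Mann-Whitney U for group 1 by exhaustive pair comparison
oracle_u <- function(g1, g2) {
  u <- 0
  for (a in g1) for (b in g2) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# mutual information / conditional mutual information by direct summation
# over a count table (x, y) or (x, y, c)
oracle_mi <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  total
}

oracle_cmi <- function(counts) { # 3-d array (xi, xj, c)
  p <- counts / sum(counts)
  total <- 0
  for (k in seq_len(dim(p)[3])) {
    pc <- sum(p[, , k])
    if (pc == 0) next
    for (i in seq_len(dim(p)[1])) for (j in seq_len(dim(p)[2])) {
      pijc <- p[i, j, k]
      if (pijc == 0) next
      pik <- sum(p[i, , k]); pjk <- sum(p[, j, k])
      total <- total + pijc * log2((pijc / pc) / ((pik / pc) * (pjk / pc)))
    }
  }
  total
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive); neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  s / (length(pos) * length(neg))
}
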