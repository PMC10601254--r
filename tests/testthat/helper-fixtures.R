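# Fixtures built in code: small hand-set networks and classifiers.

# v-structure A -> C <- B, binary, hand-set CPTs (admits two topological
# orders, which the order-invariance test exploits)
collider_network <- function() {
  bn_net(list(
    make_cpt("A", c("0", "1"), prob = c(0.6, 0.4)),
    make_cpt("B", c("0", "1"), prob = c(0.3, 0.7)),
    make_cpt("C", c("0", "1"), c("A", "B"),
             list(A = c("0", "1"), B = c("0", "1")),
             prob = c(0.9, 0.1, 0.5, 0.5, 0.4, 0.6, 0.05, 0.95))
  ))
}

# assemble a classifier object directly from hand-set CPTs (no fitting):
# parents maps each attribute to its full parent vector (class included)
manual_classifier <- function(class_var, class_states, attrs, parents, cpts,
                              method = "nb", k = 0L) {
  names(cpts) <- vapply(cpts, function(x) x$child, "")
  cpts <- cpts[c(class_var, attrs)]
  dag <- bn_dag(c(class_var, attrs),
                c(stats::setNames(list(character(0)), class_var), parents))
  levels <- lapply(cpts, function(x) x$levels)
  structure(list(
    method = method, k = k, class_var = class_var, attributes = attrs,
    dag = dag, cpts = cpts, levels = levels,
    class_prior = stats::setNames(as.vector(cpts[[class_var]]$prob),
                                  class_states),
    mi = NULL, cmi = NULL, smoothing = 0, n_train = 0L, call = NULL
  ), class = c("bnc", "bn_net"))
}

# random CPT rows (Dirichlet-ish via normalised uniforms, bounded away from 0)
rand_dist <- function(s) {
  p <- stats::runif(s, min = 0.05)
  p / sum(p)
}

# random classifier over m binary attributes with the given structure rule:
# "nb" (no attribute parents), "tan" (random tree), "kdb" (random <= k
# earlier parents). CPTs are random; used for oracle-equivalence checks.
random_classifier <- function(m, method = "nb", k = 2) {
  attrs <- paste0("X", seq_len(m))
  cls <- "Y"
  bin <- c("0", "1")
  parents <- stats::setNames(vector("list", m), attrs)
  for (i in seq_len(m)) {
    extra <- switch(method,
      nb = character(0),
      tan = if (i == 1) character(0) else attrs[sample.int(i - 1, 1)],
      kdb = if (i == 1) character(0) else {
        take <- min(i - 1, k)
        attrs[sample(seq_len(i - 1), take)]
      })
    parents[[attrs[i]]] <- c(cls, extra)
  }
  cpts <- list(make_cpt(cls, bin, prob = rand_dist(2)))
  for (i in seq_len(m)) {
    pa <- parents[[attrs[i]]]
    pstates <- stats::setNames(rep(list(bin), length(pa)), pa)
    ncfg <- 2^length(pa)
    prob <- as.vector(vapply(seq_len(ncfg), function(j) rand_dist(2),
                             numeric(2)))
    cpts <- c(cpts, list(make_cpt(attrs[i], bin, pa, pstates, prob)))
  }
  manual_classifier(cls, bin, attrs, parents, cpts, method = method,
                    k = as.integer(k))
}

# data frame of factors from explicit per-cell counts: counts is a named list
# mapping "x|y|..." value combos to counts; cols gives column names
counts_to_df <- function(counts, cols) {
  rows <- do.call(rbind, lapply(names(counts), function(key) {
    vals <- strsplit(key, "|", fixed = TRUE)[[1]]
    matrix(rep(vals, counts[[key]]), ncol = length(vals), byrow = TRUE)
  }))
  d <- as.data.frame(rows, stringsAsFactors = TRUE)
  names(d) <- cols
  d
}

# a known 2-dependence ground truth over 5 attributes, used for
# structure-recovery checks. Direct class effects decrease down the order
# (3.2, 1.7, 1.1, 0.55 on the logit) and were balanced against the
# attribute-attribute effects so the exact marginal MI(Xi; Y) is strictly
# decreasing in i (0.598, 0.459, 0.361, 0.298, 0.189 bits) — the insertion
# order the k-dependence construction must find.
kdb2_ground_truth <- function() {
  bin <- c("0", "1")
  b <- function(child, parents, p1) {
    pstates <- stats::setNames(rep(list(bin), length(parents)), parents)
    make_cpt(child, bin, parents, pstates, as.vector(rbind(1 - p1, p1)))
  }
  # logit contributions per parent configuration (class varies fastest)
  Yv <- c(0, 1, 0, 1, 0, 1, 0, 1)
  P1 <- c(0, 0, 1, 1, 0, 0, 1, 1)
  P2 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  lg <- function(y, a) stats::plogis(-(y + 2 * a) / 2 + y * Yv + a * P1 +
                                       a * P2)
  # attribute parents (beyond the class): X1: -, X2: X1, X3: X1 X2,
  # X4: X2 X3, X5: X3 X4  — a valid k = 2 structure for the order X1..X5
  bn_net(list(
    make_cpt("Y", bin, prob = c(0.5, 0.5)),
    b("X1", "Y", c(0.08, 0.92)),
    b("X2", c("Y", "X1"),
      stats::plogis(-(3.2 + 0.9) / 2 + 3.2 * c(0, 1, 0, 1) +
                      0.9 * c(0, 0, 1, 1))),
    b("X3", c("Y", "X1", "X2"), lg(1.7, 1.1)),
    b("X4", c("Y", "X2", "X3"), lg(1.1, 1.5)),
    b("X5", c("Y", "X3", "X4"), lg(0.55, 1.5))
  ))
}

kdb2_true_parents <- list(X1 = character(0), X2 = "X1", X3 = c("X1", "X2"),
                          X4 = c("X2", "X3"), X5 = c("X3", "X4"))

# simple chain A -> B -> C with strong binary CPTs for structure recovery
strong_chain <- function() {
  bin <- c("0", "1")
  bn_net(list(
    make_cpt("A", bin, prob = c(0.5, 0.5)),
    make_cpt("B", bin, "A", list(A = bin), prob = c(0.85, 0.15, 0.15, 0.85)),
    make_cpt("C", bin, "B", list(B = bin), prob = c(0.85, 0.15, 0.15, 0.85))
  ))
}

# collider with marginal dependence on both parents (logistic, not XOR, so
# marginal-independence pruning does not hide the child)
strong_collider <- function() {
  bin <- c("0", "1")
  p1 <- stats::plogis(-2.2 + 2.2 * c(0, 1, 0, 1) + 2.2 * c(0, 0, 1, 1))
  bn_net(list(
    make_cpt("A", bin, prob = c(0.5, 0.5)),
    make_cpt("B", bin, prob = c(0.5, 0.5)),
    make_cpt("C", bin, c("A", "B"), list(A = bin, B = bin),
             prob = as.vector(rbind(1 - p1, p1)))
  ))
}
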