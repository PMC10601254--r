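#' Fit a Bayesian network classifier
#'
#' Fits one of three discrete Bayesian network classifiers to a cohort table:
#'
#' * `"nb"` — naive Bayes: the class is the sole parent of every attribute,
#'   so \eqn{P(x, c) = P(c)\prod_j P(a_j \mid c)}.
#' * `"tan"` — tree-augmented naive Bayes: attribute pairs are weighted by
#'   class-conditional mutual information
#'   ([conditional_mutual_information()]); a maximum-weight spanning tree is
#'   grown by sorted greedy edge selection with cycle rejection, its edges are
#'   oriented away from a root, and the class is added as a parent of every
#'   attribute. Each attribute thus has at most one attribute parent.
#' * `"kdb"` — k-dependence Bayesian classifier: attributes are sorted by
#'   decreasing mutual information with the class ([mutual_information()]);
#'   the attribute at position \eqn{i} receives as parents the
#'   \eqn{\min(i-1, k)} earlier attributes with the highest conditional
#'   mutual information given the class, plus the class, so
#'   \eqn{P(x, c) = P(c)\prod_i P(x_i \mid c, \pi_{x_i})}.
#'
#' MI/CMI rankings use unsmoothed empirical frequencies; all CPTs (and the
#' class prior) use additive smoothing (default 1). Ties in edge sorting,
#' attribute ordering and parent selection are broken lexicographically by
#' variable name, so fits are reproducible across platforms.
#'
#' @param formula Model formula, e.g. `np ~ .` (all other columns as
#'   attributes) or `np ~ ptb + crp + afv`.
#' @param data Cohort data frame of factors.
#' @param method `"nb"`, `"tan"` or `"kdb"`.
#' @param k Maximum number of attribute parents per attribute (`"kdb"` only;
#'   default 2, the usual small-order setting). `k = 0` reduces to naive
#'   Bayes, `k = 1` to a TAN-like forest bound.
#' @param smoothing Additive pseudo-count for CPT estimation (default 1).
#' @param root TAN root attribute; default the attribute with the highest
#'   mutual information with the class.
#' @return An object of class `bnc` (and `bn_net`): the DAG over
#'   \{class\} U attributes, one CPT per node, the class prior, and the MI /
#'   CMI tables used to build the structure. Supports [predict()],
#'   [class_posterior()], `print`, `summary`, `coef`, `logLik`, `plot`,
#'   [query_cpt()], [joint_probability()] and [sample_cohort()].
#' @examples
#' cohort <- sample_cohort(default_ground_truth(), 800, seed = 1)
#' fit <- bnc(np ~ ., cohort, method = "tan")
#' fit
#' predict(fit, cohort[1:3, ])
#' @export
bnc <- function(formula, data, method = c("nb", "tan", "kdb"), k = 2,
                smoothing = 1, root = NULL) {
  method <- match.arg(method)
  vars <- parse_bnc_formula(formula, data)
  class_var <- vars$class_var
  attrs <- vars$attributes
  if (class_var %in% attrs) stop("class variable cannot be an attribute")
  if (length(attrs) < 1) stop("at least one attribute is required")
  data <- as_cohort(data[c(class_var, attrs)])
  if (nrow(data) == 0) stop("empty training table")

  mi <- vapply(attrs, function(a) mutual_information(data, a, class_var), 0)
  cmi <- NULL

  if (method == "nb") {
    k_eff <- 0L
    parents <- stats::setNames(lapply(attrs, function(a) class_var), attrs)
    order_attrs <- attrs
  } else if (method == "tan") {
    if (length(attrs) < 2) stop("TAN needs at least two attributes")
    k_eff <- 1L
    cmi <- cmi_matrix(data, attrs, class_var)
    tree <- mwst_kruskal(cmi)
    if (is.null(root)) {
      root <- attrs[order(-mi, attrs)][1] # highest MI, ties lexicographic
    }
    if (!root %in% attrs) stop("root must be one of the attributes")
    tree_par <- orient_tree(tree, attrs, root)
    parents <- stats::setNames(lapply(attrs, function(a) {
      c(class_var, tree_par[[a]])
    }), attrs)
    order_attrs <- attrs
  } else {
    n <- length(attrs)
    if (k < 0 || k > n - 1) {
      stop("k must satisfy 0 <= k <= ", n - 1, " (got ", k, ")")
    }
    k_eff <- as.integer(k)
    order_attrs <- attrs[order(-mi, attrs)] # MI desc, ties lexicographic
    cmi <- cmi_matrix(data, attrs, class_var)
    parents <- stats::setNames(vector("list", n), order_attrs)
    for (i in seq_len(n)) {
      a <- order_attrs[i]
      cand <- order_attrs[seq_len(i - 1)]
      m <- min(i - 1, k_eff)
      sel <- if (m > 0) cand[order(-cmi[a, cand], cand)][seq_len(m)]
             else character(0)
      parents[[a]] <- c(class_var, sel)
    }
    parents <- parents[attrs]
  }

  nodes <- c(class_var, order_attrs)
  dag <- bn_dag(nodes, parents)
  cpts <- stats::setNames(vector("list", length(nodes)), nodes)
  cpts[[class_var]] <- fit_cpt(data, class_var, character(0), smoothing)
  for (a in attrs) cpts[[a]] <- fit_cpt(data, a, dag$parents[[a]], smoothing)
  levels <- lapply(cpts, function(x) x$levels)

  structure(list(
    method = method, k = k_eff, class_var = class_var, attributes = attrs,
    dag = dag, cpts = cpts, levels = levels,
    class_prior = cpt_row(cpts[[class_var]]),
    mi = mi, cmi = cmi, smoothing = smoothing,
    n_train = nrow(data), call = match.call()
  ), class = c("bnc", "bn_net"))
}

parse_bnc_formula <- function(formula, data) {
  if (!inherits(formula, "formula") || length(formula) != 3) {
    stop("formula must have the form class ~ attributes")
  }
  class_var <- as.character(formula[[2]])
  tt <- stats::terms(formula, data = data)
  attributes <- attr(tt, "term.labels")
  if (!class_var %in% names(data)) stop("unknown class variable: ", class_var)
  missing <- setdiff(attributes, names(data))
  if (length(missing)) {
    stop("unknown attribute(s): ", paste(missing, collapse = ", "))
  }
  list(class_var = class_var, attributes = attributes)
}

cmi_matrix <- function(data, attrs, class_var) {
  n <- length(attrs)
  m <- matrix(0, n, n, dimnames = list(attrs, attrs))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      w <- conditional_mutual_information(data, attrs[i], attrs[j], class_var)
      m[i, j] <- w
      m[j, i] <- w
    }
  }
  m
}

# maximum-weight spanning tree by sorted greedy selection with cycle
# rejection (Kruskal). Ties: higher weight first, then lexicographic on the
# sorted endpoint pair. Returns a 2-column matrix of undirected edges.
mwst_kruskal <- function(w) {
  attrs <- rownames(w)
  n <- length(attrs)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  a <- attrs[pairs[, 1]]; b <- attrs[pairs[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  ord <- order(-w[pairs], lo, hi)
  comp <- stats::setNames(seq_len(n), attrs) # union-find, path-free (small n)
  edges <- matrix(character(0), 0, 2)
  for (e in ord) {
    ca <- comp[[a[e]]]; cb <- comp[[b[e]]]
    if (ca != cb) {
      edges <- rbind(edges, c(lo[e], hi[e]))
      comp[comp == cb] <- ca
      if (nrow(edges) == n - 1) break
    }
  }
  edges
}

# orient undirected tree edges away from the root (BFS); returns named list
# attr -> its single tree parent (character(0) for the root / isolated nodes)
orient_tree <- function(edges, attrs, root) {
  adj <- stats::setNames(vector("list", length(attrs)), attrs)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  par <- stats::setNames(vector("list", length(attrs)), attrs)
  for (a in attrs) par[[a]] <- character(0)
  visited <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in setdiff(adj[[v]], visited)) {
        par[[u]] <- v
        visited <- c(visited, u)
        nxt <- c(nxt, u)
      }
    }
    frontier <- nxt
  }
  par
}

#' Number of attribute-attribute dependencies of a k-dependence structure
#'
#' \eqn{\sum_{i=1}^{n} \min(i-1, k)}: the count of attribute-attribute arcs a
#' k-dependence classifier over `n_attributes` attributes carries (k = 1
#' gives the TAN tree's n-1 edges; k = 0 gives naive Bayes' 0).
#'
#' @param n_attributes Number of attributes (>= 1).
#' @param k Dependence order, `0 <= k <= n_attributes - 1`.
#' @return Integer arc count.
#' @examples
#' count_dependencies(17, 2) # 31
#' @export
count_dependencies <- function(n_attributes, k) {
  if (k < 0 || k > n_attributes - 1) {
    stop("k must satisfy 0 <= k <= n_attributes - 1")
  }
  as.integer(sum(pmin(seq_len(n_attributes) - 1, k)))
}

#' Class posterior given full attribute evidence
#'
#' \eqn{P(c \mid x) \propto P(c) \prod_j P(a_j \mid \mathrm{pa}(a_j))},
#' evaluated in log space and normalized — the Bayes-rule readout all three
#' classifier variants share (the evidence term is constant and cancels).
#'
#' @param model A fitted `bnc`.
#' @param evidence Named list/vector (or one-row data frame) assigning a
#'   state to every attribute.
#' @return Named numeric vector over class states, summing to 1.
#' @export
class_posterior <- function(model, evidence) {
  if (is.data.frame(evidence)) {
    stopifnot(nrow(evidence) == 1)
    evidence <- lapply(evidence, as.character)
  }
  evidence <- evidence[names(evidence) %in% model$attributes]
  missing <- setdiff(model$attributes, names(evidence))
  if (length(missing)) {
    stop("evidence missing attribute(s): ", paste(missing, collapse = ", "))
  }
  d <- data.frame(lapply(evidence, as.character), stringsAsFactors = FALSE,
                  check.names = FALSE)
  posterior_matrix(model, d)[1, ]
}

# n x nclass matrix of posteriors, log-space with log-sum-exp normalization
posterior_matrix <- function(model, newdata) {
  cls <- model$levels[[model$class_var]]
  codes <- cohort_codes(as_cohort(newdata[model$attributes]),
                        model$levels[model$attributes])
  codes <- cbind(codes, matrix(1L, nrow(codes), 1,
                               dimnames = list(NULL, model$class_var)))
  lp <- matrix(0, nrow(newdata), length(cls), dimnames = list(NULL, cls))
  for (ci in seq_along(cls)) {
    codes[, model$class_var] <- ci
    acc <- rep(log(model$class_prior[ci]), nrow(newdata))
    for (a in model$attributes) {
      acc <- acc + cpt_loglik_rows(model$cpts[[a]], codes)
    }
    lp[, ci] <- acc
  }
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post / rowSums(post)
}

#' Predict classes or posteriors from a fitted classifier
#'
#' The predicted class is the posterior argmax; exact posterior ties are
#' broken in favour of the earlier class level.
#'
#' @param object A fitted `bnc`.
#' @param newdata Data frame covering all attribute columns.
#' @param type `"class"` (default) for the argmax labels, `"posterior"` for
#'   the full posterior matrix.
#' @param ... Unused.
#' @return A factor of predicted classes, or an `n x nclass` posterior
#'   matrix.
#' @export
predict.bnc <- function(object, newdata, type = c("class", "posterior"),
                        ...) {
  type <- match.arg(type)
  missing <- setdiff(object$attributes, names(newdata))
  if (length(missing)) {
    stop("newdata missing attribute(s): ", paste(missing, collapse = ", "))
  }
  post <- posterior_matrix(object, newdata)
  if (type == "posterior") return(post)
  cls <- object$levels[[object$class_var]]
  idx <- apply(post, 1, which.max) # first maximum: documented tie-break
  factor(cls[idx], levels = cls)
}

#' @export
print.bnc <- function(x, ...) {
  lab <- c(nb = "Naive Bayes", tan = "Tree-augmented naive Bayes",
           kdb = sprintf("%d-dependence Bayesian classifier", x$k))[[x$method]]
  n_aa <- sum(lengths(x$dag$parents)) - length(x$attributes) -
    length(x$dag$parents[[x$class_var]])
  cat(lab, "\n")
  cat("  class:", x$class_var, "  attributes:", length(x$attributes),
      "  attribute-attribute arcs:", n_aa, "\n")
  cat("  trained on", x$n_train, "records, smoothing =", x$smoothing, "\n")
  cat("  class prior:",
      paste(names(x$class_prior), round(x$class_prior, 4), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.bnc <- function(object, ...) {
  print(object)
  cat("\nStructure:\n")
  for (a in object$attributes) {
    cat("  ", paste(object$dag$parents[[a]], collapse = ", "), " -> ", a,
        "\n", sep = "")
  }
  cat("\nMutual information with class (bits):\n")
  print(round(sort(object$mi, decreasing = TRUE), 4))
  invisible(object)
}

#' @export
coef.bnc <- function(object, ...) object$cpts

#' Training-set log-likelihood of a fitted classifier
#'
#' @param object A fitted `bnc`.
#' @param data Data frame to score (must contain class and attributes).
#' @param ... Unused.
#' @return `logLik` object: sum over rows of
#'   \eqn{\log P(c) + \sum_j \log P(a_j \mid \mathrm{pa}(a_j))}.
#' @export
logLik.bnc <- function(object, data, ...) {
  data <- as_cohort(data[c(object$class_var, object$attributes)])
  codes <- cohort_codes(data, object$levels)
  ll <- 0
  for (v in object$dag$nodes) {
    ll <- ll + sum(cpt_loglik_rows(object$cpts[[v]], codes))
  }
  npar <- sum(vapply(object$cpts, function(cpt) {
    (length(cpt$levels) - 1) * prod(dim(cpt$prob)[-1])
  }, 0))
  structure(ll, df = npar, nobs = nrow(data), class = "logLik")
}

#' Plot a classifier or network structure
#'
#' Simple base-graphics rendering: nodes on a circle (the class, if any, in
#' the centre), directed arcs as arrows.
#'
#' @param x A `bnc`, `bn_net` or `bn_dag`.
#' @param ... Passed to [plot.default()].
#' @export
plot.bnc <- function(x, ...) plot_bn_graph(x$dag, center = x$class_var, ...)

#' @export
plot.bn_net <- function(x, ...) plot_bn_graph(x$dag, ...)

#' @export
plot.bn_dag <- function(x, ...) plot_bn_graph(x, ...)

plot_bn_graph <- function(dag, center = NULL, ...) {
  nodes <- dag$nodes
  ring <- setdiff(nodes, center)
  theta <- seq(0, 2 * pi, length.out = length(ring) + 1)[-1]
  xy <- rbind(if (!is.null(center)) matrix(0, length(center), 2),
              cbind(cos(theta), sin(theta)))
  rownames(xy) <- c(center, ring)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1, ...)
  e <- dag_edges(dag)
  for (i in seq_len(nrow(e))) {
    p1 <- xy[e[i, 1], ]; p2 <- xy[e[i, 2], ]
    sh <- 0.12 * (p2 - p1) / sqrt(sum((p2 - p1)^2))
    graphics::arrows(p1[1] + sh[1], p1[2] + sh[2], p2[1] - sh[1],
                     p2[2] - sh[2], length = 0.08, col = "grey40")
  }
  if (!is.null(dag$undirected)) {
    for (i in seq_len(nrow(dag$undirected))) {
      p1 <- xy[dag$undirected[i, 1], ]; p2 <- xy[dag$undirected[i, 2], ]
      graphics::segments(p1[1], p1[2], p2[1], p2[2], col = "grey60", lty = 2)
    }
  }
  graphics::text(xy, labels = rownames(xy), font = 2)
  invisible(xy)
}
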