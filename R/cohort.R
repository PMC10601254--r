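#' Build a conditional probability table by hand
#'
#' Constructor for hand-specified CPTs, used to assemble ground-truth
#' networks. `prob` holds \eqn{P(child = s \mid parents = g)} with the child
#' state as the first array dimension and one further dimension per parent,
#' in the order of `parent_states`.
#'
#' @param child Node name.
#' @param states Character vector of the child's state labels.
#' @param parents Character vector of parent names (default none).
#' @param parent_states Named list of parent state-label vectors, one per
#'   parent, same order as `parents`.
#' @param prob Numeric vector (no parents) or array of conditional
#'   probabilities; each conditional distribution must sum to 1 within 1e-9.
#' @return A `bn_cpt`.
#' @export
make_cpt <- function(child, states, parents = character(0),
                     parent_states = list(), prob) {
  states <- as.character(states)
  dims <- c(length(states), unname(vapply(parent_states, length, 1L)))
  dn <- c(list(states), lapply(parent_states, as.character))
  names(dn) <- c(child, parents)
  prob <- array(as.numeric(prob), dim = dims, dimnames = dn)
  sums <- if (length(parents)) apply(prob, seq_along(dims)[-1], sum)
          else sum(prob)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("conditional distributions of ", child, " do not sum to 1")
  }
  structure(list(child = child, parents = parents, levels = states,
                 prob = prob), class = "bn_cpt")
}

#' Assemble a Bayesian network from CPTs
#'
#' Derives the DAG from the CPTs' parent lists, checks acyclicity and checks
#' that each CPT's parent dimensions match the parents' own state labels.
#'
#' @param cpts List of `bn_cpt`, one per node (order fixes the node order).
#' @return A `bn_net`: list with `dag` (`bn_dag`), `levels` (named list of
#'   state labels) and `cpts` (named list of `bn_cpt`).
#' @export
bn_net <- function(cpts) {
  nodes <- vapply(cpts, function(x) x$child, "")
  names(cpts) <- nodes
  parents <- lapply(cpts, function(x) x$parents)
  dag <- bn_dag(nodes, parents)
  levels <- lapply(cpts, function(x) x$levels)
  for (v in nodes) {
    dn <- dimnames(cpts[[v]]$prob)
    for (j in seq_along(cpts[[v]]$parents)) {
      pn <- cpts[[v]]$parents[j]
      if (!identical(dn[[j + 1]], levels[[pn]])) {
        stop("CPT of ", v, " disagrees with state labels of parent ", pn)
      }
    }
  }
  structure(list(dag = dag, levels = levels, cpts = cpts), class = "bn_net")
}

#' @export
print.bn_net <- function(x, ...) {
  card <- vapply(x$levels, length, 1L)
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      sum(lengths(x$dag$parents)), "arcs\n")
  cat("  cardinalities:", paste0(names(card), "(", card, ")", collapse = " "),
      "\n")
  invisible(x)
}

#' A three-node chain network for demonstrations
#'
#' Binary chain A -> B -> C with fixed hand-set CPTs; handy for examples and
#' for checking sampling and inference against exact enumeration.
#'
#' @return A `bn_net` over nodes A, B, C.
#' @export
chain_network <- function() {
  bn_net(list(
    make_cpt("A", c("0", "1"), prob = c(0.7, 0.3)),
    make_cpt("B", c("0", "1"), "A", list(A = c("0", "1")),
             prob = c(0.8, 0.2, 0.2, 0.8)),
    make_cpt("C", c("0", "1"), "B", list(B = c("0", "1")),
             prob = c(0.9, 0.1, 0.3, 0.7))
  ))
}

# binary-child CPT from P(child = "1") per parent configuration
bin_cpt <- function(child, parents = character(0), parent_states = list(),
                    p1) {
  p1 <- as.numeric(p1)
  prob <- as.vector(rbind(1 - p1, p1))
  make_cpt(child, c("0", "1"), parents, parent_states, prob)
}

TRI <- c("1", "2", "3")
BIN <- c("0", "1")

#' The default ground-truth cohort network
#'
#' A fixed, versioned 17-node discrete Bayesian network emulating a cohort of
#' pregnant women with diabetes mellitus and the binary outcome neonatal
#' pneumonia (`np`, marginal prevalence ~ 15.2%). Sixteen predictors: maternal
#' age band (`age`), two-hour postprandial glucose band (`pbg`), parity (`p`),
#' gestational hypertension (`hdop`), preterm birth (`ptb`), premature rupture
#' of membranes (`prom`), macrosomia (`ms`), neonatal respiratory distress
#' syndrome (`nrds`), neonatal jaundice (`nnj`), postpartum haemorrhage
#' (`pph`), neonatal asphyxia (`na`), neonatal growth restriction (`ngr`),
#' number of pregnancies (`g`), amniotic fluid volume (`afv`), amniotic fluid
#' cleanliness (`afc`) and C-reactive protein band (`crp`). Binary variables
#' are coded "0"/"1", three-level ordinal variables "1"/"2"/"3".
#'
#' The DAG encodes clinically motivated dependencies: glucose raises the risk
#' of membrane rupture and hypertension (`pbg -> prom`, `pbg -> hdop`), fluid
#' volume conditions fluid cleanliness (`afv -> afc`), and the outcome and
#' fluid cleanliness are co-parents of neonatal jaundice (`np -> nnj <- afc`).
#' The outcome depends on preterm birth, C-reactive protein, fluid volume,
#' hypertension and age through a logistic CPT whose intercept is a fixed
#' constant calibrated once (by exact marginalization) so that
#' \eqn{P(np = 1) \approx 0.152}.
#'
#' @return A `bn_net` over the 17 variables.
#' @export
default_ground_truth <- function() {
  lo <- function(ptb, crp, afv, hdop, age) {
    -4.332409 + 1.4 * ptb + 0.7 * (crp - 1) + 0.9 * (afv - 1) +
      0.9 * hdop + 0.45 * (age - 1)
  }
  np_grid <- expand.grid(ptb = 0:1, crp = 1:3, afv = 1:3, hdop = 0:1,
                         age = 1:3)
  np_p1 <- stats::plogis(with(np_grid, lo(ptb, crp, afv, hdop, age)))
  bn_net(list(
    bin_cpt("np", c("ptb", "crp", "afv", "hdop", "age"),
            list(ptb = BIN, crp = TRI, afv = TRI, hdop = BIN, age = TRI),
            np_p1),
    make_cpt("pbg", TRI, prob = c(0.45, 0.35, 0.20)),
    make_cpt("g", TRI, prob = c(0.50, 0.30, 0.20)),
    make_cpt("age", TRI, "pbg", list(pbg = TRI),
             prob = c(0.60, 0.30, 0.10, 0.30, 0.45, 0.25, 0.10, 0.35, 0.55)),
    bin_cpt("p", "g", list(g = TRI), c(0.05, 0.50, 0.95)),
    bin_cpt("hdop", "pbg", list(pbg = TRI), c(0.08, 0.20, 0.45)),
    bin_cpt("prom", "pbg", list(pbg = TRI), c(0.10, 0.25, 0.50)),
    bin_cpt("ptb", "prom", list(prom = BIN), c(0.08, 0.45)),
    make_cpt("afv", TRI, "g", list(g = TRI),
             prob = c(0.78, 0.16, 0.06, 0.22, 0.46, 0.32, 0.06, 0.26, 0.68)),
    make_cpt("afc", TRI, "afv", list(afv = TRI),
             prob = c(0.75, 0.18, 0.07, 0.35, 0.40, 0.25, 0.12, 0.33, 0.55)),
    make_cpt("crp", TRI, "afc", list(afc = TRI),
             prob = c(0.65, 0.25, 0.10, 0.30, 0.45, 0.25, 0.10, 0.35, 0.55)),
    bin_cpt("nnj", c("np", "afc"), list(np = BIN, afc = TRI),
            c(0.10, 0.70, 0.18, 0.80, 0.28, 0.90)),
    bin_cpt("nrds", "np", list(np = BIN), c(0.06, 0.55)),
    bin_cpt("na", "np", list(np = BIN), c(0.04, 0.35)),
    bin_cpt("ngr", c("np", "hdop"), list(np = BIN, hdop = BIN),
            c(0.05, 0.35, 0.18, 0.60)),
    bin_cpt("pph", "np", list(np = BIN), c(0.10, 0.30)),
    bin_cpt("ms", c("np", "age"), list(np = BIN, age = TRI),
            c(0.05, 0.15, 0.12, 0.30, 0.25, 0.50))
  ))
}

#' Exact marginal distribution of one node
#'
#' Marginalizes the network's joint distribution over the node's ancestral
#' set by full enumeration — exact, feasible whenever the ancestral state
#' space is modest (the default ground truth's outcome has ~1e4 ancestral
#' states).
#'
#' @param net A `bn_net`.
#' @param node Node name.
#' @return Named numeric vector over the node's states, summing to 1.
#' @export
exact_marginal <- function(net, node) {
  if (!node %in% net$dag$nodes) stop("unknown node: ", node)
  keep <- c(ancestors_of(net$dag, node), node)
  keep <- keep[order(match(keep, net$dag$nodes))]
  grid <- expand.grid(net$levels[keep], stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in keep) {
    cpt <- net$cpts[[v]]
    codes <- cohort_codes(grid, c(stats::setNames(list(net$levels[[v]]), v),
                                  stats::setNames(net$levels[cpt$parents],
                                                  cpt$parents)))
    p <- p * exp(cpt_loglik_rows(cpt, codes))
  }
  out <- tapply(p, grid[[node]], sum)
  out <- out[net$levels[[node]]]
  stats::setNames(as.numeric(out), net$levels[[node]])
}

#' Draw a synthetic cohort by ancestral sampling
#'
#' Samples `n` records from the network: nodes are visited in topological
#' order and each is drawn from its CPT row given the already-drawn parent
#' states. A private RNG stream is seeded from `seed`; the caller's RNG state
#' is untouched and identical `(network, n, seed)` give identical tables.
#'
#' @param net A `bn_net` (e.g. [default_ground_truth()]).
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param order Optional topological order of the nodes to sample in
#'   (defaults to [topological_order()]); any valid order yields the same
#'   distribution.
#' @return A data frame of factors, one column per node in the network's node
#'   order, with the declared state labels as levels.
#' @examples
#' cohort <- sample_cohort(default_ground_truth(), 500, seed = 1)
#' mean(cohort$np == "1")
#' @export
sample_cohort <- function(net, n, seed, order = NULL) {
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be a single integer >= 0")
  n <- as.integer(n)
  if (is.null(order)) {
    order <- topological_order(net$dag)
  } else if (!identical(sort(order), sort(net$dag$nodes))) {
    stop("order must be a permutation of the network's nodes")
  }
  for (v in order) { # verify the supplied order is topological
    for (pa in net$dag$parents[[v]]) {
      if (match(pa, order) > match(v, order)) {
        stop("order is not topological: ", pa, " -> ", v)
      }
    }
  }
  cols <- stats::setNames(vector("list", length(net$dag$nodes)),
                          net$dag$nodes)
  local_seed(seed, {
    for (v in order) {
      cpt <- net$cpts[[v]]
      s <- length(cpt$levels)
      if (n == 0) {
        cols[[v]] <- integer(0)
        next
      }
      if (length(cpt$parents) == 0) {
        pm <- matrix(as.vector(cpt$prob), s, 1)
        cfg <- rep(1L, n)
      } else {
        pm <- matrix(cpt$prob, nrow = s) # columns = parent configurations
        dims <- dim(cpt$prob)[-1]
        cfg <- rep(1L, n)
        mult <- 1L
        for (j in seq_along(cpt$parents)) {
          cfg <- cfg + (cols[[cpt$parents[j]]] - 1L) * mult
          mult <- mult * dims[j]
        }
      }
      cum <- apply(pm, 2, cumsum)
      cum[s, ] <- 1 # guard against round-off at the top of the scale
      u <- stats::runif(n)
      cols[[v]] <- 1L + as.integer(
        colSums(cum[, cfg, drop = FALSE] < rep(u, each = s)))
    }
  })
  out <- data.frame(lapply(net$dag$nodes, function(v) {
    factor(net$levels[[v]][cols[[v]]], levels = net$levels[[v]])
  }), stringsAsFactors = FALSE)
  names(out) <- net$dag$nodes
  out
}

# run expr under a private RNG stream; caller's .Random.seed is restored
local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with a header row and no row-name column; all values are
#' state labels. Reading coerces every column back to a factor.
#'
#' @param cohort Data frame of factors.
#' @param file Path.
#' @param levels Optional named list of state labels used to set factor
#'   levels on read (e.g. `default_ground_truth()$levels`); otherwise levels
#'   are the sorted observed values.
#' @return `write_cohort_csv` returns `file` invisibly; `read_cohort_csv`
#'   returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file, levels = NULL) {
  d <- utils::read.csv(file, colClasses = "character",
                       fileEncoding = "UTF-8", check.names = FALSE)
  for (v in names(d)) {
    lv <- if (!is.null(levels) && v %in% names(levels)) levels[[v]]
          else sort(unique(d[[v]]))
    d[[v]] <- factor(d[[v]], levels = lv)
  }
  d
}

#' Serialize / restore a network as JSON
#'
#' The document carries `variables` (name, cardinality, state labels),
#' `edges` and one flattened CPT per node, enough to reconstruct the network
#' exactly.
#'
#' @param net A `bn_net`.
#' @param file Path to a JSON file.
#' @return `write_bn_json` returns `file` invisibly; `read_bn_json` returns
#'   the reconstructed `bn_net`.
#' @export
write_bn_json <- function(net, file) {
  doc <- list(
    variables = lapply(net$dag$nodes, function(v) {
      list(name = v, cardinality = length(net$levels[[v]]),
           state_labels = net$levels[[v]])
    }),
    edges = apply(dag_edges(net$dag), 1, function(r) {
      list(from = r[[1]], to = r[[2]])
    }),
    cpts = lapply(net$dag$nodes, function(v) {
      cpt <- net$cpts[[v]]
      list(child = v, parents = cpt$parents,
           dim = dim(cpt$prob), prob = as.vector(cpt$prob))
    })
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  levels <- list()
  for (v in doc$variables) levels[[v$name]] <- as.character(v$state_labels)
  cpts <- lapply(doc$cpts, function(cc) {
    parents <- as.character(unlist(cc$parents))
    make_cpt(cc$child, levels[[cc$child]], parents,
             stats::setNames(levels[parents], parents),
             array(as.numeric(unlist(cc$prob)), dim = unlist(cc$dim)))
  })
  bn_net(cpts)
}
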