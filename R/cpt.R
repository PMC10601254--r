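#' Estimate a conditional probability table from data
#'
#' Maximum-likelihood counts with additive (Laplace) smoothing:
#' \deqn{P(child = s \mid parents = g) = \frac{n_{s,g} + \alpha}{n_g + \alpha
#' |states(child)|}}
#' Parent configurations never observed are uniform when `smoothing = 0`
#' (0/0 is resolved to the uniform distribution) and shrink towards uniform
#' otherwise. The table covers the full Cartesian product of the declared
#' factor levels, not just observed combinations.
#'
#' @param data A data frame of factors (a cohort table).
#' @param child Column name of the child variable.
#' @param parents Character vector of parent column names (possibly empty).
#' @param smoothing Non-negative pseudo-count added to every cell; default 1.
#' @return A `bn_cpt`: list with `child`, `parents`, `levels` (child states)
#'   and `prob`, an array whose first dimension indexes child states and whose
#'   remaining dimensions index parent states; every conditional distribution
#'   (slice along dim 1) sums to 1.
#' @examples
#' d <- data.frame(x = factor(c(0, 0, 1, 1, 1)), y = factor(c(0, 1, 0, 1, 1)))
#' fit_cpt(d, "y", "x", smoothing = 1)
#' @export
fit_cpt <- function(data, child, parents = character(0), smoothing = 1) {
  if (smoothing < 0) stop("smoothing must be >= 0")
  cols <- c(child, parents)
  if (!all(cols %in% names(data))) {
    stop("missing column(s): ", paste(setdiff(cols, names(data)), collapse = ", "))
  }
  data <- as_cohort(data[cols])
  counts <- table(data) # dims: child first, then parents
  counts <- array(as.numeric(counts), dim = dim(counts),
                  dimnames = dimnames(counts))
  nstates <- dim(counts)[1]
  sm <- counts + smoothing
  if (length(parents) == 0) {
    tot <- sum(sm)
    prob <- if (tot > 0) sm / tot else rep(1 / nstates, nstates)
    prob <- array(prob, dim = dim(counts), dimnames = dimnames(counts))
  } else {
    tot <- apply(sm, seq_along(dim(sm))[-1], sum)
    prob <- sweep(sm, seq_along(dim(sm))[-1], tot, "/")
    if (any(tot == 0)) { # unobserved configuration with smoothing = 0
      uni <- slice.index(prob, 1) > 0 & is.nan(prob)
      prob[uni] <- 1 / nstates
    }
  }
  structure(list(child = child, parents = parents,
                 levels = dimnames(counts)[[1]], prob = prob),
            class = "bn_cpt")
}

#' @export
print.bn_cpt <- function(x, digits = 4, ...) {
  cat("CPT for", x$child,
      if (length(x$parents)) paste("given", paste(x$parents, collapse = ", "))
      else "(no parents)", "\n")
  print(round(x$prob, digits))
  invisible(x)
}

# P(child = value | parents = assignment) for one configuration
cpt_prob <- function(cpt, value, assignment = NULL) {
  idx <- c(list(as.character(value)),
           as.list(as.character(unlist(assignment[cpt$parents]))))
  unname(do.call(`[`, c(list(cpt$prob), idx)))
}

# conditional distribution row for one parent configuration
cpt_row <- function(cpt, assignment = NULL) {
  if (length(cpt$parents) == 0) {
    p <- as.vector(cpt$prob)
    names(p) <- cpt$levels
    return(p)
  }
  idx <- c(list(quote(expr = )),
           as.list(as.character(unlist(assignment[cpt$parents]))))
  p <- do.call(`[`, c(list(cpt$prob), idx))
  names(p) <- cpt$levels
  p
}

# vectorised log P(child | parents) for integer-coded columns.
# `codes` is an integer matrix with named columns covering child and parents.
cpt_loglik_rows <- function(cpt, codes) {
  d <- dim(cpt$prob)
  lin <- codes[, cpt$child]
  if (length(cpt$parents)) {
    mult <- cumprod(d)[-length(d)]
    for (j in seq_along(cpt$parents)) {
      lin <- lin + (codes[, cpt$parents[j]] - 1L) * mult[j]
    }
  }
  log(cpt$prob[lin])
}

#' Joint probability of a complete assignment
#'
#' Factorizes the joint as the product of each node's conditional probability
#' given its parents — the defining identity of a Bayesian network.
#'
#' @param net A `bn_net` or fitted `bnc` (anything with `$dag` and `$cpts`).
#' @param assignment Named list or vector assigning a state (as a string or
#'   factor level) to every node.
#' @return The joint probability, a number in \eqn{[0, 1]}.
#' @examples
#' net <- chain_network()
#' joint_probability(net, list(A = "0", B = "1", C = "1"))
#' @export
joint_probability <- function(net, assignment) {
  assignment <- lapply(assignment, as.character)
  missing <- setdiff(net$dag$nodes, names(assignment))
  if (length(missing)) {
    stop("assignment missing node(s): ", paste(missing, collapse = ", "))
  }
  p <- 1
  for (v in net$dag$nodes) {
    p <- p * cpt_prob(net$cpts[[v]], assignment[[v]], assignment)
  }
  p
}

#' Read one conditional distribution out of a fitted model
#'
#' Returns the stored conditional distribution of `child` for a given
#' assignment of its parents — the mechanism behind reading, e.g., the
#' probability of neonatal jaundice under each combination of neonatal
#' pneumonia and amniotic fluid cleanliness from a fitted network.
#'
#' @param model A `bn_net` or fitted `bnc`.
#' @param child Node name.
#' @param parent_assignment Named list/vector assigning a state to exactly the
#'   child's parents (empty for a parentless node).
#' @return Named numeric vector over the child's states, summing to 1.
#' @export
query_cpt <- function(model, child, parent_assignment = NULL) {
  if (!child %in% names(model$cpts)) stop("unknown node: ", child)
  cpt <- model$cpts[[child]]
  got <- names(parent_assignment)
  if (!setequal(got, cpt$parents)) {
    stop("parent assignment must cover exactly {",
         paste(cpt$parents, collapse = ", "), "} for node ", child)
  }
  vals <- unlist(lapply(parent_assignment, as.character))
  for (pn in cpt$parents) {
    if (!vals[[pn]] %in% dimnames(cpt$prob)[[match(pn, cpt$parents) + 1L]]) {
      stop("unknown state '", vals[[pn]], "' for parent ", pn)
    }
  }
  cpt_row(cpt, as.list(vals))
}

# coerce all columns to factors (stable sorted levels for characters),
# preserving existing factor levels
as_cohort <- function(data) {
  for (j in seq_along(data)) {
    if (!is.factor(data[[j]])) {
      data[[j]] <- factor(as.character(data[[j]]),
                          levels = sort(unique(as.character(data[[j]]))))
    }
  }
  data
}

# integer codes matrix from a factor data frame, aligned to given level sets
cohort_codes <- function(data, levels) {
  m <- matrix(0L, nrow(data), length(levels),
              dimnames = list(NULL, names(levels)))
  for (v in names(levels)) {
    codes <- match(as.character(data[[v]]), levels[[v]])
    if (anyNA(codes) && nrow(data) > 0) {
      bad <- unique(as.character(data[[v]])[is.na(codes)])
      stop("unknown state(s) for ", v, ": ", paste(bad, collapse = ", "))
    }
    m[, v] <- codes
  }
  m
}
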