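#' Construct a directed acyclic graph
#'
#' A lightweight DAG container used throughout the package: classifier
#' structures, ground-truth networks and structure-learning output all share
#' it. Edges are stored as a named list mapping each node to its parents.
#'
#' @param nodes Character vector of node names (unique, non-empty).
#' @param parents Named list; `parents[[v]]` is the character vector of
#'   parents of node `v`. Nodes absent from the list have no parents.
#' @param undirected Optional two-column character matrix of undirected edges
#'   (used only by partially directed structure-learning output).
#' @param check_acyclic If `TRUE` (default), an error is raised when the
#'   directed part contains a cycle.
#' @return An object of class `bn_dag` with elements `nodes`, `parents` and
#'   `undirected`.
#' @examples
#' g <- bn_dag(c("A", "B", "C"), list(B = "A", C = "B"))
#' markov_blanket(g, "B")
#' @export
bn_dag <- function(nodes, parents = list(), undirected = NULL,
                   check_acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) full[[v]] <- character(0)
  for (v in names(parents)) {
    if (!v %in% nodes) stop("parent list refers to unknown node: ", v)
    p <- as.character(parents[[v]])
    if (v %in% p) stop("self-loop at node: ", v)
    if (anyDuplicated(p)) stop("duplicate edge into node: ", v)
    if (!all(p %in% nodes)) {
      stop("unknown parent(s) of ", v, ": ",
           paste(setdiff(p, nodes), collapse = ", "))
    }
    full[[v]] <- p
  }
  if (!is.null(undirected)) {
    undirected <- matrix(as.character(undirected), ncol = 2)
    if (!all(undirected %in% nodes)) stop("undirected edge names unknown")
  }
  g <- structure(list(nodes = nodes, parents = full, undirected = undirected),
                 class = "bn_dag")
  if (check_acyclic && !is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  nu <- if (is.null(x$undirected)) 0L else nrow(x$undirected)
  cat("Directed graph:", length(x$nodes), "nodes,", ne, "directed arc(s)")
  if (nu > 0) cat(",", nu, "undirected edge(s)")
  cat("\n")
  for (v in x$nodes) {
    if (length(x$parents[[v]])) {
      cat("  ", paste(x$parents[[v]], collapse = ", "), " -> ", v, "\n",
          sep = "")
    }
  }
  if (nu > 0) {
    for (i in seq_len(nu)) {
      cat("  ", x$undirected[i, 1], " -- ", x$undirected[i, 2], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Edge list of a DAG
#'
#' @param dag A `bn_dag`.
#' @return Two-column character matrix with columns `from`, `to` (directed
#'   arcs only).
#' @export
dag_edges <- function(dag) {
  from <- unlist(dag$parents, use.names = FALSE)
  to <- rep(names(dag$parents), lengths(dag$parents))
  matrix(c(from, to), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; among nodes with no remaining parents the one earliest
#' in `dag$nodes` is emitted first, so the result is deterministic.
#'
#' @param dag A `bn_dag`.
#' @return Character vector of node names, parents before children.
#' @export
topological_order <- function(dag) {
  indeg <- lengths(dag$parents)
  children <- children_map(dag)
  out <- character(0)
  avail <- dag$nodes[indeg == 0]
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
    # keep original node order among ready nodes
    avail <- avail[order(match(avail, dag$nodes))]
  }
  if (length(out) != length(dag$nodes)) stop("graph contains a directed cycle")
  out
}

#' Test a directed graph for acyclicity
#'
#' @param dag A `bn_dag`.
#' @return `TRUE` if the directed part has no cycle.
#' @export
is_acyclic <- function(dag) {
  ok <- TRUE
  tryCatch(topological_order(dag), error = function(e) ok <<- FALSE)
  ok
}

children_map <- function(dag) {
  ch <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) ch[[v]] <- character(0)
  for (v in names(dag$parents)) {
    for (p in dag$parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

ancestors_of <- function(dag, node) {
  seen <- character(0)
  frontier <- dag$parents[[node]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  seen
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents — the minimal set that
#' renders the node conditionally independent of every other variable.
#'
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector (possibly empty), sorted by position in
#'   `dag$nodes`.
#' @export
markov_blanket <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  ch <- children_map(dag)[[node]]
  coparents <- unlist(dag$parents[ch], use.names = FALSE)
  mb <- setdiff(unique(c(dag$parents[[node]], ch, coparents)), node)
  mb[order(match(mb, dag$nodes))]
}

#' Export a graph in Graphviz DOT format
#'
#' Works for `bn_dag` objects (including partially directed graphs, whose
#' undirected edges are rendered with `dir=none`) and for fitted classifiers
#' and networks carrying a `$dag`.
#'
#' @param x A `bn_dag`, `bn_net` or `bnc` object.
#' @param file Path to write to; `""` prints to the console.
#' @param name Graph name used in the DOT header.
#' @return Invisibly, the DOT text as a character scalar.
#' @export
write_dot <- function(x, file = "", name = "bn") {
  dag <- if (inherits(x, "bn_dag")) x else x$dag
  lines <- c(sprintf("digraph %s {", name),
             sprintf("  \"%s\";", dag$nodes))
  e <- dag_edges(dag)
  if (nrow(e)) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", e[, 1], e[, 2]))
  }
  if (!is.null(dag$undirected) && nrow(dag$undirected)) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [dir=none];",
                              dag$undirected[, 1], dag$undirected[, 2]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!identical(file, "")) writeLines(txt, file) else cat(txt, "\n")
  invisible(txt)
}
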