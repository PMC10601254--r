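#' Serialize / restore a fitted classifier as JSON
#'
#' The document records the variant, `k`, class variable, node order, edges,
#' state labels, smoothing and flattened CPTs — everything needed to rebuild
#' the classifier exactly (MI/CMI tables, which only matter during structure
#' construction, are not kept).
#'
#' @param model A fitted `bnc`.
#' @param file Path to a JSON file.
#' @return `write_bnc_json` returns `file` invisibly; `read_bnc_json` the
#'   reconstructed `bnc`.
#' @export
write_bnc_json <- function(model, file) {
  doc <- list(
    type = model$method, k = model$k, class_var = model$class_var,
    smoothing = model$smoothing, n_train = model$n_train,
    nodes = model$dag$nodes,
    state_labels = model$levels,
    edges = apply(dag_edges(model$dag), 1, function(r) {
      list(from = r[[1]], to = r[[2]])
    }),
    cpts = lapply(model$dag$nodes, function(v) {
      cpt <- model$cpts[[v]]
      list(child = v, parents = cpt$parents,
           dim = dim(cpt$prob), prob = as.vector(cpt$prob))
    })
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_bnc_json
#' @export
read_bnc_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  levels <- lapply(doc$state_labels, function(x) as.character(unlist(x)))
  cpts <- stats::setNames(lapply(doc$cpts, function(cc) {
    parents <- as.character(unlist(cc$parents))
    make_cpt(cc$child, levels[[cc$child]], parents,
             stats::setNames(levels[parents], parents),
             array(as.numeric(unlist(cc$prob)), dim = unlist(cc$dim)))
  }), vapply(doc$cpts, function(cc) cc$child, ""))
  nodes <- as.character(unlist(doc$nodes))
  cpts <- cpts[nodes]
  dag <- bn_dag(nodes, lapply(cpts, function(x) x$parents))
  class_var <- doc$class_var
  attrs <- setdiff(nodes, class_var)
  structure(list(
    method = doc$type, k = as.integer(doc$k), class_var = class_var,
    attributes = attrs, dag = dag, cpts = cpts, levels = levels[nodes],
    class_prior = cpt_row(cpts[[class_var]]),
    mi = NULL, cmi = NULL, smoothing = doc$smoothing,
    n_train = doc$n_train, call = NULL
  ), class = c("bnc", "bn_net"))
}
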