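#' Empirical mutual information between two discrete variables
#'
#' \deqn{I(X;Y) = \sum_{x,y} \hat p(x,y) \log_2 \frac{\hat p(x,y)}
#' {\hat p(x)\hat p(y)}}
#' computed from unsmoothed empirical frequencies, in bits, with the
#' convention \eqn{0 \log 0 = 0}. Used to rank attributes by relevance to the
#' class when building the k-dependence classifier.
#'
#' @param data Data frame containing both columns.
#' @param x,y Column names.
#' @return Mutual information in bits (non-negative up to floating-point
#'   round-off; clamped at 0).
#' @export
mutual_information <- function(data, x, y) {
  if (nrow(data) == 0) stop("empty table")
  pxy <- table(data[[x]], data[[y]]) / nrow(data)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  e <- outer(px, py)
  nz <- pxy > 0
  max(0, sum(pxy[nz] * log2(pxy[nz] / e[nz])))
}

#' Empirical conditional mutual information given the class
#'
#' \deqn{I(X_i;X_j \mid C) = \sum_{x_i,x_j,c} \hat p(x_i,x_j,c) \log_2
#' \frac{\hat p(x_i,x_j \mid c)}{\hat p(x_i \mid c)\,\hat p(x_j \mid c)}}
#' the edge weight of the tree-augmented classifier's maximum-weight spanning
#' tree and the parent-selection score of the k-dependence classifier. Zero
#' exactly when the empirical conditional distributions factorize.
#'
#' @param data Data frame containing all three columns.
#' @param xi,xj Attribute column names.
#' @param c Class column name.
#' @return Conditional mutual information in bits (clamped at 0).
#' @export
conditional_mutual_information <- function(data, xi, xj, c) {
  if (nrow(data) == 0) stop("empty table")
  n <- nrow(data)
  pijc <- table(data[[xi]], data[[xj]], data[[c]]) / n
  pic <- apply(pijc, c(1, 3), sum) # p(xi, c)
  pjc <- apply(pijc, c(2, 3), sum) # p(xj, c)
  pc <- apply(pijc, 3, sum)
  total <- 0
  for (k in seq_along(pc)) {
    if (pc[k] == 0) next
    joint <- pijc[, , k]
    e <- outer(pic[, k], pjc[, k]) / pc[k] # p(xi|c) p(xj|c) p(c)
    nz <- joint > 0
    total <- total + sum(joint[nz] * log2(joint[nz] / e[nz]))
  }
  max(0, total)
}
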