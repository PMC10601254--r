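#' G-squared conditional independence test
#'
#' Likelihood-ratio test of X independent of Y given Z on stratified
#' contingency tables:
#' \deqn{G^2 = 2 \sum_z \sum_{x,y} n_{xyz} \log \frac{n_{xyz}\, n_{z}}
#' {n_{xz}\, n_{yz}}}
#' with degrees of freedom \eqn{(|X|-1)(|Y|-1)\prod_k |Z_k|} over the levels
#' observed in the full table. Cells with zero count, and whole strata with a
#' zero margin, contribute 0 to the statistic (the degrees of freedom are not
#' adjusted).
#'
#' @param data Cohort data frame.
#' @param x,y Column names of the tested pair.
#' @param conditioning Character vector of conditioning column names
#'   (possibly empty; must exclude `x` and `y`).
#' @return List of class `bn_citest`: `statistic`, `df`, `p_value`, plus the
#'   cell count used by the reliability heuristic.
#' @export
ci_test <- function(data, x, y, conditioning = character(0)) {
  if (nrow(data) == 0) stop("empty table")
  if (x %in% conditioning || y %in% conditioning) {
    stop("conditioning set must exclude the tested pair")
  }
  fx <- droplevels(factor(data[[x]]))
  fy <- droplevels(factor(data[[y]]))
  nx <- nlevels(fx); ny <- nlevels(fy)
  n <- nrow(data)
  if (length(conditioning)) {
    zc <- rep(1L, n); nz <- 1L
    for (v in conditioning) {
      fz <- droplevels(factor(data[[v]]))
      zc <- zc + (as.integer(fz) - 1L) * nz
      nz <- nz * nlevels(fz)
    }
  } else {
    zc <- rep(1L, n); nz <- 1L
  }
  code <- as.integer(fx) + nx * (as.integer(fy) - 1L) +
    nx * ny * (zc - 1L)
  o <- array(tabulate(code, nbins = nx * ny * nz), dim = c(nx, ny, nz))
  g2 <- 0
  for (k in seq_len(nz)) {
    ok <- o[, , k]
    tot <- sum(ok)
    if (tot == 0) next
    e <- outer(rowSums(ok), colSums(ok)) / tot
    nzc <- ok > 0
    g2 <- g2 + 2 * sum(ok[nzc] * log(ok[nzc] / e[nzc]))
  }
  df <- as.integer((nx - 1) * (ny - 1) * nz)
  structure(list(statistic = max(0, g2), df = df,
                 p_value = stats::pchisq(max(0, g2), df, lower.tail = FALSE),
                 n_cells = nx * ny * nz),
            class = "bn_citest")
}

#' @export
print.bn_citest <- function(x, ...) {
  cat(sprintf("G^2 test: statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# dependence decision used by grow-shrink; a test with fewer than five
# observations per degree of freedom is considered uninformative and treated
# as independence (the standard safeguard in constraint-based learning)
is_dependent <- function(data, x, y, z, alpha, min_per_df = 5) {
  fx <- droplevels(factor(data[[x]]))
  fy <- droplevels(factor(data[[y]]))
  df <- (nlevels(fx) - 1) * (nlevels(fy) - 1)
  for (v in z) df <- df * nlevels(droplevels(factor(data[[v]])))
  if (nrow(data) < min_per_df * df) return(FALSE)
  ci_test(data, x, y, z)$p_value < alpha
}

#' Grow-Shrink constraint-based structure learning
#'
#' Discovers each variable's Markov blanket with G-squared conditional
#' independence tests — a grow phase that adds any variable dependent on the
#' target given the current blanket (variables scanned in column order), then
#' a shrink phase that removes any blanket member independent of the target
#' given the rest. Blankets are symmetrized (intersection), resolved to direct
#' neighbours by searching for separating subsets within the smaller blanket,
#' and v-structures X -> Z <- Y are oriented wherever a common neighbour Z of
#' a non-adjacent pair lies outside the pair's separating set. Remaining
#' edges are left undirected.
#'
#' @param data Cohort data frame (>= 2 columns of factors).
#' @param alpha Significance level of the CI tests, in (0, 1); default 0.05.
#' @return A partially directed `bn_dag`: v-structure arcs in `parents`,
#'   everything else in `undirected`.
#' @export
grow_shrink <- function(data, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  vars <- names(data)
  if (length(vars) < 2) stop("need at least two columns")
  data <- as_cohort(data)

  mb <- stats::setNames(vector("list", length(vars)), vars)
  for (x in vars) {
    b <- character(0)
    repeat { # grow
      changed <- FALSE
      for (y in setdiff(vars, c(x, b))) {
        if (is_dependent(data, x, y, b, alpha)) {
          b <- c(b, y)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    repeat { # shrink
      changed <- FALSE
      for (y in b) {
        if (!is_dependent(data, x, y, setdiff(b, y), alpha)) {
          b <- setdiff(b, y)
          changed <- TRUE
          break
        }
      }
      if (!changed) break
    }
    mb[[x]] <- b
  }
  # symmetry correction
  for (x in vars) mb[[x]] <- Filter(function(y) x %in% mb[[y]], mb[[x]])

  # neighbour resolution: X - Y adjacent unless a subset of the smaller
  # blanket separates them; remember separating sets
  adj <- matrix(FALSE, length(vars), length(vars),
                dimnames = list(vars, vars))
  sepsets <- list()
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      x <- vars[i]; y <- vars[j]
      if (!(y %in% mb[[x]])) next
      tx <- setdiff(mb[[x]], y); ty <- setdiff(mb[[y]], x)
      t_small <- if (length(tx) <= length(ty)) tx else ty
      sep <- find_sepset(data, x, y, t_small, alpha)
      if (is.null(sep)) {
        adj[x, y] <- adj[y, x] <- TRUE
      } else {
        sepsets[[pair_key(x, y)]] <- sep
      }
    }
  }

  # v-structure orientation
  oriented <- matrix(FALSE, length(vars), length(vars),
                     dimnames = list(vars, vars)) # oriented[a, b]: a -> b
  for (z in vars) {
    nb <- vars[adj[z, ]]
    if (length(nb) < 2) next
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (j <= i) next
        x <- nb[i]; y <- nb[j]
        if (adj[x, y]) next # x, y adjacent: no v-structure
        key <- pair_key(x, y)
        sep <- sepsets[[key]]
        if (is.null(sep)) {
          cand <- union(setdiff(vars[adj[x, ]], y), setdiff(vars[adj[y, ]], x))
          sep <- find_sepset(data, x, y, cand, alpha)
          if (is.null(sep)) next # inconsistent tests; leave unoriented
          sepsets[[key]] <- sep
        }
        if (!(z %in% sep)) {
          if (!oriented[z, x]) oriented[x, z] <- TRUE
          if (!oriented[z, y]) oriented[y, z] <- TRUE
        }
      }
    }
  }

  parents <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) parents[[v]] <- vars[oriented[, v]]
  und <- matrix(character(0), 0, 2)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      x <- vars[i]; y <- vars[j]
      if (adj[x, y] && !oriented[x, y] && !oriented[y, x]) {
        und <- rbind(und, c(x, y))
      }
    }
  }
  bn_dag(vars, parents, undirected = und, check_acyclic = FALSE)
}

# smallest separating subset of `pool` (searched by increasing size); NULL if
# none separates
find_sepset <- function(data, x, y, pool, alpha, max_size = 3) {
  pool <- unique(pool)
  for (s in 0:min(length(pool), max_size)) {
    if (s == 0) {
      if (!is_dependent(data, x, y, character(0), alpha)) return(character(0))
    } else {
      subsets <- utils::combn(pool, s, simplify = FALSE)
      for (ss in subsets) {
        if (!is_dependent(data, x, y, ss, alpha)) return(ss)
      }
    }
  }
  NULL
}

#' Bootstrap model averaging of learned structures
#'
#' Draws `B` bootstrap resamples (with replacement, same size), learns a
#' structure on each with [grow_shrink()], and summarizes every edge ever
#' seen: its strength (fraction of replicates containing the edge in either
#' orientation or undirected) and its direction confidence (fraction of those
#' replicates orienting it from `from` to `to`; an undirected occurrence
#' counts half to each orientation). The reported orientation is the majority
#' one; ties go to the lexicographically smaller endpoint first.
#'
#' @param data Cohort data frame.
#' @param B Number of bootstrap replicates (>= 1); 1000 for a full run,
#'   typically 200 for desk-scale checks.
#' @param alpha CI-test significance level.
#' @param seed Integer seed (private RNG stream; caller's state untouched).
#' @param threshold Strength threshold in \eqn{[0, 1]} (default 0.5,
#'   majority rule) deciding which arcs are retained.
#' @return Object of class `bn_avgnet`: `nodes`, `arcs` (data frame with
#'   `from`, `to`, `strength`, `direction_confidence`, `retained`),
#'   `threshold`, `B`, `alpha`.
#' @export
bootstrap_average <- function(data, B = 1000, alpha = 0.05, seed = 1,
                              threshold = 0.5) {
  if (B < 1) stop("B must be >= 1")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  data <- as_cohort(data)
  n <- nrow(data)
  vars <- names(data)
  seen <- list() # key -> c(present, dir_lo_hi, dir_hi_lo)
  local_seed(seed, {
    for (b in seq_len(B)) {
      g <- grow_shrink(data[sample.int(n, n, replace = TRUE), , drop = FALSE],
                       alpha = alpha)
      e <- dag_edges(g)
      rec <- function(a, bb, w_ab, w_ba) {
        lo <- min(a, bb); hi <- max(a, bb)
        key <- paste(lo, hi, sep = "|")
        cur <- seen[[key]]
        if (is.null(cur)) cur <- c(0, 0, 0)
        if (a == lo) seen[[key]] <<- cur + c(1, w_ab, w_ba)
        else seen[[key]] <<- cur + c(1, w_ba, w_ab)
      }
      if (nrow(e)) {
        for (i in seq_len(nrow(e))) rec(e[i, 1], e[i, 2], 1, 0)
      }
      if (!is.null(g$undirected) && nrow(g$undirected)) {
        for (i in seq_len(nrow(g$undirected))) {
          rec(g$undirected[i, 1], g$undirected[i, 2], 0.5, 0.5)
        }
      }
    }
  })
  keys <- sort(names(seen))
  arcs <- data.frame(from = character(0), to = character(0),
                     strength = numeric(0), direction_confidence = numeric(0),
                     retained = logical(0), stringsAsFactors = FALSE)
  for (key in keys) {
    v <- strsplit(key, "|", fixed = TRUE)[[1]]
    cnt <- seen[[key]]
    conf_lo <- cnt[2] / cnt[1]
    if (conf_lo >= 0.5) {
      from <- v[1]; to <- v[2]; conf <- conf_lo
    } else {
      from <- v[2]; to <- v[1]; conf <- 1 - conf_lo
    }
    strength <- cnt[1] / B
    arcs <- rbind(arcs, data.frame(
      from = from, to = to, strength = strength,
      direction_confidence = conf, retained = strength >= threshold,
      stringsAsFactors = FALSE))
  }
  structure(list(nodes = vars, arcs = arcs, threshold = threshold, B = B,
                 alpha = alpha),
            class = "bn_avgnet")
}

#' @export
print.bn_avgnet <- function(x, ...) {
  cat("Bootstrap-averaged network:", length(x$nodes), "nodes,", x$B,
      "replicates, threshold", x$threshold, "\n")
  cat(" ", sum(x$arcs$retained), "arc(s) retained of", nrow(x$arcs),
      "ever seen\n")
  if (nrow(x$arcs)) {
    a <- x$arcs[order(-x$arcs$strength), ]
    a$strength <- round(a$strength, 3)
    a$direction_confidence <- round(a$direction_confidence, 3)
    print(utils::head(a, 25), row.names = FALSE)
  }
  invisible(x)
}

#' Count directed versus undirected arcs of an averaged network
#'
#' Among the retained arcs, those whose direction confidence reaches
#' `direction_cutoff` are counted as directed, the rest as undirected — the
#' operational version of reading a bootstrap summary where an edge pointing
#' one way in ~51% of replicates is best treated as undirected.
#'
#' @param net A `bn_avgnet`.
#' @param direction_cutoff Confidence needed to call an arc directed, in
#'   (0.5, 1]; default 0.9.
#' @return List with `n_directed` and `n_undirected`.
#' @export
summarize_arcs <- function(net, direction_cutoff = 0.9) {
  if (!(direction_cutoff > 0.5 && direction_cutoff <= 1)) {
    stop("direction_cutoff must lie in (0.5, 1]")
  }
  a <- net$arcs[net$arcs$retained, , drop = FALSE]
  list(n_directed = sum(a$direction_confidence >= direction_cutoff),
       n_undirected = sum(a$direction_confidence < direction_cutoff))
}
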