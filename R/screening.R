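#' Chi-squared screen of one categorical predictor
#'
#' Pearson chi-squared test (no continuity correction) of the r x c
#' contingency table between a categorical predictor and the binary outcome,
#' with (r-1)(c-1) degrees of freedom. Unobserved factor levels are dropped
#' before tabulation.
#'
#' @param data Cohort data frame.
#' @param variable Predictor column name.
#' @param outcome Outcome column name (default `"np"`).
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @return One-row data frame: `variable`, `test`, `statistic`, `df`,
#'   `p_value`, `selected`.
#' @export
chi_squared_screen <- function(data, variable, outcome = "np", alpha = 0.05) {
  tab <- table(droplevels(factor(data[[variable]])),
               droplevels(factor(data[[outcome]])))
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate contingency table for variable '", variable,
         "': needs at least two observed levels in both margins")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  screening_row(variable, "chi_squared", unname(ht$statistic),
                unname(ht$parameter), ht$p.value, alpha)
}

#' Mann-Whitney U screen of one ordinal predictor
#'
#' U statistic with midrank handling of ties, comparing the ordinal
#' predictor between the two outcome groups. The reported U counts pairs won
#' by the group belonging to the outcome's first factor level (ties count
#' 0.5). For combined sample sizes above 20 the p-value uses the normal
#' approximation with the tie-corrected variance; below that, the exact
#' permutation distribution of U is enumerated (valid with ties).
#'
#' @inheritParams chi_squared_screen
#' @return One-row data frame as in [chi_squared_screen()], with `df = NA`.
#' @export
mann_whitney_screen <- function(data, variable, outcome = "np", alpha = 0.05) {
  y <- droplevels(factor(data[[outcome]]))
  if (nlevels(y) != 2) stop("outcome must have exactly two observed levels")
  v <- as.integer(factor(data[[variable]])) # ordinal scores: level codes
  g1 <- v[y == levels(y)[1]]
  g2 <- v[y == levels(y)[2]]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("empty outcome group when screening variable '", variable, "'")
  }
  res <- mann_whitney_u(g1, g2)
  screening_row(variable, "mann_whitney_u", res$U, NA_real_, res$p, alpha)
}

# core U computation on two numeric vectors
mann_whitney_u <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  r <- rank(c(g1, g2)) # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= 20) {
    # exact permutation distribution of U (handles ties): enumerate all
    # assignments of n1 ranks to group 1
    subsets <- utils::combn(N, n1)
    R1 <- colSums(matrix(r[subsets], nrow = n1))
    Uall <- R1 - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(r)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (s2 <= 0) 1 else 2 * stats::pnorm(-abs(U - mu) / sqrt(s2))
    p <- min(1, p)
  }
  list(U = U, p = p)
}

screening_row <- function(variable, test, statistic, df, p_value, alpha) {
  out <- data.frame(variable = variable, test = test,
                    statistic = as.numeric(statistic), df = as.numeric(df),
                    p_value = p_value, selected = p_value < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Variable kinds of the default cohort
#'
#' The screening test assigned to each of the 16 predictors: chi-squared for
#' the twelve categorical variables, Mann-Whitney U for the four rank
#' (ordinal) variables (number of pregnancies, amniotic fluid volume,
#' amniotic fluid cleanliness, C-reactive protein).
#'
#' @return Named character vector mapping variable name to `"categorical"` or
#'   `"rank"`.
#' @export
default_variable_kinds <- function() {
  c(age = "categorical", pbg = "categorical", p = "categorical",
    hdop = "categorical", ptb = "categorical", prom = "categorical",
    ms = "categorical", nrds = "categorical", nnj = "categorical",
    pph = "categorical", na = "categorical", ngr = "categorical",
    g = "rank", afv = "rank", afc = "rank", crp = "rank")
}

#' Screen all predictors against the outcome
#'
#' Applies the kind-appropriate univariate test to every predictor and flags
#' those with p below `alpha`. Screening is advisory: model fitting accepts
#' any attribute list, and the pipeline default is the screened-in set.
#'
#' @param data Cohort data frame.
#' @param kinds Named vector mapping each predictor to `"categorical"` or
#'   `"rank"`; default [default_variable_kinds()].
#' @param alpha Significance threshold (default 0.05).
#' @param outcome Outcome column name.
#' @return Data frame of class `bn_screen`, one row per predictor.
#' @examples
#' cohort <- sample_cohort(default_ground_truth(), 300, seed = 1)
#' screen_all(cohort)
#' @export
screen_all <- function(data, kinds = default_variable_kinds(), alpha = 0.05,
                       outcome = "np") {
  kinds <- unlist(kinds)
  bad <- setdiff(kinds, c("categorical", "rank"))
  if (length(bad)) stop("unknown variable kind(s): ", paste(bad, collapse = ", "))
  rows <- lapply(names(kinds), function(v) {
    if (kinds[[v]] == "categorical") {
      chi_squared_screen(data, v, outcome, alpha)
    } else {
      mann_whitney_screen(data, v, outcome, alpha)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("bn_screen", class(out))
  out
}

#' @export
print.bn_screen <- function(x, digits = 4, ...) {
  alpha <- attr(x, "alpha")
  cat("Univariate screening",
      if (!is.null(alpha)) paste0("(alpha = ", alpha, ")"), ":",
      sum(x$selected), "of", nrow(x), "predictors selected\n")
  y <- data.frame(x)
  for (cn in intersect(c("statistic", "p_value"), names(y))) {
    y[[cn]] <- signif(y[[cn]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}
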