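#' Train/test split of a cohort
#'
#' Row-disjoint partition with `round(ratio * n)` training rows. With
#' `stratify = TRUE` (the default — advisable at a ~15% outcome prevalence)
#' the rounding is applied within each outcome level, so class proportions
#' carry over to both halves.
#'
#' @param data Cohort data frame.
#' @param ratio Training fraction, in (0, 1); default 0.7.
#' @param seed Integer seed (private RNG stream).
#' @param stratify Stratify on the outcome column? Default `TRUE`.
#' @param outcome Outcome column name (used when stratifying).
#' @return List with elements `train` and `test`.
#' @export
split_cohort <- function(data, ratio = 0.7, seed = 1, stratify = TRUE,
                         outcome = "np") {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)")
  n <- nrow(data)
  idx_train <- local_seed(seed, {
    if (stratify) {
      y <- factor(data[[outcome]])
      out <- integer(0)
      for (lv in levels(y)) {
        rows <- which(y == lv)
        n_tr <- round(ratio * length(rows))
        if (n_tr == 0 || n_tr == length(rows)) {
          stop("outcome level '", lv, "' would be absent from one split")
        }
        out <- c(out, sample(rows, n_tr))
      }
      sort(out)
    } else {
      sort(sample.int(n, round(ratio * n)))
    }
  })
  list(train = data[idx_train, , drop = FALSE],
       test = data[-idx_train, , drop = FALSE])
}

#' Confusion matrix of binary predictions
#'
#' Counts with the convention rows = predicted, columns = measured:
#' `tp` predicted-positive & measured-positive, `fp` predicted-positive &
#' measured-negative, `fn` predicted-negative & measured-positive, `tn`
#' predicted-negative & measured-negative.
#'
#' @param predicted,measured Equal-length vectors of class labels.
#' @param positive The label counted as positive.
#' @return Object of class `bn_confusion`: list with `tp`, `fp`, `fn`, `tn`.
#' @seealso [as_confusion()] to wrap already-tabulated counts, [metrics()].
#' @export
confusion <- function(predicted, measured, positive) {
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must have the same length")
  }
  p <- as.character(predicted) == as.character(positive)
  m <- as.character(measured) == as.character(positive)
  as_confusion(tp = sum(p & m), fp = sum(p & !m),
               fn = sum(!p & m), tn = sum(!p & !m))
}

#' Wrap confusion-matrix counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Object of class `bn_confusion`.
#' @export
as_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "bn_confusion")
}

#' @export
print.bn_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              measured = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Standard definitions: accuracy \eqn{(TP+TN)/(TP+FN+FP+TN)}, sensitivity
#' (= recall) \eqn{TP/(TP+FN)}, specificity \eqn{TN/(FP+TN)}, positive
#' predictive value (= precision) \eqn{TP/(TP+FP)}, negative predictive value
#' \eqn{TN/(TN+FN)}, F1 the harmonic mean of precision and recall. A ratio
#' with a zero denominator is reported as `NA` (absent), never as 0, so a
#' degenerate predictor remains distinguishable from a bad one. Values are
#' kept at full precision; round only for display.
#'
#' @param cm A `bn_confusion` (from [confusion()] or [as_confusion()]).
#' @return Object of class `bn_metrics`: named list with `accuracy`,
#'   `precision`, `recall`, `f1`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   and the underlying counts.
#' @examples
#' metrics(as_confusion(tp = 62, fp = 24, fn = 20, tn = 497))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "bn_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  recall <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(
    accuracy = (cm$tp + cm$tn) / total,
    precision = precision, recall = recall, f1 = f1,
    sensitivity = recall, specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = precision, npv = ratio(cm$tn, cm$tn + cm$fn),
    confusion = cm, n = total
  ), class = "bn_metrics")
}

#' @export
print.bn_metrics <- function(x, digits = 2, ...) {
  cat("Classification metrics (n =", x$n, "):\n")
  v <- unlist(x[c("accuracy", "precision", "recall", "f1", "sensitivity",
                  "specificity", "ppv", "npv")])
  if (!is.null(x$auc)) v <- c(v, auc = x$auc)
  print(round(100 * v, digits))
  invisible(x)
}

#' Area under the ROC curve by pairwise concordance
#'
#' The probability-of-concordance (Mann-Whitney) estimator: the fraction of
#' positive-negative pairs where the positive case scores higher, ties
#' counting one half. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric scores (e.g. posterior probability of the positive
#'   class).
#' @param labels Class labels, same length.
#' @param positive Label counted as positive.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc <- function(scores, labels, positive) {
  pos <- as.character(labels) == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate several classifiers on one shared split
#'
#' Splits the cohort once ([split_cohort()]), fits each requested classifier
#' variant on the training half, and scores the held-out half: confusion
#' counts, the full metric battery and AUC from the positive-class
#' posterior.
#'
#' @param formula Model formula, e.g. `np ~ .`.
#' @param data Cohort data frame.
#' @param methods Character vector of variants (`"nb"`, `"tan"`, `"kdb"`;
#'   duplicates allowed).
#' @param k Dependence order used by `"kdb"` entries (default 2).
#' @param ratio Training fraction (default 0.7).
#' @param seed Split seed.
#' @param smoothing CPT smoothing (default 1).
#' @param positive Positive class label; default the outcome's last level
#'   (`"1"` for 0/1 coding).
#' @param stratify Stratified split? Default `TRUE`.
#' @return Object of class `bn_comparison`: data frame with one row per
#'   model (accuracy through npv in \eqn{[0,1]}, plus `auc`), with the fitted
#'   models and per-model `bn_metrics` in attributes `models` and `reports`.
#' @examples
#' cohort <- sample_cohort(default_ground_truth(), 600, seed = 5)
#' compare_models(np ~ ., cohort, methods = c("nb", "tan"), seed = 5)
#' @export
compare_models <- function(formula, data, methods = c("nb", "tan", "kdb"),
                           k = 2, ratio = 0.7, seed = 1, smoothing = 1,
                           positive = NULL, stratify = TRUE) {
  if (length(methods) < 1) stop("at least one model is required")
  class_var <- as.character(formula[[2]])
  if (is.null(positive)) {
    lv <- levels(factor(data[[class_var]]))
    positive <- lv[length(lv)]
  }
  halves <- split_cohort(data, ratio = ratio, seed = seed,
                         stratify = stratify, outcome = class_var)
  reports <- list()
  models <- list()
  rows <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    fit <- bnc(formula, halves$train, method = m, k = k,
               smoothing = smoothing)
    pred <- predict(fit, halves$test)
    post <- predict(fit, halves$test, type = "posterior")
    cm <- confusion(pred, halves$test[[class_var]], positive)
    rep_i <- metrics(cm)
    rep_i$auc <- auc(post[, as.character(positive)],
                     halves$test[[class_var]], positive)
    id <- if (m == "kdb") sprintf("kdb(%d)", k) else m
    if (id %in% names(reports)) id <- sprintf("%s.%d", id, i)
    reports[[id]] <- rep_i
    models[[id]] <- fit
    rows[[id]] <- data.frame(
      model = id, accuracy = rep_i$accuracy, precision = rep_i$precision,
      recall = rep_i$recall, f1 = rep_i$f1, sensitivity = rep_i$sensitivity,
      specificity = rep_i$specificity, ppv = rep_i$ppv, npv = rep_i$npv,
      auc = rep_i$auc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "reports") <- reports
  attr(out, "positive") <- positive
  class(out) <- c("bn_comparison", class(out))
  out
}

#' @export
print.bn_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (positive class:", attr(x, "positive"), ")\n")
  y <- data.frame(x)
  for (j in 2:ncol(y)) y[[j]] <- round(y[[j]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
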