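# Diagnostic-accuracy statistics: confusion matrices and derived metrics,
# stratified k-fold cross-validation of the tree trainer, rank-based ROC AUC
# with the Hanley-McNeil standard error, the Mann-Whitney U test, and the
# histology-vs-molecular discordance summary.

#' Build a confusion matrix
#'
#' @param truth,predicted aligned label vectors.
#' @param classes class order (rows = truth, columns = predicted); defaults
#'   to the sorted union of observed labels. Predictions of `NA` are dropped
#'   (with the matching truth entries).
#' @return k x k integer matrix of class `confusion_table`.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  keep <- !is.na(predicted) & !is.na(truth)
  truth <- truth[keep]
  predicted <- predicted[keep]
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_table", "matrix"))
}

#' Diagnostic metrics from a confusion matrix
#'
#' The matrix is collapsed to positive-vs-rest before computing sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`
#' and the total error `(FP+FN)/total`. A ratio with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm `confusion_table` (k x k; rows truth, columns predicted).
#' @param positive_class the class treated as positive.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `total_error`, plus the collapsed counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_metrics <- function(cm, positive_class) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  if (!positive_class %in% rownames(cm)) {
    stop("positive_class '", positive_class, "' not among classes")
  }
  pos <- rownames(cm) == positive_class
  tp <- sum(cm[pos, pos])
  fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos])
  tn <- sum(cm[!pos, !pos])
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       total_error = (fp + fn) / sum(cm),
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-class sensitivity and PPV
#'
#' @param cm k x k `confusion_table`.
#' @return data.frame with one row per class: `class`, `sensitivity`
#'   (recall), `ppv` (precision); undefined ratios are `NA`.
#' @export
per_class_metrics <- function(cm) {
  classes <- rownames(cm)
  sens <- diag(cm) / rowSums(cm)
  ppv <- diag(cm) / colSums(cm)
  sens[rowSums(cm) == 0] <- NA_real_
  ppv[colSums(cm) == 0] <- NA_real_
  data.frame(class = classes, sensitivity = as.numeric(sens),
             ppv = as.numeric(ppv), stringsAsFactors = FALSE)
}

#' Stratified fold assignment
#'
#' Samples of each class are shuffled (deterministically under `seed`) and
#' dealt round-robin into `k` folds, so the assignment depends only on the
#' labels, `k` and `seed`.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
fold_assignments <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of samples")
  if (k < 2) stop("k must be >= 2")
  small <- table(labels) < k
  if (any(small)) {
    warning("class(es) with fewer than k members, stratification degrades: ",
            paste(names(small)[small], collapse = ", "))
  }
  folds <- integer(n)
  with_local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the C4.5 trainer
#'
#' Training metrics come from a tree fit on the full table and applied to it;
#' cross-validated metrics pool the held-out predictions of `k` fits, each
#' trained with one fold removed. Deterministic under a fixed seed.
#'
#' @param x feature data frame.
#' @param y class labels.
#' @param params [c45_params()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `folds`, `tree` (full-table fit), `train_cm`/`cv_cm`
#'   (confusion tables), `train_metrics`/`cv_metrics` (per-class sensitivity
#'   and PPV), `total_error` and `cv_total_error` (fractions in `[0, 1]`).
#' @export
kfold_cv <- function(x, y, params = c45_params(), k = 5, seed = 1L) {
  y <- as.character(y)
  folds <- fold_assignments(y, k, seed)
  classes <- sort(unique(y))
  full <- c45_train(x, y, params)
  train_pred <- predict_tree(full, x)
  cv_pred <- character(length(y))
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- c45_train(x[!hold, , drop = FALSE], y[!hold], params)
    cv_pred[hold] <- predict_tree(fit, x[hold, , drop = FALSE])
  }
  train_cm <- confusion_table(y, train_pred, classes)
  cv_cm <- confusion_table(y, cv_pred, classes)
  err <- function(cm) 1 - sum(diag(cm)) / sum(cm)
  list(folds = folds, tree = full,
       train_cm = train_cm, cv_cm = cv_cm,
       train_metrics = per_class_metrics(train_cm),
       cv_metrics = per_class_metrics(cv_cm),
       total_error = err(train_cm),
       cv_total_error = err(cv_cm))
}

#' ROC AUC by the rank (Mann-Whitney) identity
#'
#' `AUC = U / (n1 * n0)` with ties counted one half, equivalently the
#' probability that a random positive scores above a random negative. The
#' standard error is the Hanley-McNeil estimate.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @param positive value of `labels` counted as positive.
#' @return list with `auc` and `se`.
#' @export
roc_auc <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks for ties
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se)
}

#' Mann-Whitney U test for two independent samples
#'
#' `U` is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact (enumeration of all rank assignments) when
#' `n1 + n2 <= 12` and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `U` (statistic of the first sample), `p` (two-sided)
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (n1 + n2 <= 12 && !ties) {
    # exact null distribution of U by enumeration of rank assignments
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(combos, nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    return(list(U = u, p = min(1, p), method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_sizes <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- u - mu
  correction <- sign(z) * 0.5
  z <- (z - correction) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(U = u, p = min(1, p), method = "normal")
}

#' Histology-vs-molecular discordance summary
#'
#' A sample is a false positive when the molecular classification calls it
#' malignant but histology calls it benign, and a false negative in the
#' opposite case. Percentages are of the total sample count, to two decimal
#' places (half away from zero).
#'
#' @param molecular,histology aligned binary label vectors
#'   (`"benign"`/`"malignant"`).
#' @return list with `n`, `n_discordant`, `n_false_pos`, `n_false_neg`,
#'   `pct_discordant`, `pct_false_pos`, `pct_false_neg`.
#' @export
discordance_report <- function(molecular, histology) {
  if (length(molecular) != length(histology)) {
    stop("label vectors differ in length")
  }
  lv <- c("benign", "malignant")
  if (!all(molecular %in% lv) || !all(histology %in% lv)) {
    stop("labels must be 'benign' or 'malignant'")
  }
  n <- length(molecular)
  fp <- sum(molecular == "malignant" & histology == "benign")
  fn <- sum(molecular == "benign" & histology == "malignant")
  pct <- function(x) round_half_away(100 * x / n, 2)
  list(n = n, n_discordant = fp + fn, n_false_pos = fp, n_false_neg = fn,
       pct_discordant = pct(fp + fn), pct_false_pos = pct(fp),
       pct_false_neg = pct(fn))
}
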