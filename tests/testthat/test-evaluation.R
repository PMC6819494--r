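# Diagnostic metrics, cross-validation, ROC AUC, Mann-Whitney and the
# discordance summary.

test_that("confusion metrics reproduce the textbook ratios", {
  cm <- confusion_table(c(rep("malignant", 43), rep("benign", 101)),
                        c(rep("malignant", 17), rep("benign", 26),
                          rep("malignant", 2), rep("benign", 99)),
                        classes = c("malignant", "benign"))
  m <- confusion_metrics(cm, "malignant")
  expect_equal(round(m$ppv, 2), 0.89)      # 17/19 = 0.8947
  expect_equal(round(m$npv, 2), 0.79)      # 99/125 = 0.7920
  expect_equal(m$total_error, 28 / 144)
  perfect <- confusion_table(c("a", "a", "b"), c("a", "a", "b"))
  mp <- confusion_metrics(perfect, "a")
  expect_equal(unlist(mp[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_equal(mp$total_error, 0)
  # nobody called positive: PPV undefined, not zero
  none <- confusion_table(c("a", "b"), c("b", "b"), classes = c("a", "b"))
  expect_true(is.na(confusion_metrics(none, "a")$ppv))
  expect_error(confusion_metrics(none[0, 0, drop = FALSE], "a"))
})

test_that("metrics are invariant to consistent class relabelling", {
  truth <- sample(c("x", "y"), 40, replace = TRUE)
  pred <- sample(c("x", "y"), 40, replace = TRUE)
  m1 <- confusion_metrics(confusion_table(truth, pred), "x")
  relabel <- c(x = "pos", y = "neg")
  m2 <- confusion_metrics(confusion_table(relabel[truth], relabel[pred]), "pos")
  expect_equal(m1, m2)
})

test_that("fold assignment is a stratified, seed-deterministic partition", {
  labels <- rep(c("a", "b", "c"), c(30, 20, 10))
  f1 <- fold_assignments(labels, 5, seed = 3)
  f2 <- fold_assignments(labels, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, fold_assignments(labels, 5, seed = 4)))
  expect_setequal(unique(f1), 1:5)
  for (cls in unique(labels)) {
    per_fold <- table(f1[labels == cls])
    expect_lte(max(per_fold) - min(per_fold), 1)   # balanced within class
  }
  expect_error(fold_assignments(labels, 100, 1), "exceeds")
  expect_warning(fold_assignments(c("a", "a", "b", "a", "a"), 3, 1),
                 "stratification")
})

test_that("cross-validation memorizes a noiseless separable table", {
  x <- data.frame(f = c(rnorm(20, 0), rnorm(20, 10)))
  y <- rep(c("lo", "hi"), each = 20)
  cv <- kfold_cv(x, y, c45_params(min_leaf = 1), k = 5, seed = 2)
  expect_equal(cv$cv_total_error, 0)
  expect_equal(cv$total_error, 0)
  # folds partition the samples
  expect_equal(length(cv$folds), 40)
  expect_setequal(unique(cv$folds), 1:5)
})

test_that("cross-validated error shows optimism over training error", {
  replicates <- 50
  worse <- logical(replicates)
  for (s in seq_len(replicates)) {
    coh <- generate_cohort(cohort_config(seed = s))
    g <- molecular_grouping(coh)
    cv <- kfold_cv(panel_feature_matrix(coh), g$binary_label, k = 5, seed = s)
    worse[s] <- cv$cv_total_error > cv$total_error
  }
  expect_gte(mean(worse), 0.9)
})

test_that("rank AUC equals exhaustive pair counting and behaves at the edges", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1), positive = 1)$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4), positive = 1)$auc, 0.5)
  set.seed(6)
  for (i in 1:40) {
    scores <- sample(1:8, 12, replace = TRUE)      # ties likely
    labels <- rep(c(TRUE, FALSE), each = 6)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC complement identity holds for tie-free scores", {
  set.seed(7)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1)
})

test_that("the Hanley-McNeil standard error matches its closed form", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.9, 0.7)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  out <- roc_auc(scores, labels)
  a <- out$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  expect_equal(out$se,
               sqrt((a * (1 - a) + 2 * (q1 - a^2) + 2 * (q2 - a^2)) / 9))
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("Mann-Whitney matches exact enumeration and the reference code", {
  out <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)                      # 2 * 1/20
  expect_equal(out$method, "exact")
  same <- mann_whitney(c(1, 2, 2, 5), c(2, 5, 1, 2))
  expect_gt(same$p, 0.95)
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(8:30, 1))
    b <- rnorm(sample(8:30, 1), mean = runif(1, -1, 1))
    mine <- mann_whitney(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                               exact = FALSE))
    expect_equal(mine$U, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("discordance counts false positives and negatives correctly", {
  mol <- c(rep("malignant", 5), rep("benign", 15), rep("benign", 474))
  his <- c(rep("benign", 5), rep("malignant", 15), rep("benign", 474))
  out <- discordance_report(mol, his)
  expect_equal(out$n_discordant, 20)
  expect_equal(out$pct_false_pos, 1.01)          # 5/494
  expect_equal(out$pct_false_neg, 3.04)          # 15/494 to 2 dp
  same <- discordance_report(rep("benign", 10), rep("benign", 10))
  expect_equal(same$n_discordant, 0)
  flipped <- discordance_report(rep("benign", 4), rep("malignant", 4))
  expect_equal(flipped$n_discordant, 4)
  expect_error(discordance_report("benign", c("benign", "benign")), "length")
})
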