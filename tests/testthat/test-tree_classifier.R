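# Fixed trees, rendering, entropy / gain-ratio splitting and the C4.5
# trainer.

test_that("the malignancy tree reproduces every printed branch", {
  # root right: elevated HMGA2 alone decides Malignant
  r <- apply_malignancy_tree(panel_row(hmga2_lin = 0.1))
  expect_equal(r$class, "Malignant")
  expect_match(r$trace, "HMGA2 >= 0.0918")
  # deep benign path
  r <- apply_malignancy_tree(panel_row(hmga2_lin = 0.05, mir375_log2 = -13,
                                       mir221_lin = 0.001, mir146b_lin = 1.0))
  expect_equal(r$class, "Benign")
  expect_match(r$trace, "miR-146b < 1.5362")
  # miR-375 decides without inspecting the deeper markers
  r <- apply_malignancy_tree(panel_row(hmga2_lin = 0.05, mir375_log2 = -10))
  expect_equal(r$class, "Malignant")
  expect_false(grepl("miR-221", r$trace))
  # miR-221 branch and miR-146b malignant branch
  expect_equal(apply_malignancy_tree(panel_row(hmga2_lin = 0.05,
                                               mir221_lin = 0.02))$class,
               "Malignant")
  expect_equal(apply_malignancy_tree(panel_row(hmga2_lin = 0.05,
                                               mir146b_lin = 2.0))$class,
               "Malignant")
  # boundary values go right (>= convention)
  expect_equal(apply_malignancy_tree(panel_row(hmga2_lin = 0.0918))$class,
               "Malignant")
  expect_equal(apply_malignancy_tree(panel_row(hmga2_lin = 0.05,
                                               mir375_log2 = -12.1213))$class,
               "Malignant")
})

test_that("the typing tree reproduces every printed branch", {
  expect_equal(apply_typing_tree(panel_row(mir375_log2 = log2(5.2514)))$class,
               "MTC")
  expect_equal(apply_typing_tree(panel_row(mir375_log2 = log2(6)))$class, "MTC")
  expect_equal(apply_typing_tree(panel_row(mir146b_lin = 0.5))$class, "PTC")
  expect_equal(apply_typing_tree(panel_row(mir146b_lin = 0.1,
                                           mtdna_lin = 6000))$class, "HCC")
  expect_equal(apply_typing_tree(panel_row(mir146b_lin = 0.1,
                                           mtdna_lin = 100))$class, "FNMM")
  # boundaries
  expect_equal(apply_typing_tree(panel_row(mir146b_lin = 0.1721))$class, "PTC")
  expect_equal(apply_typing_tree(panel_row(mtdna_lin = 5716.3013))$class, "HCC")
})

test_that("missing markers on the realized path are reported, off-path ignored", {
  p <- panel_row(hmga2_lin = 0.05)
  p$level_mir375 <- NA
  out <- apply_malignancy_tree(p)
  expect_true(is.na(out$class))
  expect_match(out$reason, "miR-375")
  # HMGA2 decides at the root: a missing miR-375 is never consulted
  p2 <- panel_row(hmga2_lin = 0.5)
  p2$level_mir375 <- NA
  expect_equal(apply_malignancy_tree(p2)$class, "Malignant")
})

test_that("fixed trees are pure functions", {
  p <- panel_row(hmga2_lin = 0.05, mir221_lin = 0.02)
  expect_identical(apply_malignancy_tree(p), apply_malignancy_tree(p))
})

test_that("leaf rendering matches the printed listing format", {
  expect_equal(format_leaf("Malignant", 8 / 9, 9),
               "Diagnosis = Malignant (88.9% of 9 examples)")
  expect_equal(format_leaf("Benign", 0.986, 214),
               "Diagnosis = Benign (98.6% of 214 examples)")
  expect_equal(format_leaf("MTC", 1, 18),
               "Diagnosis = MTC (100.0% of 18 examples)")
  lines <- render_tree(malignancy_tree())
  expect_true(any(grepl("^HMGA2 < 0.0918$", lines)))
  expect_true(any(grepl(
    "HMGA2 >= 0.0918 then Diagnosis = Malignant \\(100.0% of 214 examples\\)",
    lines)))
  expect_true(any(grepl("miR-146b < 1.5362 then Diagnosis = Benign \\(98.6% of 214 examples\\)",
                        lines)))
  tlines <- render_tree(typing_tree())
  expect_true(any(grepl("mtDNA < 5716.3013 then Diagnosis = FNMM \\(96.0% of 76 examples\\)",
                        tlines)))
  expect_true(any(grepl("miR-146b >= 0.1721 then Diagnosis = PTC \\(98.8% of 164 examples\\)",
                        tlines)))
})

test_that("entropy matches closed forms and its invariants", {
  expect_equal(entropy(c(5, 5)), 1)
  expect_equal(entropy(c(7, 0)), 0)
  expect_equal(entropy(c(1, 1, 2)), 1.5)
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(c(-1, 2)), "non-negative")
  set.seed(4)
  for (i in 1:20) {
    counts <- rpois(sample(2:5, 1), 4) + 1
    e <- entropy(counts)
    expect_equal(e, entropy(sample(counts)))              # permutation invariant
    expect_gte(e, 0)
    expect_lte(e, log2(length(counts)) + 1e-12)
  }
  expect_equal(entropy(c(3, 3, 3)), log2(3))               # maximal iff equal
  expect_lt(entropy(c(4, 3, 2)), log2(3))
})

test_that("best_split solves the worked examples", {
  s <- best_split(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain_ratio, 1)
  expect_null(best_split(c(1, 2, 3, 4), c("A", "A", "A", "A")))
  expect_null(best_split(c(2, 2, 2), c("A", "B", "A")))    # identical values
})

test_that("best_split equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:150) {
    n <- sample(4:25, 1)
    values <- round(runif(n, 0, 10), sample(c(0, 1, 3), 1))  # allow ties
    labels <- sample(LETTERS[1:sample(2:3, 1)], n, replace = TRUE)
    mine <- best_split(values, labels)
    oracle <- brute_best_split(values, labels)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$gain_ratio, oracle$gain_ratio, tolerance = 1e-9)
      expect_equal(mine$threshold, oracle$threshold, tolerance = 1e-9)
    }
  }
})

test_that("c45_train handles the degenerate and tiny cases", {
  x <- data.frame(f = c(1, 2, 3))
  expect_error(c45_train(x[0, , drop = FALSE], character(0)), "empty")
  single <- c45_train(x, c("A", "A", "A"), c45_params(min_leaf = 1))
  expect_equal(single$root$type, "leaf")
  expect_equal(single$root$purity, 1)
  four <- c45_train(data.frame(f = c(1, 2, 3, 4)), c("A", "A", "B", "B"),
                    c45_params(min_leaf = 1, pruning_cf = 1))
  expect_equal(four$root$marker, "f")
  expect_equal(four$root$threshold, 2.5)
  expect_equal(four$root$left$class, "A")
  expect_equal(four$root$right$class, "B")
  expect_equal(predict_tree(four, data.frame(f = c(0, 2.5, 9))),
               c("A", "B", "B"))
})

test_that("a trained tree never does worse than the majority class on its training set", {
  set.seed(12)
  for (i in 1:10) {
    n <- 60
    x <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- ifelse(x$a + rnorm(n, 0, 0.5) > 0, "pos", "neg")
    fit <- c45_train(x, y)
    err <- mean(predict_tree(fit, x) != y)
    majority_err <- 1 - max(table(y)) / n
    expect_lte(err, majority_err + 1e-12)
  }
})

test_that("pessimistic pruning simplifies noise and keeps signal", {
  set.seed(8)
  n <- 200
  x <- data.frame(signal = rnorm(n), noise = rnorm(n))
  y <- ifelse(x$signal > 0, "pos", "neg")
  count_nodes <- function(node) {
    if (node$type == "leaf") 1L
    else 1L + count_nodes(node$left) + count_nodes(node$right)
  }
  unpruned <- c45_train(x, y, c45_params(min_leaf = 2, pruning_cf = 1))
  pruned <- c45_train(x, y, c45_params(min_leaf = 2, pruning_cf = 0.25))
  expect_lte(count_nodes(pruned$root), count_nodes(unpruned$root))
  expect_equal(tree_root_feature(pruned), "signal")
  # pure-noise labels collapse to (nearly) a stump under pruning
  y_rand <- sample(c("pos", "neg"), n, replace = TRUE)
  shrunk <- c45_train(x, y_rand, c45_params(min_leaf = 2, pruning_cf = 0.25))
  grown <- c45_train(x, y_rand, c45_params(min_leaf = 2, pruning_cf = 1))
  expect_lt(count_nodes(shrunk$root), count_nodes(grown$root))
})

test_that("trees survive a JSON round trip", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_tree_json(malignancy_tree(), tmp)
  back <- read_tree_json(tmp)
  expect_equal(render_tree(back), render_tree(malignancy_tree()))
  p <- panel_row(hmga2_lin = 0.05, mir221_lin = 0.02)
  expect_equal(classify_with_tree(back, p)$class,
               apply_malignancy_tree(p)$class)
  # trained tree too
  fit <- c45_train(data.frame(f = c(1, 2, 3, 4)), c("A", "A", "B", "B"),
                   c45_params(min_leaf = 1))
  tmp2 <- tempfile(fileext = ".json")
  on.exit(unlink(tmp2), add = TRUE)
  write_tree_json(fit, tmp2)
  expect_equal(predict_tree(read_tree_json(tmp2), data.frame(f = c(0, 5))),
               c("A", "B"))
})

test_that("majority-branch policy routes missing values, exclude reports them", {
  fit <- c45_train(data.frame(f = c(1, 2, 3, 4, 5, 6)),
                   c("A", "A", "A", "B", "B", "B"), c45_params(min_leaf = 1))
  miss <- data.frame(f = NA_real_)
  expect_true(is.na(predict_tree(fit, miss, missing_policy = "exclude")))
  expect_false(is.na(predict_tree(fit, miss, missing_policy = "majority_branch")))
})
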