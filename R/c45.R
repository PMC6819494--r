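# C4.5-style decision-tree induction: entropy impurity, gain-ratio selection
# over midpoint thresholds of continuous features, greedy recursive growth,
# and pessimistic (confidence-bound) post-pruning.

#' Shannon entropy of class counts
#'
#' @param class_counts non-negative counts (named or not), total `> 0`.
#' @return Entropy in bits, `-sum(p_i log2 p_i)` with `0 log 0 = 0`; lies in
#'   `[0, log2(k)]` and is maximal iff the counts are equal.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative")
  total <- sum(class_counts)
  if (total <= 0) stop("total count must be positive")
  p <- class_counts[class_counts > 0] / total
  -sum(p * log2(p))
}

# entropy of each row of a count matrix (vectorized helper for best_split)
.row_entropy <- function(m) {
  s <- rowSums(m)
  p <- m / s
  lp <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(lp)
}

#' Best binary split of a continuous feature
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values; the candidate maximizing the gain ratio (information gain divided
#' by split information) among splits with positive gain is returned, ties
#' broken towards the smaller threshold. Instances with a missing value are
#' excluded.
#'
#' @param values numeric feature values.
#' @param labels class labels, same length.
#' @param min_leaf minimum number of instances required on each side.
#' @return list with `threshold`, `gain_ratio` and `gain`, or `NULL` when no
#'   admissible split exists (all values identical, all labels identical, or
#'   no candidate with positive gain).
#' @export
best_split <- function(values, labels, min_leaf = 1) {
  ok <- !is.na(values)
  values <- values[ok]
  labels <- labels[ok]
  n <- length(values)
  if (n < 2 || length(unique(values)) < 2) return(NULL)
  ord <- order(values)
  v <- values[ord]
  l <- factor(labels[ord])
  k <- nlevels(l)
  ind <- matrix(0L, nrow = n, ncol = k)
  ind[cbind(seq_len(n), as.integer(l))] <- 1L
  cum <- apply(ind, 2, cumsum)
  if (k == 1) return(NULL)
  cand <- which(v[-n] < v[-1])                       # split after position i
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (length(cand) == 0) return(NULL)
  left <- cum[cand, , drop = FALSE]
  total <- cum[n, ]
  right <- matrix(rep(total, each = length(cand)), nrow = length(cand)) - left
  nl <- cand
  nr <- n - cand
  h_all <- entropy(total)
  gain <- h_all - (nl / n) * .row_entropy(left) - (nr / n) * .row_entropy(right)
  split_info <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
  ratio <- gain / split_info
  pos <- gain > 1e-12
  if (!any(pos)) return(NULL)
  ratio[!pos] <- -Inf
  best <- which.max(ratio)                           # first max: smaller threshold
  i <- cand[best]
  list(threshold = (v[i] + v[i + 1]) / 2,
       gain_ratio = ratio[best],
       gain = gain[best])
}

#' C4.5 trainer settings
#'
#' @param min_leaf minimum instances per branch of a split (default 5).
#' @param pruning_cf confidence factor in `(0, 1]` for pessimistic pruning
#'   (default 0.25, the classical C4.5 default); 1 disables pruning.
#' @param max_depth maximum tree depth (`Inf` = unlimited).
#' @param missing_policy how prediction handles a missing split attribute:
#'   `"exclude"` (unclassifiable, reported) or `"majority_branch"` (follow
#'   the branch with larger training support).
#' @return named list of class `c45_params`.
#' @export
c45_params <- function(min_leaf = 5, pruning_cf = 0.25, max_depth = Inf,
                       missing_policy = c("exclude", "majority_branch")) {
  if (min_leaf < 1) stop("min_leaf must be >= 1")
  if (pruning_cf <= 0 || pruning_cf > 1) stop("pruning_cf must lie in (0, 1]")
  missing_policy <- match.arg(missing_policy)
  structure(list(min_leaf = as.integer(min_leaf), pruning_cf = pruning_cf,
                 max_depth = max_depth, missing_policy = missing_policy),
            class = "c45_params")
}

# upper confidence bound on the error rate of a leaf with e errors out of n
# (Clopper-Pearson upper limit at level 1 - cf); used by pessimistic pruning
.pessimistic_error <- function(e, n, cf) {
  if (n == 0) return(0)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

.majority <- function(counts) {
  names(counts)[which.max(counts)]
}

.grow_c45 <- function(x, y, params, depth) {
  counts <- table(y)
  total <- sum(counts)
  make_leaf <- function() {
    tree_leaf(.majority(counts), max(counts) / total, total)
  }
  if (length(unique(as.character(y))) == 1 || total < 2 * params$min_leaf ||
      depth >= params$max_depth) {
    return(make_leaf())
  }
  splits <- lapply(names(x), function(f) best_split(x[[f]], y, params$min_leaf))
  ok <- !vapply(splits, is.null, logical(1))
  if (!any(ok)) return(make_leaf())
  ratios <- vapply(splits, function(s) if (is.null(s)) -Inf else s$gain_ratio,
                   numeric(1))
  best <- which.max(ratios)                # first max: fixed feature order
  sp <- splits[[best]]
  feat <- names(x)[best]
  v <- x[[feat]]
  go_right <- !is.na(v) & v >= sp$threshold
  go_left <- !is.na(v) & !go_right
  # missing split attribute: instance dropped from the subtree (exclude policy
  # at training time; prediction-time handling is configurable)
  node <- tree_node(feat, "identity", sp$threshold,
                    left = .grow_c45(x[go_left, , drop = FALSE], y[go_left],
                                     params, depth + 1),
                    right = .grow_c45(x[go_right, , drop = FALSE], y[go_right],
                                      params, depth + 1))
  node$counts <- as.integer(counts)
  node$count_classes <- names(counts)
  node
}

# bottom-up pessimistic pruning; returns list(node, est_errors)
.prune_c45 <- function(node, cf) {
  if (node$type == "leaf") {
    e <- node$support * (1 - node$purity)
    return(list(node = node, est = .pessimistic_error(e, node$support, cf)))
  }
  left <- .prune_c45(node$left, cf)
  right <- .prune_c45(node$right, cf)
  node$left <- left$node
  node$right <- right$node
  subtree_est <- left$est + right$est
  counts <- stats::setNames(node$counts, node$count_classes)
  n <- sum(counts)
  e_leaf <- n - max(counts)
  leaf_est <- .pessimistic_error(e_leaf, n, cf)
  if (leaf_est <= subtree_est) {
    leaf <- tree_leaf(.majority(counts), max(counts) / n, n)
    return(list(node = leaf, est = leaf_est))
  }
  list(node = node, est = subtree_est)
}

#' Train a C4.5-style decision tree
#'
#' Greedy recursive induction on gain ratio over continuous features, with
#' stopping at node purity, at `2 * min_leaf` instances, at `max_depth`, or
#' when no positive-gain split exists; followed by pessimistic post-pruning
#' at confidence `pruning_cf` (a subtree is replaced by a leaf when the
#' upper-bound error estimate of the leaf does not exceed that of the
#' subtree). Leaves record the majority class, its purity and the training
#' support.
#'
#' @param x data.frame of numeric feature columns (e.g.
#'   [panel_feature_matrix()]).
#' @param y class labels (character or factor), one per row of `x`.
#' @param params [c45_params()].
#' @return `decision_tree` with provenance `"trained"`. Node scales are
#'   `"identity"`: prediction reads the feature columns of the supplied data
#'   frame directly.
#' @export
c45_train <- function(x, y, params = c45_params()) {
  if (nrow(x) == 0) stop("empty training table")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (anyNA(y)) stop("missing class labels")
  y <- as.character(y)
  root <- .grow_c45(x, y, params, 0)
  if (params$pruning_cf < 1) {
    root <- .prune_c45(root, params$pruning_cf)$node
  }
  tree <- decision_tree(root, sort(unique(y)), "trained")
  tree$params <- params
  tree
}

#' Predict classes with a trained tree
#'
#' @param tree trained `decision_tree`.
#' @param x feature data frame.
#' @param missing_policy see [c45_params()]; `"majority_branch"` routes
#'   instances with a missing split attribute towards the branch with larger
#'   training support.
#' @return character vector of predicted classes (`NA` for unclassifiable
#'   rows under the `"exclude"` policy).
#' @export
predict_tree <- function(tree, x, missing_policy = NULL) {
  if (is.null(missing_policy)) {
    missing_policy <- if (!is.null(tree$params)) tree$params$missing_policy
    else "exclude"
  }
  n <- nrow(x)
  out <- character(n)
  predict_one <- function(node, i) {
    while (node$type != "leaf") {
      v <- x[[node$marker]][i]
      if (is.na(v)) {
        if (missing_policy == "exclude") return(NA_character_)
        v <- if (.branch_support(node$right) >= .branch_support(node$left))
          node$threshold else -Inf
      }
      node <- if (v >= node$threshold) node$right else node$left
    }
    node$class
  }
  for (i in seq_len(n)) out[i] <- predict_one(tree$root, i)
  out
}

.branch_support <- function(node) {
  if (node$type == "leaf") return(node$support)
  .branch_support(node$left) + .branch_support(node$right)
}

#' Root split feature of a tree
#'
#' @param tree a `decision_tree`.
#' @return Marker/feature name tested at the root, or `NA` for a single-leaf
#'   tree.
#' @export
tree_root_feature <- function(tree) {
  if (tree$root$type == "leaf") NA_character_ else tree$root$marker
}
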