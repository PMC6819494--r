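# The two fixed decision trees, tree application with leaf traces, text
# rendering in the "Diagnosis = <class> (<purity>% of <n> examples)" style,
# and JSON (de)serialization.
#
# Node representation: internal nodes are lists with `marker`, `scale`
# ("linear" or "log2" for panel markers, "identity" for trained trees over a
# plain feature frame), `threshold`, `left` (< branch) and `right` (>=
# branch); leaves carry `class`, `purity` and `support`. A value equal to a
# threshold goes right. The miR-375 threshold of the malignancy tree
# (-12.1213) can only be a log2 quantity; every other fixed threshold is a
# linear 2^-dCq level, so each node carries its scale explicitly.

tree_node <- function(marker, scale, threshold, left, right) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(type = "node", marker = marker, scale = scale,
                 threshold = threshold, left = left, right = right),
            class = "tree_node")
}

tree_leaf <- function(class, purity, support) {
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  structure(list(type = "leaf", class = class, purity = purity,
                 support = as.integer(support)),
            class = "tree_node")
}

decision_tree <- function(root, classes, provenance) {
  structure(list(root = root, classes = classes, provenance = provenance),
            class = "decision_tree")
}

#' Fixed benign-vs-malignant decision tree
#'
#' The four-marker malignancy tree: HMGA2 (linear cutoff 0.0918) at the root,
#' then miR-375 (log2 cutoff -12.1213), miR-221 (linear 0.0105) and miR-146b
#' (linear 1.5362); a value at or above a cutoff moves towards "Malignant".
#' Leaf purities and supports are those of the original training series.
#'
#' @return `decision_tree` object with classes `Benign`/`Malignant`.
#' @export
malignancy_tree <- function() {
  root <- tree_node(
    "hmga2", "linear", 0.0918,
    left = tree_node(
      "mir375", "log2", -12.1213,
      left = tree_node(
        "mir221", "linear", 0.0105,
        left = tree_node(
          "mir146b", "linear", 1.5362,
          left = tree_leaf("Benign", 0.986, 214),
          right = tree_leaf("Malignant", 0.889, 9)),
        right = tree_leaf("Malignant", 1.000, 19)),
      right = tree_leaf("Malignant", 1.000, 37)),
    right = tree_leaf("Malignant", 1.000, 214))
  decision_tree(root, c("Benign", "Malignant"), "fixed_malignancy")
}

#' Fixed tumor-typing decision tree
#'
#' Types molecularly malignant tumors: miR-375 (linear cutoff 5.2514) -> MTC;
#' else miR-146b (linear 0.1721) -> PTC; else mtDNA/nDNA ratio (5716.3013) ->
#' HCC, otherwise FNMM.
#'
#' @return `decision_tree` object with classes `FNMM`/`HCC`/`PTC`/`MTC`.
#' @export
typing_tree <- function() {
  root <- tree_node(
    "mir375", "linear", 5.2514,
    left = tree_node(
      "mir146b", "linear", 0.1721,
      left = tree_node(
        "mtdna", "linear", 5716.3013,
        left = tree_leaf("FNMM", 0.960, 76),
        right = tree_leaf("HCC", 1.000, 23)),
      right = tree_leaf("PTC", 0.988, 164)),
    right = tree_leaf("MTC", 1.000, 18))
  decision_tree(root, c("FNMM", "HCC", "PTC", "MTC"), "fixed_typing")
}

# fetch the value a node tests, for panel-marker nodes or identity features
.node_value <- function(node, data) {
  if (node$scale == "identity") {
    if (!node$marker %in% names(data)) {
      stop("data lack feature '", node$marker, "'")
    }
    data[[node$marker]]
  } else {
    panel_value(data, node$marker, node$scale)
  }
}

# classify one row index through the tree, collecting the visited-node trace
.apply_node <- function(node, data, i, trace) {
  if (node$type == "leaf") {
    return(list(class = node$class, trace = c(trace, format_leaf(node)),
                reason = NA_character_))
  }
  v <- .node_value(node, data)[i]
  lbl <- sprintf("%s %s %s", marker_display_name(node$marker),
                 c("<", ">=")[(!is.na(v) && v >= node$threshold) + 1L],
                 format(node$threshold, digits = 10))
  if (is.na(v)) {
    return(list(class = NA_character_, trace = trace,
                reason = paste0("missing ", marker_display_name(node$marker),
                                " on the decision path")))
  }
  branch <- if (v >= node$threshold) node$right else node$left
  .apply_node(branch, data, i, c(trace, lbl))
}

#' Classify samples with a decision tree
#'
#' @param tree a `decision_tree` (fixed or trained).
#' @param data marker panel data frame (fixed trees) or feature data frame
#'   (trained trees).
#' @return data.frame with one row per input row: `class` (NA when a marker
#'   on the realized path is missing), `trace` (visited nodes, `" | "`
#'   separated) and `reason` (why a sample was unclassifiable).
#' @export
classify_with_tree <- function(tree, data) {
  n <- nrow(data)
  res <- lapply(seq_len(n), function(i) .apply_node(tree$root, data, i, character()))
  out <- data.frame(
    class = vapply(res, `[[`, character(1), "class"),
    trace = vapply(res, function(r) paste(r$trace, collapse = " | "), character(1)),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  if ("sample_id" %in% names(data)) {
    out <- cbind(data.frame(sample_id = data$sample_id,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' @rdname classify_with_tree
#' @param panels marker panel data frame.
#' @return `apply_malignancy_tree()`: classification by the fixed
#'   benign/malignant tree.
#' @export
apply_malignancy_tree <- function(panels) {
  classify_with_tree(malignancy_tree(), panels)
}

#' @rdname classify_with_tree
#' @return `apply_typing_tree()`: classification by the fixed typing tree.
#' @export
apply_typing_tree <- function(panels) {
  classify_with_tree(typing_tree(), panels)
}

#' Format a leaf in the printed-listing style
#'
#' @param leaf a leaf node, or a class label when `purity`/`support` given.
#' @param purity,support leaf purity in `[0, 1]` and training support.
#' @return e.g. `"Diagnosis = Malignant (88.9% of 9 examples)"` (purity to one
#'   decimal place).
#' @export
format_leaf <- function(leaf, purity = NULL, support = NULL) {
  if (is.character(leaf)) {
    leaf <- list(class = leaf, purity = purity, support = support)
  }
  sprintf("Diagnosis = %s (%.1f%% of %d examples)",
          leaf$class, 100 * leaf$purity, as.integer(leaf$support))
}

.render_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    return(paste0(pad, format_leaf(node)))
  }
  name <- marker_display_name(node$marker)
  thr <- format(node$threshold, digits = 10)
  branch <- function(child, op) {
    head <- sprintf("%s%s %s %s", pad, name, op, thr)
    if (child$type == "leaf") {
      paste0(head, " then ", format_leaf(child))
    } else {
      c(head, .render_node(child, indent + 1))
    }
  }
  c(branch(node$left, "<"), branch(node$right, ">="))
}

#' Render a decision tree as indented text
#'
#' One branch per line; branches ending in a leaf append
#' `then Diagnosis = <class> (<purity>% of <n> examples)`.
#'
#' @param tree a `decision_tree`.
#' @return character vector of lines.
#' @export
render_tree <- function(tree) {
  .render_node(tree$root, 0)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("Decision tree (%s; classes: %s)\n", x$provenance,
              paste(x$classes, collapse = ", ")))
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

.node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", class = node$class, purity = node$purity,
         support = node$support)
  } else {
    list(type = "node", marker = node$marker, scale = node$scale,
         threshold = node$threshold,
         left = .node_to_list(node$left), right = .node_to_list(node$right))
  }
}

.node_from_list <- function(x) {
  if (x$type == "leaf") {
    tree_leaf(x$class, x$purity, x$support)
  } else {
    tree_node(x$marker, x$scale, x$threshold,
              .node_from_list(x$left), .node_from_list(x$right))
  }
}

#' Read and write decision trees as JSON
#'
#' Node scale tags and thresholds are preserved exactly.
#'
#' @param tree a `decision_tree`.
#' @param path file path.
#' @return `write_tree_json()` returns `path` invisibly; `read_tree_json()`
#'   the reconstructed `decision_tree`.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(provenance = tree$provenance, classes = tree$classes,
              root = .node_to_list(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  decision_tree(.node_from_list(obj$root),
                unlist(obj$classes), obj$provenance)
}
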