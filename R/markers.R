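# Marker registry shared by the generator, normalization and classifiers.
#
# Internal marker keys are lower-case tokens without punctuation (column-name
# safe); display names carry the conventional miRBase/HGNC spelling.

#' Marker panel vocabulary
#'
#' The panel consists of 13 target miRNAs (malignancy markers), three reference
#' miRNAs used for normalization, the HMGA2 mRNA level (normalized to PGK1) and
#' the mitochondrial-to-nuclear DNA copy ratio.
#'
#' @return `target_mirnas()`: character vector of the 13 target miRNA keys.
#' @export
target_mirnas <- function() {
  c("mir144", "mir145", "mir155", "mir146b", "mir183", "mir199b", "mir221",
    "mir223", "mir31", "mir375", "mir451a", "mir551b", "mir7")
}

#' @rdname target_mirnas
#' @return `reference_mirnas()`: the three reference miRNA keys.
#' @export
reference_mirnas <- function() {
  c("mir197", "mir23a", "mir29b")
}

#' @rdname target_mirnas
#' @return `panel_markers()`: all per-sample level keys (13 miRNAs, `hmga2`,
#'   `mtdna`).
#' @export
panel_markers <- function() {
  c(target_mirnas(), "hmga2", "mtdna")
}

# display names used by tree rendering and reports
.MARKER_DISPLAY <- c(
  mir144 = "miR-144", mir145 = "miR-145", mir155 = "miR-155",
  mir146b = "miR-146b", mir183 = "miR-183", mir199b = "miR-199b",
  mir221 = "miR-221", mir223 = "miR-223", mir31 = "miR-31",
  mir375 = "miR-375", mir451a = "miR-451a", mir551b = "miR-551b",
  mir7 = "miR-7", mir197 = "miR-197", mir23a = "miR-23a", mir29b = "miR-29b",
  hmga2 = "HMGA2", mtdna = "mtDNA", pgk1 = "PGK1", ndna = "nDNA"
)

#' Display name of a marker key
#'
#' @param marker character vector of internal marker keys.
#' @return Conventional names (e.g. `"miR-146b"`, `"HMGA2"`, `"mtDNA"`);
#'   unknown keys are returned unchanged.
#' @export
marker_display_name <- function(marker) {
  out <- .MARKER_DISPLAY[marker]
  out[is.na(out)] <- marker[is.na(out)]
  unname(out)
}

#' Histotype vocabulary
#'
#' @return Character vector of the histological diagnoses handled by the
#'   pipeline. `"anaplastic"` can additionally appear in generated cohorts but
#'   is excluded before classification (too few specimens to model).
#' @export
histotypes <- function() {
  c("goiter", "FTA", "FTC", "HCC", "PTC", "FVPTC", "MTC")
}

# papillary-family histotypes: the only ones where BRAF V600E / RET-PTC1 occur
.PTC_FAMILY <- c("PTC", "FVPTC")
# follicular-pattern histotypes subject to the BRAF discordance rule
.BRAF_DISCORDANT_SET <- c("goiter", "FTA", "FTC", "HCC")
# histologically malignant diagnoses
.MALIGNANT_HISTOTYPES <- c("FTC", "HCC", "PTC", "FVPTC", "MTC")

#' Mutation flag columns
#'
#' Binary 0/1 columns carried by every sample: the BRAF V600E point mutation,
#' the four RAS codon-61 mutations, and the RET-PTC1 and PAX8-PPARgamma
#' rearrangements.
#'
#' @return `mutation_columns()`: all seven flag column names.
#' @export
mutation_columns <- function() {
  c("mut_braf_v600e", "mut_hras_q61r", "mut_nras_q61k", "mut_nras_q61r",
    "mut_nras_q61l", "fus_ret_ptc1", "fus_pax8_pparg")
}

#' @rdname mutation_columns
#' @return `ras_columns()`: the four RAS codon-61 flag columns.
#' @export
ras_columns <- function() {
  c("mut_hras_q61r", "mut_nras_q61k", "mut_nras_q61r", "mut_nras_q61l")
}

#' Any-RAS indicator
#'
#' @param panels data frame carrying the RAS flag columns.
#' @return Integer vector, 1 where any of the four RAS codon-61 flags is set;
#'   missing flags are treated as 0 (see [ras_fn_confusion()] for the
#'   rationale).
#' @export
ras_any <- function(panels) {
  flags <- panels[, ras_columns(), drop = FALSE]
  flags[is.na(flags)] <- 0L
  as.integer(rowSums(flags) > 0)
}

# panel level column for a marker key ("mtdna" is stored as linear mtdna_ratio)
level_column <- function(marker) {
  ifelse(marker == "mtdna", "mtdna_ratio", paste0("level_", marker))
}

#' Extract the classifier feature matrix from a marker panel table
#'
#' Returns one numeric column per panel marker, all on log2 scale (the
#' mtDNA/nDNA ratio is log2-transformed), named by marker key. This is the
#' feature representation consumed by [c45_train()].
#'
#' @param panels marker panel data frame (see [generate_cohort()]).
#' @param markers marker keys to extract (default: all panel markers).
#' @return data.frame of log2 feature columns.
#' @export
panel_feature_matrix <- function(panels, markers = panel_markers()) {
  bad <- setdiff(markers, panel_markers())
  if (length(bad) > 0) {
    stop("unknown markers: ", paste(bad, collapse = ", "))
  }
  out <- lapply(markers, function(m) {
    col <- level_column(m)
    if (!col %in% names(panels)) {
      stop("panel table lacks column '", col, "'")
    }
    v <- panels[[col]]
    if (m == "mtdna") log2(v) else v
  })
  names(out) <- markers
  as.data.frame(out, optional = TRUE)
}

# fetch a panel marker on the scale a tree node asks for
panel_value <- function(panels, marker, scale) {
  col <- level_column(marker)
  if (!col %in% names(panels)) {
    stop("panel table lacks column '", col, "' needed by the tree")
  }
  v <- panels[[col]]
  stored_linear <- marker == "mtdna"
  if (scale == "linear") {
    if (stored_linear) v else 2^v
  } else if (scale == "log2") {
    if (stored_linear) log2(v) else v
  } else {
    stop("unknown node scale: ", scale)
  }
}

#' Round half away from zero
#'
#' Reported percentages use the round-half-away-from-zero convention
#' (41.5 -> 42, -41.5 -> -42), whereas base [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
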