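# delta-Cq normalization and sample-level QC filters.
#
# All miRNA and HMGA2 levels are stored on log2 scale (log2 of the 2^-dCq
# relative quantity); the mtDNA/nDNA ratio is stored linear. A Cq difference
# of 1 cycle corresponds to a factor of 2 in template amount, so the log2
# relative level is simply (reference Cq - target Cq).

#' Normalize a target miRNA against the three reference miRNAs
#'
#' The relative quantity is `2^-dCq` with `dCq = Cq_target - mean(Cq_refs)`.
#' Taking the arithmetic mean of the reference Cq values is mathematically
#' identical to normalizing against the geometric mean of the reference
#' amounts, since Cq is already a log2 quantity.
#'
#' @param cq_target Cq of the target miRNA.
#' @param cq_ref1,cq_ref2,cq_ref3 Cq of the three reference miRNAs
#'   (miR-197-3p, miR-23a-3p, miR-29b-3p).
#' @return log2 relative level, `mean(cq_refs) - cq_target`. `NA` if any
#'   reference Cq is missing. The linear level is `2^result`.
#' @examples
#' normalize_mirna(24, 25, 26, 27)  # +2 -> linear 4
#' @export
normalize_mirna <- function(cq_target, cq_ref1, cq_ref2, cq_ref3) {
  ref <- (cq_ref1 + cq_ref2 + cq_ref3) / 3
  ref - cq_target
}

#' Normalize HMGA2 mRNA against PGK1
#'
#' @param cq_hmga2 Cq of the HMGA2 assay.
#' @param cq_pgk1 Cq of the PGK1 reference assay.
#' @return log2 relative level `cq_pgk1 - cq_hmga2`; linear value `2^result`.
#' @export
normalize_hmga2 <- function(cq_hmga2, cq_pgk1) {
  cq_pgk1 - cq_hmga2
}

#' Mitochondrial-to-nuclear DNA copy ratio
#'
#' @param cq_mt Cq of the mtDNA-specific assay.
#' @param cq_n Cq of the nuclear-DNA assay.
#' @return Linear copy ratio `2^(cq_n - cq_mt)`, strictly positive.
#' @export
mtdna_ratio <- function(cq_mt, cq_n) {
  2^(cq_n - cq_mt)
}

#' Exclude samples with insufficient total RNA
#'
#' Samples whose total-RNA concentration is strictly below the threshold are
#' excluded from analysis; a concentration exactly at the threshold is
#' retained.
#'
#' @param records data frame with an `rna_ng_ul` column.
#' @param threshold exclusion cutoff in ng/ul (default 5).
#' @return list with elements `retained` and `excluded` (disjoint, order
#'   preserved, union = input).
#' @export
qc_low_rna <- function(records, threshold = 5) {
  if (!"rna_ng_ul" %in% names(records)) {
    stop("records lack an 'rna_ng_ul' column")
  }
  if (anyNA(records$rna_ng_ul)) {
    stop("rna_ng_ul must be present for every record")
  }
  low <- records$rna_ng_ul < threshold
  list(retained = records[!low, , drop = FALSE],
       excluded = records[low, , drop = FALSE])
}

#' Exclude BRAF-discordant follicular-pattern samples
#'
#' BRAF V600E is specific to papillary carcinoma; a BRAF-positive sample whose
#' pathology report says goiter, FTA, FTC or HCC indicates a probable
#' reporting error and is excluded from classifier development. BRAF-positive
#' PTC/FVPTC samples are retained.
#'
#' @param panels marker panel data frame with `histotype` and
#'   `mut_braf_v600e` columns.
#' @return list with `retained` and `excluded` data frames (disjoint, order
#'   preserved). Samples with a missing BRAF flag are retained with a warning.
#' @export
braf_discordance_filter <- function(panels) {
  for (col in c("histotype", "mut_braf_v600e")) {
    if (!col %in% names(panels)) stop("panels lack a '", col, "' column")
  }
  flag <- panels$mut_braf_v600e
  if (anyNA(flag)) {
    warning(sum(is.na(flag)), " sample(s) with missing BRAF flag retained")
    flag[is.na(flag)] <- 0L
  }
  discordant <- flag == 1 & panels$histotype %in% .BRAF_DISCORDANT_SET
  list(retained = panels[!discordant, , drop = FALSE],
       excluded = panels[discordant, , drop = FALSE])
}

#' Normalize a raw-Cq cohort table into a marker panel table
#'
#' Applies [normalize_mirna()] to the 13 target miRNAs, [normalize_hmga2()]
#' to HMGA2/PGK1 and [mtdna_ratio()] to the mtDNA/nDNA pair, keeping all
#' identifier, histotype, RNA-concentration and mutation columns.
#'
#' @param raw data frame in raw-Cq layout (columns `cq_<marker>`; see
#'   [generate_cohort()] with `emit_raw_cq = TRUE`).
#' @return marker panel data frame (columns `level_<mirna>`, `level_hmga2`,
#'   `mtdna_ratio`). Missing Cq values propagate to missing levels.
#' @export
normalize_cohort <- function(raw) {
  needed <- c(paste0("cq_", c(target_mirnas(), reference_mirnas())),
              "cq_hmga2", "cq_pgk1", "cq_mtdna", "cq_ndna")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("raw table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c("sample_id", "patient_id", "histotype", "bethesda",
                      "rna_ng_ul", mutation_columns()), names(raw))
  out <- raw[, keep, drop = FALSE]
  for (m in target_mirnas()) {
    out[[paste0("level_", m)]] <- normalize_mirna(
      raw[[paste0("cq_", m)]], raw$cq_mir197, raw$cq_mir23a, raw$cq_mir29b)
  }
  out$level_hmga2 <- normalize_hmga2(raw$cq_hmga2, raw$cq_pgk1)
  out$mtdna_ratio <- mtdna_ratio(raw$cq_mtdna, raw$cq_ndna)
  out
}
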