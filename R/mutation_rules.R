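# Somatic mutation / translocation logic: the RAS-based benign-vs-malignant
# discrimination of follicular neoplasms, and the tumor-type specificity
# audit (BRAF V600E and RET-PTC1 belong to papillary carcinomas,
# PAX8-PPARgamma to follicular carcinomas, drivers are mutually exclusive).

#' RAS-based discrimination of follicular neoplasms
#'
#' Categorizes follicular neoplasms (histotype FTC = malignant, FTA = benign)
#' as test-positive when any RAS codon-61 mutation is present, and tabulates
#' the result against histology. Missing RAS flags count as negative: a
#' positive call drives a "malignant" conclusion, so unmeasured samples are
#' treated conservatively.
#'
#' @param fn_panels marker panel rows, all labelled `FTC` or `FTA`.
#' @return 2x2 `confusion_table` (truth rows `malignant`/`benign`, predicted
#'   columns in the same order) where truth `malignant` = FTC and prediction
#'   `malignant` = RAS-positive.
#' @export
ras_fn_confusion <- function(fn_panels) {
  bad <- !fn_panels$histotype %in% c("FTC", "FTA")
  if (any(bad)) {
    stop("ras_fn_confusion expects only FTC/FTA samples; offending sample(s): ",
         paste(utils::head(fn_panels$sample_id[bad], 5), collapse = ", "))
  }
  truth <- ifelse(fn_panels$histotype == "FTC", "malignant", "benign")
  pred <- ifelse(ras_any(fn_panels) == 1, "malignant", "benign")
  confusion_table(truth, pred, classes = c("malignant", "benign"))
}

#' Mutation-by-histotype specificity report
#'
#' Cross-tabulates each mutation flag against histotype and lists rule
#' violations rather than silently dropping them: BRAF V600E or RET-PTC1
#' outside the papillary family, PAX8-PPARgamma outside FTC, and co-occurring
#' driver events within one sample. Missing flags are counted separately.
#'
#' @param panels marker panel data frame with `histotype` and mutation flags.
#' @return list with `counts` (mutation x histotype matrix of positives),
#'   `missing` (same shape, count of missing flags) and `violations` (data
#'   frame `sample_id`/`rule`).
#' @export
mutation_specificity_report <- function(panels) {
  if (!"histotype" %in% names(panels)) stop("panels lack a 'histotype' column")
  hts <- unique(panels$histotype)
  muts <- mutation_columns()
  counts <- matrix(0L, nrow = length(muts), ncol = length(hts),
                   dimnames = list(muts, hts))
  missing <- counts
  for (m in muts) {
    flag <- panels[[m]]
    for (h in hts) {
      in_h <- panels$histotype == h
      counts[m, h] <- sum(flag[in_h] == 1, na.rm = TRUE)
      missing[m, h] <- sum(is.na(flag[in_h]))
    }
  }
  viol <- list()
  braf_bad <- panels$mut_braf_v600e %in% 1 & !panels$histotype %in% .PTC_FAMILY
  ret_bad <- panels$fus_ret_ptc1 %in% 1 & !panels$histotype %in% .PTC_FAMILY
  pax_bad <- panels$fus_pax8_pparg %in% 1 & panels$histotype != "FTC"
  drivers <- panels[, muts, drop = FALSE]
  drivers[is.na(drivers)] <- 0L
  co_occ <- rowSums(drivers) > 1
  add_viol <- function(mask, rule) {
    if (any(mask)) data.frame(sample_id = panels$sample_id[mask], rule = rule,
                              stringsAsFactors = FALSE)
  }
  viol <- rbind(add_viol(braf_bad, "BRAF_outside_PTC_family"),
                add_viol(ret_bad, "RET_PTC1_outside_PTC_family"),
                add_viol(pax_bad, "PAX8_PPARG_outside_FTC"),
                add_viol(co_occ, "co_occurring_drivers"))
  if (is.null(viol)) {
    viol <- data.frame(sample_id = character(), rule = character(),
                       stringsAsFactors = FALSE)
  }
  list(counts = counts, missing = missing, violations = viol)
}
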