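# Molecular regrouping of follicular-pattern tumors.
#
# FVPTC samples are split by miR-146b into a PTC-like and a
# follicular-neoplasm-like subtype; follicular neoplasms (FTA, FTC and the
# FN-like FVPTCs) are split by HMGA2 / miR-221 / miR-375 into neoplasms with
# (FNMM) and without (FNNMM) markers of malignancy. The resulting molecular
# classes are Benign (goiter + FNNMM), PTC, MTC, HCC and FNMM; Benign maps to
# the binary label "benign", everything else to "malignant".

#' Marker cutoffs for the molecular regrouping
#'
#' "Elevated" expression is defined by cutoffs on log2 scale; a level equal to
#' its cutoff counts as elevated (matching the `>=`-goes-malignant convention
#' of the fixed trees). The defaults reuse the fixed-tree thresholds, the only
#' quantitative cutoffs available for these markers: miR-146b 0.1721 (linear),
#' HMGA2 0.0918 (linear), miR-221 0.0105 (linear), miR-375 -12.1213 (log2).
#'
#' @param mir146b_over,hmga2_over,mir221_over,mir375_over log2-scale cutoffs.
#' @return named list of class `reclass_thresholds`.
#' @export
reclass_thresholds <- function(mir146b_over = log2(0.1721),
                               hmga2_over = log2(0.0918),
                               mir221_over = log2(0.0105),
                               mir375_over = -12.1213) {
  th <- list(mir146b_over = mir146b_over, hmga2_over = hmga2_over,
             mir221_over = mir221_over, mir375_over = mir375_over)
  if (!all(vapply(th, is.finite, logical(1)))) stop("cutoffs must be finite")
  structure(th, class = "reclass_thresholds")
}

#' Split FVPTC samples into PTC-like and FN-like subtypes
#'
#' @param panels marker panel rows with histotype `FVPTC`.
#' @param th [reclass_thresholds()].
#' @return character vector, `"PTC_like"` where the miR-146b level is at or
#'   above the cutoff, else `"FN_like"`; `NA` (reported via warning) where
#'   miR-146b is missing.
#' @export
split_fvptc <- function(panels, th = reclass_thresholds()) {
  if (any(panels$histotype != "FVPTC")) {
    stop("split_fvptc expects FVPTC samples only")
  }
  lv <- panels$level_mir146b
  out <- ifelse(lv >= th$mir146b_over, "PTC_like", "FN_like")
  if (anyNA(lv)) {
    warning(sum(is.na(lv)), " FVPTC sample(s) unclassifiable: missing miR-146b")
  }
  out
}

#' Split follicular neoplasms by markers of malignancy
#'
#' A follicular neoplasm is `FNMM` ("with markers of malignancy") when HMGA2,
#' miR-221 or miR-375 is at or above its cutoff, and `FNNMM` (expression
#' profile typical of goiter) when all three are below.
#'
#' @param panels marker panel rows (FTA, FTC, or FN-like FVPTC).
#' @param th [reclass_thresholds()].
#' @return character vector `"FNMM"`/`"FNNMM"`; `NA` with a warning where any
#'   of the three trigger markers is missing.
#' @export
split_fn <- function(panels, th = reclass_thresholds()) {
  hm <- panels$level_hmga2
  m221 <- panels$level_mir221
  m375 <- panels$level_mir375
  elevated <- hm >= th$hmga2_over | m221 >= th$mir221_over |
    m375 >= th$mir375_over
  # OR with NA: a TRUE from any present marker decides FNMM even if another
  # marker is missing; all-below requires all three present
  out <- ifelse(elevated, "FNMM", "FNNMM")
  if (anyNA(out)) {
    warning(sum(is.na(out)), " sample(s) unclassifiable: missing trigger marker")
  }
  out
}

#' Assign molecular classes to a cohort
#'
#' Goiter maps to Benign; classic PTC, MTC and HCC keep their labels; FTA and
#' FTC go through [split_fn()] (FNNMM maps to Benign); FVPTC goes through
#' [split_fvptc()], its PTC-like part to PTC and its FN-like part through
#' [split_fn()].
#'
#' @param panels marker panel data frame with `histotype` labels.
#' @param th [reclass_thresholds()].
#' @return data.frame with `sample_id`, `histotype`, `molecular_class`
#'   (`Benign`, `PTC`, `MTC`, `HCC`, `FNMM`) and `binary_label`
#'   (`benign`/`malignant`).
#' @export
molecular_grouping <- function(panels, th = reclass_thresholds()) {
  known <- histotypes()
  bad <- !panels$histotype %in% known
  if (any(bad)) {
    stop("unknown histotype for sample(s): ",
         paste(utils::head(panels$sample_id[bad], 5), collapse = ", "))
  }
  class <- rep(NA_character_, nrow(panels))
  h <- panels$histotype
  class[h == "goiter"] <- "Benign"
  class[h %in% c("PTC", "MTC", "HCC")] <- h[h %in% c("PTC", "MTC", "HCC")]

  is_fvptc <- h == "FVPTC"
  fn_like <- rep(FALSE, nrow(panels))
  if (any(is_fvptc)) {
    sub <- split_fvptc(panels[is_fvptc, , drop = FALSE], th)
    class[is_fvptc][sub == "PTC_like"] <- "PTC"
    fn_like[is_fvptc] <- sub == "FN_like"
  }
  is_fn <- h %in% c("FTA", "FTC") | fn_like
  if (any(is_fn)) {
    sub <- split_fn(panels[is_fn, , drop = FALSE], th)
    class[is_fn] <- ifelse(sub == "FNMM", "FNMM", "Benign")
  }
  data.frame(sample_id = panels$sample_id,
             histotype = h,
             molecular_class = class,
             binary_label = ifelse(class == "Benign", "benign", "malignant"),
             stringsAsFactors = FALSE)
}

#' Per-class composition report
#'
#' Counts the histotype composition of each molecular class and reports
#' whole-number percentages (rounded half away from zero). Empty classes are
#' omitted.
#'
#' @param grouping data frame as returned by [molecular_grouping()] (or any
#'   frame with `molecular_class` and `histotype` columns).
#' @return data.frame with `molecular_class`, `histotype`, `n`, `class_total`,
#'   `percent`.
#' @export
composition_report <- function(grouping) {
  tab <- table(grouping$molecular_class, grouping$histotype)
  rows <- list()
  for (cls in rownames(tab)) {
    total <- sum(tab[cls, ])
    if (total == 0) next
    present <- colnames(tab)[tab[cls, ] > 0]
    rows[[cls]] <- data.frame(
      molecular_class = cls,
      histotype = present,
      n = as.integer(tab[cls, present]),
      class_total = as.integer(total),
      percent = round_half_away(100 * as.integer(tab[cls, present]) / total),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
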