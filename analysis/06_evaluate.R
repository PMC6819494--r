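#!/usr/bin/env Rscript
# Step 6: diagnostic accuracy, cross-validation and discordance.
#
# Cross-validates the C4.5 classifier on the binary molecular labels
# (5-fold, stratified), reports per-class sensitivity/PPV under training and
# cross-validation, computes stand-alone marker AUCs against histology,
# compares HMGA2 between histotypes with the Mann-Whitney U test, and
# summarizes histology-vs-molecular discordance.

suppressPackageStartupMessages(library(thyroclass))

seed <- 20160106L
panels <- read_marker_table("results/cohort_analyzed.tsv")
grouping <- read_marker_table("results/molecular_classes.tsv")

cv <- kfold_cv(panel_feature_matrix(panels), grouping$binary_label,
               k = 5, seed = seed)
metrics <- merge(cv$train_metrics, cv$cv_metrics, by = "class",
                 suffixes = c("_train", "_cv"))
write_marker_table(metrics, "results/classifier_metrics.tsv")
message(sprintf("total error %.2f%%, cross-validation total error %.2f%%",
                100 * cv$total_error, 100 * cv$cv_total_error))

histology_malignant <- panels$histotype %in% c("FTC", "HCC", "PTC", "FVPTC",
                                               "MTC")
aucs <- do.call(rbind, lapply(c("hmga2", "mir146b", "mir221", "mir375"),
  function(m) {
    scores <- panel_feature_matrix(panels, m)[[1]]
    a <- roc_auc(scores, histology_malignant, positive = TRUE)
    data.frame(marker = marker_display_name(m), auc = a$auc, se = a$se)
  }))
write_marker_table(aucs, "results/marker_auc.tsv")
print(aucs)

groups <- c("goiter", "FTA", "FTC", "PTC")
pw <- list()
for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
  a <- panels$level_hmga2[panels$histotype == groups[i]]
  b <- panels$level_hmga2[panels$histotype == groups[j]]
  mw <- mann_whitney(a, b)
  pw[[length(pw) + 1]] <- data.frame(group_a = groups[i], group_b = groups[j],
                                     U = mw$U, p = mw$p)
}
write_marker_table(do.call(rbind, pw), "results/hmga2_pairwise_tests.tsv")

disc <- discordance_report(grouping$binary_label,
                           ifelse(histology_malignant, "malignant", "benign"))
message(sprintf(
  "discordance: %d of %d (%.2f%%), %d false positive (%.2f%%), %d false negative (%.2f%%)",
  disc$n_discordant, disc$n, disc$pct_discordant,
  disc$n_false_pos, disc$pct_false_pos, disc$n_false_neg, disc$pct_false_neg))
jsonlite::write_json(disc, "results/discordance.json", auto_unbox = TRUE,
                     digits = NA)
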