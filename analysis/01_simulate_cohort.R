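#!/usr/bin/env Rscript
# Step 1: draw the synthetic FNA cohort.
#
# Generates the pre-exclusion series (501 specimens: 107 goiter, 103 FTA,
# 44 FTC, 25 HCC, 121 PTC, 80 FVPTC, 19 MTC, 2 anaplastic) in both raw-Cq
# and normalized-panel form and writes them under results/. Five
# follicular-pattern samples carry an injected discordant BRAF V600E call
# (two goiter, two FTA, one FTC), emulating mis-reported papillary
# carcinomas.

suppressPackageStartupMessages(library(thyroclass))

seed <- 20160101L
dir.create("results", showWarnings = FALSE)

raw <- generate_cohort(full_cohort_config(seed = seed, emit_raw_cq = TRUE))
panel <- generate_cohort(full_cohort_config(seed = seed))

write_marker_table(raw, "results/cohort_raw_cq.tsv")
write_marker_table(panel, "results/cohort_panels.tsv")

message("cohort: ", nrow(panel), " samples")
print(table(panel$histotype))
message("BRAF+ outside the papillary family: ",
        sum(panel$mut_braf_v600e == 1 &
              !panel$histotype %in% c("PTC", "FVPTC")))
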