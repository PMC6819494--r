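#!/usr/bin/env Rscript
# Step 2: delta-Cq normalization and sample-level exclusions.
#
# Reads the raw-Cq table written by step 1, normalizes the 13 target miRNAs
# against the geometric mean of the three reference miRNAs (arithmetic mean
# on the Cq scale), HMGA2 against PGK1 and the mtDNA/nDNA pair into a copy
# ratio; then applies the exclusion rules: RNA below 5 ng/ul, anaplastic
# carcinoma, and BRAF V600E calls in non-papillary histotypes. With the
# default generator settings the accounting is 501 - 2 - 5 = 494.

suppressPackageStartupMessages(library(thyroclass))

raw <- read_marker_table("results/cohort_raw_cq.tsv")

qc <- qc_low_rna(raw)
message("low-RNA exclusions: ", nrow(qc$excluded))

panels <- normalize_cohort(qc$retained)
ana <- panels$histotype == "anaplastic"
message("anaplastic exclusions: ", sum(ana))
panels <- panels[!ana, ]

braf <- braf_discordance_filter(panels)
message("BRAF-discordant exclusions: ", nrow(braf$excluded),
        " (", paste(braf$excluded$histotype, collapse = ", "), ")")

analyzed <- braf$retained
message("samples reaching analysis: ", nrow(analyzed))
write_marker_table(analyzed, "results/cohort_analyzed.tsv")
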