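#!/usr/bin/env Rscript
# Step 4: molecular regrouping of follicular-pattern tumors.
#
# FVPTCs are split by miR-146b into PTC-like and FN-like subtypes;
# follicular neoplasms (FTA, FTC, FN-like FVPTC) are split by
# HMGA2/miR-221/miR-375 into FNMM (markers of malignancy present) and FNNMM.
# The cohort is then redistributed into Benign (goiter + FNNMM), PTC, MTC,
# HCC and FNMM, and the class compositions are tabulated with whole-number
# percentages.

suppressPackageStartupMessages(library(thyroclass))

panels <- read_marker_table("results/cohort_analyzed.tsv")

fvptc <- panels[panels$histotype == "FVPTC", ]
sub <- split_fvptc(fvptc)
message("FVPTC split: ", sum(sub == "PTC_like"), " PTC-like (",
        round_half_away(100 * mean(sub == "PTC_like")), "%), ",
        sum(sub == "FN_like"), " FN-like")

grouping <- molecular_grouping(panels)
write_marker_table(grouping, "results/molecular_classes.tsv")
print(table(grouping$molecular_class))

comp <- composition_report(grouping)
write_marker_table(comp, "results/class_composition.tsv")
fnmm <- comp[comp$molecular_class == "FNMM", ]
message("FNMM composition: ",
        paste(sprintf("%s %d (%d%%)", fnmm$histotype, fnmm$n, fnmm$percent),
              collapse = ", "))
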