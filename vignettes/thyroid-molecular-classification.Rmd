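---
title: "Molecular classification of thyroid FNA samples: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular classification of thyroid FNA samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroclass)
```

## The problem

Fine-needle aspiration (FNA) cytology is the standard preoperative test for
thyroid nodules, but follicular-pattern lesions (Bethesda category IV) often
cannot be called benign or malignant from morphology alone. This package
implements a classification workflow that supplements cytology with a small
real-time-PCR marker panel measured on the same smear:

* 13 target miRNAs, normalized by the $2^{-\Delta Cq}$ method against the
  geometric mean of three reference miRNAs (miR-197-3p, miR-23a-3p,
  miR-29b-3p);
* *HMGA2* mRNA, normalized against *PGK1*;
* the mitochondrial-to-nuclear DNA copy ratio (mtDNA/nDNA), a marker of
  Hürthle (oncocytic) cells;
* seven binary somatic-event flags: *BRAF* V600E, *HRAS* Q61R, *NRAS*
  Q61K/Q61R/Q61L, *RET-PTC1* and *PAX8-PPARγ*.

Because Cq is a base-2 logarithmic quantity, all expression levels are kept
on log2 scale internally: for a target with reference assays $r_1, r_2,
r_3$,

$$\log_2 \text{level} = \tfrac{1}{3}(Cq_{r_1}+Cq_{r_2}+Cq_{r_3}) - Cq_{\text{target}},$$

which is identical to normalizing the linear amount against the geometric
mean of the three reference amounts. The linear level is `2^level` and the
mtDNA/nDNA ratio is stored linear (it is conventionally reported that way).

## Sample-level exclusions

Two QC rules precede classification:

* `qc_low_rna()` drops samples whose total-RNA concentration is *strictly*
  below 5 ng/µl; a sample at exactly 5 ng/µl is retained (the rule is
  worded "below").
* `braf_discordance_filter()` drops samples carrying *BRAF* V600E whose
  pathology report says goiter, FTA, FTC or HCC. V600E is specific to
  papillary carcinoma, so such a combination indicates a probable reporting
  error rather than a benign BRAF-mutant lesion.

Anaplastic carcinomas are excluded before classification because two
specimens cannot support a class of their own. With the shipped
pre-exclusion cohort configuration (`full_cohort_config()`) the accounting
is 501 − 2 anaplastic − 5 BRAF-discordant = 494 analyzed samples. The
full-cohort generator draws all RNA concentrations at or above the QC
cutoff so that this accounting is driven by the two structural rules alone;
the low-RNA filter is exercised on separately configured cohorts
(`lowrna_frac > 0`).

## The molecular regrouping

Histological classes are heterogeneous in marker space, so the workflow
regroups follicular-pattern tumors on molecular grounds
(`molecular_grouping()`):

1. FVPTC samples with miR-146b at or above its cutoff are PTC-like and join
   the PTC class; the rest are treated as follicular neoplasms (FNs).
2. FNs (FTA, FTC, FN-like FVPTC) with *HMGA2*, miR-221 **or** miR-375 at or
   above its cutoff become **FNMM** ("follicular neoplasm with markers of
   malignancy"); FNs with all three unremarkable become **FNNMM** and join
   the benign class.

The final classes are Benign (goiter + FNNMM), PTC, MTC, HCC and FNMM;
everything except Benign maps to the binary label *malignant*.

The texts describing this regrouping never state numeric cutoffs for
"elevated" expression. The package defaults (`reclass_thresholds()`) reuse
the fixed-tree thresholds — the only quantitative cutoffs available for
exactly these markers — and every cutoff is overridable. The boundary
convention is `>=` ("at the cutoff counts as elevated"), matching the fixed
trees, where a value equal to a threshold follows the `>=` branch.

## The fixed decision trees

Two trees are shipped verbatim (`malignancy_tree()`, `typing_tree()`):

```{r}
malignancy_tree()
typing_tree()
```

Each node carries an explicit `scale` tag. The miR-375 threshold of the
malignancy tree (−12.1213) cannot be a linear $2^{-\Delta Cq}$ value, so
that node operates on log2 scale; every other printed threshold (0.0918,
0.0105, 1.5362, 5.2514, 0.1721, 5716.3013) is linear. Making the scale part
of the node data rather than of the code keeps this interpretation
auditable and serializable (`write_tree_json()`).

The typing-tree FNMM leaf stores the published purity 0.960 verbatim; a
reconstructed integer count (73/76) would render as 96.1%, so the printed
value takes precedence for rendering fidelity. All other leaves are
consistent with integer counts.

## The C4.5-style trainer

`c45_train()` re-induces trees from labelled marker tables: at each node,
for every feature, candidate thresholds are the midpoints between
consecutive distinct sorted values; the split maximizing the **gain ratio**
(information gain divided by split information) among positive-gain
candidates wins, with ties broken towards the smaller threshold and, across
features, towards the first feature in column order. Growth stops at node
purity, below `2 * min_leaf` instances, at `max_depth`, or when no
positive-gain split exists.

Settings of the original induction software are not recorded, so the
defaults are the classical ones: `min_leaf = 5`, `pruning_cf = 0.25`,
unlimited depth. Post-pruning is pessimistic: the error of a would-be leaf
and of a subtree are both estimated by an upper confidence bound on the
binomial error rate, here the Clopper–Pearson upper limit
`qbeta(1 - cf, E + 1, N - E)`; the subtree is replaced when the leaf bound
does not exceed the subtree's. Instances missing the split attribute are
dropped from the subtree during training; at prediction time the
`missing_policy` chooses between reporting the sample as unclassifiable
(`"exclude"`, default) and following the branch with larger training
support (`"majority_branch"`).

Training operates on the log2 feature matrix (`panel_feature_matrix()`;
the mtDNA ratio is log2-transformed). Trees are invariant to monotone
transforms of their inputs, so this choice only affects the printed
thresholds, which then live on the same scale as the stored levels.

## Evaluation machinery

* `confusion_metrics()` reports sensitivity, specificity, PPV, NPV and
  total error; a ratio with a zero denominator is `NA` (undefined), never
  0.
* `kfold_cv()` implements the "five partitions" validation as stratified
  5-fold cross-validation at the *sample* level (the tree method does not
  require independence of samples from the same patient; a patient-level
  grouping can be obtained by passing patient-aggregated tables).
* `roc_auc()` uses the rank identity $AUC = U/(n_1 n_0)$ with midranks for
  ties; the standard error is Hanley–McNeil, the standard choice for
  "AUC ± SE" reporting when no formula is named.
* `mann_whitney()` is exact (full enumeration) for $n_1+n_2 \le 12$ without
  ties and otherwise uses the normal approximation with tie and continuity
  corrections. No multiplicity correction is applied to pairwise marker
  comparisons, since none is stated for the published tables.
* Printed percentages are reproduced with round-half-away-from-zero
  (`round_half_away()`) at the printed precision.

## The synthetic cohort generator

No per-sample clinical data are publicly deposited, so
`generate_cohort()` provides the cohort every downstream stage runs on.
What it emulates:

* the published group sizes (105/101/43/25/121/80/19 samples; the
  pre-exclusion variant adds 2 goiter, 2 FTA, 1 FTC and two anaplastic
  specimens and flags five BRAF-discordant samples);
* log2-normal marker levels per histotype (i.e. lognormal linear levels),
  an assumption of convenience — the sources report only medians and
  quartiles in figures, not distribution families;
* group separations consistent with the fixed-tree thresholds: benign
  group means sit several SDs below the malignancy cutoffs, PTC clears the
  HMGA2 and miR-146b cutoffs, MTC the miR-375 cutoff, HCC the miR-221 and
  mtDNA cutoffs, and FTC straddles the cutoffs so that roughly 70% of FTCs
  carry at least one marker of malignancy;
* the FVPTC dichotomy as an explicit two-component mixture
  (`fvptc_ptc_like_frac = 0.54`), with *BRAF* V600E restricted to the
  PTC-like component;
* mutation frequencies in the published range (RAS: FVPTC 48%, FTC 40%,
  MTC 21%, HCC 16%), with driver mutual exclusivity enforced by a fixed
  priority (BRAF > RET-PTC1 > RAS > PAX8-PPARγ) and histotype specificity
  validated at profile construction;
* non-detects: raw Cq values outside (0, 45) are missing.

The default location/spread constants are package constants chosen once to
realize these separations; they are synthetic, not estimates of the
clinical data. What the generator deliberately does **not** emulate:
intra-patient correlation (samples are dealt round-robin to patients),
inter-laboratory batch effects, Bethesda category assignment, the published
single NRAS/RET-PTC1 double-positive case, and heavy-tailed outliers. Tests
passing on this cohort therefore demonstrate the correctness and internal
consistency of the pipeline, not its clinical accuracy; quantities that
depend on the real data's noise structure (e.g. cross-validated error
rates) are checked as properties (cross-validated error exceeding training
error; threshold recovery) rather than as numeric reproductions.

Determinism: a configuration (including its seed) fully determines the
cohort, and the reference assays are drawn in both emission modes so that
the same seed yields the same underlying levels whether raw Cq values or
normalized panels are emitted. With Cq noise disabled, generating raw Cq
and re-normalizing reproduces the generation-time levels to floating
precision.

## Problem sizes used by the tests and the acceptance script

The threshold-recovery experiment trains on the default cohort scaled
proportionally so the smallest histotype reaches 500 samples (13,338 in
total) and evaluates agreement with the fixed malignancy tree on an
independently drawn default cohort (494 samples); these sizes give stable
estimates while a full run of the suite stays fast. Oracle comparisons for
`best_split()` and `roc_auc()` use 1000 random instances each of up to 25
points, the size range where exhaustive enumeration is itself instant. The
cross-validation optimism property is checked over 50 seeded replicates of
the default cohort.

## Known limitations

* The regrouping cutoffs are a design decision (reused tree thresholds),
  not an independently validated operating point.
* The exact-p branch of `mann_whitney()` enumerates only up to 12
  observations; beyond that the normal approximation is used even where an
  exact test would be feasible.
* Pessimistic pruning uses the Clopper–Pearson upper limit, which is close
  to but not bit-identical with the heuristic bound of classical C4.5
  implementations.
* The synthetic cohort is cleaner than clinical data; stand-alone marker
  AUCs computed on it run higher than published ones, and nothing in the
  package should be read as a clinical performance claim.
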