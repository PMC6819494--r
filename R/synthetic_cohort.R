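# Seeded synthetic FNA cohort generator.
#
# Marker levels are drawn normally on log2 scale (i.e. lognormal linear
# levels), per histotype, with default location/spread constants chosen so
# that each printed tree threshold separates the relevant groups; mutation
# flags are Bernoulli draws with driver mutual exclusivity enforced by a
# fixed priority order. Nothing here is estimated from clinical data: the
# profiles are synthetic package constants.

#' Per-histotype generative profile
#'
#' @param histotype one of [histotypes()] or `"anaplastic"`.
#' @param n_samples number of FNA samples to draw for the group.
#' @param n_patients number of distinct patients the samples are spread over
#'   (round-robin); `n_samples >= n_patients >= 1`.
#' @param marker_log2_mean named numeric, log2 mean relative level per marker
#'   (keys from [panel_markers()]; `mtdna` is the log2 of the copy ratio).
#' @param marker_log2_sd named numeric, log2-scale SD per marker (all `>= 0`).
#' @param mutation_freq named numeric, per-mutation Bernoulli probability;
#'   names from `"braf_v600e"`, `"hras_q61r"`, `"nras_q61k"`, `"nras_q61r"`,
#'   `"nras_q61l"`, `"ret_ptc1"`, `"pax8_pparg"`. BRAF V600E and RET-PTC1 are
#'   only permitted in papillary-family profiles, PAX8-PPARgamma only in FTC.
#' @param fvptc_ptc_like_frac FVPTC only: probability that a sample belongs to
#'   the PTC-like (miR-146b-high) subtype rather than the follicular-like one.
#' @param marker_log2_mean_ptc_like FVPTC only: log2 means for the PTC-like
#'   component (defaults to `marker_log2_mean` entries where not given).
#' @return object of class `group_profile`.
#' @export
group_profile <- function(histotype, n_samples, n_patients,
                          marker_log2_mean, marker_log2_sd,
                          mutation_freq = numeric(),
                          fvptc_ptc_like_frac = NA_real_,
                          marker_log2_mean_ptc_like = NULL) {
  if (!histotype %in% c(histotypes(), "anaplastic")) {
    stop("unknown histotype: ", histotype)
  }
  if (n_samples < n_patients || n_patients < 1) {
    stop("need n_samples >= n_patients >= 1")
  }
  bad <- setdiff(names(marker_log2_mean), panel_markers())
  if (length(bad) > 0) stop("unknown marker(s) in profile: ",
                            paste(bad, collapse = ", "))
  missing_m <- setdiff(panel_markers(), names(marker_log2_mean))
  if (length(missing_m) > 0) stop("profile lacks marker mean(s): ",
                                  paste(missing_m, collapse = ", "))
  if (!all(names(marker_log2_sd) %in% panel_markers()) ||
      !all(panel_markers() %in% names(marker_log2_sd))) {
    stop("marker_log2_sd must cover exactly the panel markers")
  }
  if (any(marker_log2_sd < 0)) stop("negative marker SD in profile")
  known_mut <- c("braf_v600e", "hras_q61r", "nras_q61k", "nras_q61r",
                 "nras_q61l", "ret_ptc1", "pax8_pparg")
  bad <- setdiff(names(mutation_freq), known_mut)
  if (length(bad) > 0) stop("unknown mutation(s): ", paste(bad, collapse = ", "))
  freq <- stats::setNames(numeric(length(known_mut)), known_mut)
  freq[names(mutation_freq)] <- mutation_freq
  if (any(freq < 0 | freq > 1)) stop("mutation frequencies must lie in [0, 1]")
  if (freq["braf_v600e"] > 0 && !histotype %in% .PTC_FAMILY) {
    stop("BRAF V600E is only permitted in papillary-family profiles")
  }
  if (freq["ret_ptc1"] > 0 && !histotype %in% .PTC_FAMILY) {
    stop("RET-PTC1 is only permitted in papillary-family profiles")
  }
  if (freq["pax8_pparg"] > 0 && histotype != "FTC") {
    stop("PAX8-PPARgamma is only permitted in the FTC profile")
  }
  if (histotype == "FVPTC") {
    if (is.na(fvptc_ptc_like_frac)) fvptc_ptc_like_frac <- 0.54
    if (fvptc_ptc_like_frac < 0 || fvptc_ptc_like_frac > 1) {
      stop("fvptc_ptc_like_frac must lie in [0, 1]")
    }
    alt <- marker_log2_mean
    if (!is.null(marker_log2_mean_ptc_like)) {
      bad <- setdiff(names(marker_log2_mean_ptc_like), panel_markers())
      if (length(bad) > 0) stop("unknown marker(s) in PTC-like means: ",
                                paste(bad, collapse = ", "))
      alt[names(marker_log2_mean_ptc_like)] <- marker_log2_mean_ptc_like
    }
    marker_log2_mean_ptc_like <- alt
  } else {
    fvptc_ptc_like_frac <- NA_real_
    marker_log2_mean_ptc_like <- NULL
  }
  structure(list(histotype = histotype,
                 n_samples = as.integer(n_samples),
                 n_patients = as.integer(n_patients),
                 marker_log2_mean = marker_log2_mean[panel_markers()],
                 marker_log2_sd = marker_log2_sd[panel_markers()],
                 mutation_freq = freq,
                 fvptc_ptc_like_frac = fvptc_ptc_like_frac,
                 marker_log2_mean_ptc_like = marker_log2_mean_ptc_like),
            class = "group_profile")
}

# default log2 means per histotype. Rows: markers, columns: groups. The
# printed tree thresholds (log2): hmga2 -3.4454, mir375 -12.1213 / +2.3928,
# mir221 -6.5735, mir146b +0.6193 / -2.5388, mtdna +12.4809. Group means are
# placed so benign groups sit several SDs below the malignancy cutoffs and
# each carcinoma group clears the cutoff(s) its biology implies.
.default_mean_table <- function() {
  groups <- c("goiter", "FTA", "FTC", "HCC", "PTC", "FVPTC", "FVPTC_ptc_like",
              "MTC", "anaplastic")
  m <- matrix(NA_real_, nrow = length(panel_markers()), ncol = length(groups),
              dimnames = list(panel_markers(), groups))
  #              goiter  FTA    FTC    HCC    PTC   FVPTC  FVPTCp  MTC   ana
  m["hmga2", ]   <- c(-8.0, -7.5, -4.0, -7.0, -0.5, -2.5, -0.5, -7.0, -1.0)
  m["mir375", ]  <- c(-16.0, -15.5, -13.0, -13.0, -13.0, -12.5, -13.0, 5.0, -14.0)
  m["mir221", ]  <- c(-8.8, -9.0, -7.0, -4.5, -5.5, -6.0, -5.5, -5.0, -6.0)
  m["mir146b", ] <- c(-3.0, -2.8, -4.5, -5.0, 2.5, -5.0, 2.5, -5.0, -2.0)
  m["mtdna", ]   <- c(8.0, 8.0, 8.0, 14.0, 8.0, 8.0, 8.0, 8.0, 8.0)
  m["mir144", ]  <- c(-6.0, -6.0, -6.0, -6.0, -6.0, -6.0, -6.0, -6.0, -6.0)
  m["mir145", ]  <- c(-4.0, -4.0, -3.0, -4.0, -4.0, -3.5, -4.0, -4.0, -4.0)
  m["mir155", ]  <- c(-5.0, -5.0, -4.0, -5.0, -4.5, -4.5, -4.5, -7.0, -5.0)
  m["mir183", ]  <- c(-5.0, -5.0, -5.0, -5.0, -4.0, -5.0, -4.0, -5.0, -5.0)
  m["mir199b", ] <- c(-4.0, -4.0, -3.0, -4.0, -4.0, -3.5, -4.0, -4.0, -4.0)
  m["mir223", ]  <- c(-4.0, -4.0, -4.0, -4.0, -3.0, -4.0, -3.0, -4.0, -4.0)
  m["mir31", ]   <- c(-6.0, -6.0, -5.0, -6.0, -3.0, -5.0, -3.0, -8.0, -6.0)
  m["mir451a", ] <- c(-3.0, -3.0, -3.0, -3.0, -3.0, -3.0, -3.0, -3.0, -3.0)
  m["mir551b", ] <- c(-7.0, -7.0, -7.0, -7.0, -4.0, -7.0, -4.0, -9.0, -7.0)
  m["mir7", ]    <- c(-5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0, -5.0)
  m
}

.default_sd <- function(group) {
  sd <- stats::setNames(rep(1.5, length(panel_markers())), panel_markers())
  sd["mir146b"] <- 1.2
  if (group == "HCC") sd["mtdna"] <- 1.2
  sd
}

.default_mutation_freq <- function(group) {
  switch(group,
    goiter = numeric(),
    FTA = c(hras_q61r = 0.01, nras_q61r = 0.01),
    FTC = c(hras_q61r = 0.10, nras_q61k = 0.10, nras_q61r = 0.15,
            nras_q61l = 0.05, pax8_pparg = 0.10),
    HCC = c(hras_q61r = 0.08, nras_q61r = 0.08),
    PTC = c(braf_v600e = 0.45, ret_ptc1 = 0.08, nras_q61r = 0.05),
    FVPTC = c(braf_v600e = 0.30, hras_q61r = 0.12, nras_q61k = 0.12,
              nras_q61r = 0.18, nras_q61l = 0.06),
    MTC = c(hras_q61r = 0.11, nras_q61r = 0.10),
    anaplastic = numeric(),
    numeric())
}

#' Default per-histotype profiles
#'
#' Group sizes follow the analyzed clinical series: goiter 105 (50 patients),
#' FTA 101 (48), FTC 43 (28), HCC 25 (11), PTC 121 (56), FVPTC 80 (32), MTC
#' 19 (12) - 494 samples from 232 patients. With `full = TRUE` the
#' pre-exclusion series is produced instead (goiter 107, FTA 103, FTC 44 plus
#' two anaplastic samples, 501 in total), for exercising the exclusion
#' bookkeeping.
#'
#' @param full logical; return the pre-exclusion cohort composition.
#' @return list of [group_profile()] objects.
#' @export
default_group_profiles <- function(full = FALSE) {
  sizes <- list(
    goiter = c(105, 50), FTA = c(101, 48), FTC = c(43, 28), HCC = c(25, 11),
    PTC = c(121, 56), FVPTC = c(80, 32), MTC = c(19, 12))
  if (full) {
    sizes$goiter <- c(107, 50); sizes$FTA <- c(103, 48); sizes$FTC <- c(44, 28)
    sizes$anaplastic <- c(2, 2)
  }
  means <- .default_mean_table()
  lapply(names(sizes), function(g) {
    group_profile(
      histotype = g,
      n_samples = sizes[[g]][1], n_patients = sizes[[g]][2],
      marker_log2_mean = means[, g],
      marker_log2_sd = .default_sd(g),
      mutation_freq = .default_mutation_freq(g),
      fvptc_ptc_like_frac = if (g == "FVPTC") 0.54 else NA_real_,
      marker_log2_mean_ptc_like = if (g == "FVPTC") means[, "FVPTC_ptc_like"])
  })
}

#' Cohort generation configuration
#'
#' @param profiles list of [group_profile()] objects.
#' @param seed integer RNG seed; identical configs (including seed) produce
#'   identical cohorts.
#' @param emit_raw_cq logical; emit raw Cq columns (`cq_<marker>`) instead of
#'   normalized levels.
#' @param reference_cq_mean,reference_cq_sd per-sample reference-assay Cq
#'   distribution (used in raw mode; also for PGK1 and nDNA assays).
#' @param cq_noise_sd additional per-well Cq noise in raw mode (0 keeps the
#'   raw/normalized round trip exact).
#' @param rna_conc_range total-RNA concentration range in ng/ul; draws are
#'   uniform on `[max(range[1], qc), range[2]]` except low-RNA samples.
#' @param lowrna_frac probability that a sample's RNA concentration falls
#'   below the 5 ng/ul QC cutoff.
#' @param braf_discordant named integer vector (e.g. `c(goiter = 2)`): number
#'   of samples per non-papillary histotype whose BRAF flag is set after
#'   generation, emulating mis-reported papillary carcinomas.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(profiles = default_group_profiles(),
                          seed = 1L,
                          emit_raw_cq = FALSE,
                          reference_cq_mean = 26,
                          reference_cq_sd = 1,
                          cq_noise_sd = 0,
                          rna_conc_range = c(1.2, 92.6),
                          lowrna_frac = 0,
                          braf_discordant = integer()) {
  if (!all(vapply(profiles, inherits, logical(1), "group_profile"))) {
    stop("profiles must be group_profile objects")
  }
  if (reference_cq_mean <= 0 || reference_cq_mean >= 45) {
    stop("reference_cq_mean must lie in (0, 45)")
  }
  if (any(rna_conc_range < 0) || any(rna_conc_range > 200) ||
      rna_conc_range[1] > rna_conc_range[2]) {
    stop("rna_conc_range must be an increasing interval within [0, 200]")
  }
  if (lowrna_frac < 0 || lowrna_frac > 1) stop("lowrna_frac must lie in [0, 1]")
  if (length(braf_discordant) > 0) {
    bad <- setdiff(names(braf_discordant), .BRAF_DISCORDANT_SET)
    if (length(bad) > 0) {
      stop("braf_discordant only applies to ",
           paste(.BRAF_DISCORDANT_SET, collapse = "/"), "; got: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(profiles = profiles, seed = as.integer(seed),
                 emit_raw_cq = emit_raw_cq,
                 reference_cq_mean = reference_cq_mean,
                 reference_cq_sd = reference_cq_sd,
                 cq_noise_sd = cq_noise_sd,
                 rna_conc_range = rna_conc_range,
                 lowrna_frac = lowrna_frac,
                 braf_discordant = braf_discordant),
            class = "cohort_config")
}

#' Pre-exclusion cohort configuration
#'
#' Convenience config reproducing the exclusion bookkeeping of the clinical
#' series: 501 specimens (including two anaplastic carcinomas) of which five
#' follicular-pattern samples carry a discordant BRAF V600E call (two goiter,
#' two FTA, one FTC), so that 501 - 2 - 5 = 494 reach classification. RNA
#' concentrations are drawn at or above the QC cutoff so the accounting is
#' driven by the two exclusion rules alone.
#'
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [cohort_config()].
#' @return `cohort_config` object.
#' @export
full_cohort_config <- function(seed = 1L, ...) {
  cohort_config(profiles = default_group_profiles(full = TRUE), seed = seed,
                braf_discordant = c(goiter = 2L, FTA = 2L, FTC = 1L), ...)
}

#' Convert a log2 level back into a raw target Cq
#'
#' Inverse of the `2^-dCq` normalization, used to produce raw-Cq fixtures:
#' a target with log2 relative level `x` against a reference Cq `r` has
#' `Cq = r - x`. Round-tripping through [normalize_mirna()] recovers the
#' level exactly.
#'
#' @param level_log2 log2 relative level.
#' @param reference_cq reference Cq (must lie in `(0, 45)`).
#' @return Target Cq; values outside the instrument range `(0, 45)` are
#'   flagged as non-detects and returned as `NA`.
#' @export
levels_to_cq <- function(level_log2, reference_cq) {
  if (any(reference_cq <= 0 | reference_cq >= 45)) {
    stop("reference_cq must lie in (0, 45)")
  }
  cq <- reference_cq - level_log2
  cq[cq <= 0 | cq >= 45] <- NA_real_
  cq
}

# draw mutation flags for one group, enforcing driver exclusivity by the fixed
# priority BRAF > RET-PTC1 > HRAS Q61R > NRAS Q61K > NRAS Q61R > NRAS Q61L >
# PAX8-PPARg (when several drivers are drawn, the first is kept)
.draw_mutations <- function(n, freq, ptc_like = NULL) {
  order_keys <- c("braf_v600e", "ret_ptc1", "hras_q61r", "nras_q61k",
                  "nras_q61r", "nras_q61l", "pax8_pparg")
  m <- vapply(order_keys, function(k) stats::rbinom(n, 1L, freq[[k]]),
              integer(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, order_keys))
  if (!is.null(ptc_like)) {
    # BRAF only arises in the PTC-like FVPTC component
    m[, "braf_v600e"] <- m[, "braf_v600e"] * as.integer(ptc_like)
  }
  taken <- rep(FALSE, n)
  for (k in order_keys) {
    m[, k] <- ifelse(taken, 0L, m[, k])
    taken <- taken | m[, k] == 1L
  }
  colnames(m) <- c("mut_braf_v600e", "fus_ret_ptc1", "mut_hras_q61r",
                   "mut_nras_q61k", "mut_nras_q61r", "mut_nras_q61l",
                   "fus_pax8_pparg")
  m[, mutation_columns(), drop = FALSE]
}

.bethesda_of <- function(histotype) {
  switch(histotype,
         goiter = "II",
         FTA = , FTC = , HCC = "IV",
         "VI")
}

#' Generate a synthetic FNA cohort
#'
#' Draws one row per sample: identifiers, histotype, Bethesda category, RNA
#' concentration, marker levels (normalized panel columns, or raw Cq columns
#' with `emit_raw_cq = TRUE`) and 0/1 mutation flags. Deterministic under a
#' fixed config.
#'
#' @param config a [cohort_config()].
#' @return data.frame, one row per sample. Panel mode: `level_<mirna>` and
#'   `level_hmga2` (log2 relative levels) plus linear `mtdna_ratio`. Raw mode:
#'   `cq_<mirna>` for the 13 targets and 3 references, `cq_hmga2`, `cq_pgk1`,
#'   `cq_mtdna`, `cq_ndna`; Cq values outside `(0, 45)` are non-detects
#'   (`NA`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  with_local_seed(config$seed, {
    parts <- lapply(config$profiles, function(p) .generate_group(p, config))
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    df <- .inject_braf_discordant(df, config$braf_discordant)
    df
  })
}

.generate_group <- function(profile, config) {
  n <- profile$n_samples
  h <- profile$histotype
  markers <- panel_markers()
  ptc_like <- NULL
  means <- matrix(rep(profile$marker_log2_mean, each = n), nrow = n,
                  dimnames = list(NULL, markers))
  if (h == "FVPTC") {
    ptc_like <- stats::rbinom(n, 1L, profile$fvptc_ptc_like_frac) == 1L
    means[ptc_like, ] <- matrix(rep(profile$marker_log2_mean_ptc_like[markers],
                                    each = sum(ptc_like)), nrow = sum(ptc_like))
  }
  levels <- means + vapply(markers, function(m) {
    stats::rnorm(n, 0, profile$marker_log2_sd[[m]])
  }, numeric(n))
  levels <- matrix(levels, nrow = n, dimnames = list(NULL, markers))

  low <- stats::runif(n) < config$lowrna_frac
  lo <- max(config$rna_conc_range[1], 0)
  hi <- config$rna_conc_range[2]
  rna <- stats::runif(n, max(lo, 5), hi)
  rna[low] <- stats::runif(sum(low), min(lo, 4.99), 4.99)

  mut <- .draw_mutations(n, as.list(profile$mutation_freq), ptc_like)

  # reference assays are drawn in both modes so that the RNG stream (and
  # hence the drawn marker levels) is identical whether or not raw Cq values
  # are emitted
  refs <- vapply(reference_mirnas(), function(m) {
    stats::rnorm(n, config$reference_cq_mean, config$reference_cq_sd)
  }, numeric(n))
  refs <- matrix(refs, nrow = n, dimnames = list(NULL, reference_mirnas()))
  cq_pgk1 <- stats::rnorm(n, 22, config$reference_cq_sd)
  cq_ndna <- stats::rnorm(n, 28, config$reference_cq_sd)

  df <- data.frame(
    sample_id = sprintf("%s_s%03d", h, seq_len(n)),
    patient_id = sprintf("%s_p%03d", h, ((seq_len(n) - 1L) %% profile$n_patients) + 1L),
    histotype = h,
    bethesda = .bethesda_of(h),
    rna_ng_ul = round(rna, 1),
    stringsAsFactors = FALSE)

  if (config$emit_raw_cq) {
    ref_mean <- rowMeans(refs)
    noise <- function() if (config$cq_noise_sd > 0)
      stats::rnorm(n, 0, config$cq_noise_sd) else 0
    for (m in reference_mirnas()) df[[paste0("cq_", m)]] <- refs[, m]
    for (m in target_mirnas()) {
      cq <- ref_mean - levels[, m] + noise()
      cq[cq <= 0 | cq >= 45] <- NA_real_
      df[[paste0("cq_", m)]] <- cq
    }
    df$cq_pgk1 <- cq_pgk1
    df$cq_hmga2 <- cq_pgk1 - levels[, "hmga2"] + noise()
    df$cq_ndna <- cq_ndna
    df$cq_mtdna <- cq_ndna - levels[, "mtdna"] + noise()
    for (col in c("cq_hmga2", "cq_mtdna")) {
      df[[col]][df[[col]] <= 0 | df[[col]] >= 45] <- NA_real_
    }
  } else {
    for (m in c(target_mirnas(), "hmga2")) {
      df[[paste0("level_", m)]] <- levels[, m]
    }
    df$mtdna_ratio <- 2^levels[, "mtdna"]
  }
  cbind(df, as.data.frame(mut))
}

# flip the BRAF flag on the first k mutation-free samples of the named
# histotypes (emulates pathology-report errors on papillary carcinomas)
.inject_braf_discordant <- function(df, counts) {
  for (h in names(counts)) {
    k <- counts[[h]]
    if (k == 0) next
    candidates <- which(df$histotype == h &
                          rowSums(df[, mutation_columns(), drop = FALSE]) == 0)
    if (length(candidates) < k) {
      stop("not enough mutation-free ", h, " samples for BRAF injection")
    }
    df$mut_braf_v600e[candidates[seq_len(k)]] <- 1L
  }
  df
}
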