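# Synthetic cohort generator: determinism, composition, distributional
# checks, raw-Cq round trip and mutation bookkeeping.

test_that("generation is deterministic and reproduces the cohort sizes", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
  expect_equal(nrow(a), 494)
  expect_equal(as.integer(table(a$histotype)[c("goiter", "FTA", "FTC", "HCC",
                                               "PTC", "FVPTC", "MTC")]),
               c(105, 101, 43, 25, 121, 80, 19))
  expect_equal(length(unique(a$sample_id)), nrow(a))
  full <- generate_cohort(full_cohort_config(seed = 42))
  expect_equal(nrow(full), 501)
  expect_equal(sum(full$histotype == "anaplastic"), 2)
  # the injected discordant BRAF calls sit in goiter/FTA/FTC
  disc <- full$mut_braf_v600e == 1 & !full$histotype %in% c("PTC", "FVPTC")
  expect_equal(as.integer(table(full$histotype[disc])[c("FTA", "FTC", "goiter")]),
               c(2, 1, 2))
})

test_that("different seeds give different cohorts", {
  a <- generate_cohort(cohort_config(seed = 1))
  b <- generate_cohort(cohort_config(seed = 2))
  expect_false(identical(a$level_hmga2, b$level_hmga2))
})

test_that("zero marker variance collapses a group to a single marker vector", {
  profs <- default_group_profiles()[1]
  profs[[1]]$marker_log2_sd[] <- 0
  coh <- generate_cohort(cohort_config(profiles = profs, seed = 3))
  lv <- coh[, grep("^level_", names(coh))]
  expect_true(all(vapply(lv, function(x) length(unique(x)) == 1, logical(1))))
})

test_that("mutation draws match their Bernoulli frequency", {
  # isolated RAS draw (no competing drivers) at the FVPTC rate
  means <- thyroclass:::.default_mean_table()[, "FVPTC"]
  prof <- group_profile("FVPTC", 10000, 100, means,
                        thyroclass:::.default_sd("FVPTC"),
                        mutation_freq = c(nras_q61r = 0.48))
  coh <- generate_cohort(cohort_config(profiles = list(prof), seed = 9))
  frac <- mean(ras_any(coh))
  se <- sqrt(0.48 * 0.52 / 10000)
  expect_lt(abs(frac - 0.48), 3 * se)
})

test_that("driver events are mutually exclusive and histotype-specific", {
  coh <- generate_cohort(cohort_config(seed = 21))
  drivers <- coh[, mutation_columns()]
  expect_true(all(rowSums(drivers) <= 1))
  expect_true(all(coh$histotype[coh$mut_braf_v600e == 1] %in% c("PTC", "FVPTC")))
  expect_true(all(coh$histotype[coh$fus_ret_ptc1 == 1] %in% c("PTC", "FVPTC")))
  expect_true(all(coh$histotype[coh$fus_pax8_pparg == 1] == "FTC"))
  expect_true(all(drivers[coh$histotype == "goiter", ] == 0))
})

test_that("profile validation rejects bad configurations", {
  means <- thyroclass:::.default_mean_table()[, "goiter"]
  sds <- thyroclass:::.default_sd("goiter")
  expect_error(group_profile("goiter", 10, 5, c(means, bogus = 1),
                             c(sds, bogus = 1)), "unknown marker")
  bad_sd <- sds; bad_sd["hmga2"] <- -1
  expect_error(group_profile("goiter", 10, 5, means, bad_sd), "negative")
  expect_error(group_profile("goiter", 10, 5, means, sds,
                             mutation_freq = c(braf_v600e = 0.1)),
               "papillary")
  expect_error(group_profile("goiter", 4, 5, means, sds), "n_samples")
})

test_that("levels_to_cq inverts normalization and flags non-detects", {
  expect_equal(levels_to_cq(0, 26), 26)
  expect_equal(levels_to_cq(-12.1213, 26), 38.1213)
  expect_equal(levels_to_cq(5.2514, 26), 20.7486)
  expect_true(is.na(levels_to_cq(-20, 26)))        # Cq 46 > 45: non-detect
  expect_error(levels_to_cq(0, 45), "reference_cq")
  lv <- c(-12.1213, 0, 5.2514, -3.4454)
  cq <- levels_to_cq(lv, 26)
  expect_equal(normalize_mirna(cq, 26, 26, 26), lv, tolerance = 1e-12)
})

test_that("raw-Cq emission round-trips through normalization exactly", {
  cfg_panel <- cohort_config(seed = 77)
  cfg_raw <- cohort_config(seed = 77, emit_raw_cq = TRUE, cq_noise_sd = 0)
  panels <- generate_cohort(cfg_panel)
  raw <- generate_cohort(cfg_raw)
  norm <- normalize_cohort(raw)
  for (m in c(paste0("level_", target_mirnas()), "level_hmga2")) {
    expect_lt(max(abs(norm[[m]] - panels[[m]]), na.rm = TRUE), 1e-9)
  }
  expect_lt(max(abs(log2(norm$mtdna_ratio) - log2(panels$mtdna_ratio)),
                na.rm = TRUE), 1e-9)
})

test_that("low-RNA fraction is honoured", {
  coh <- generate_cohort(cohort_config(seed = 5, lowrna_frac = 0.5))
  frac <- mean(coh$rna_ng_ul < 5)
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
  coh0 <- generate_cohort(cohort_config(seed = 5, lowrna_frac = 0))
  expect_true(all(coh0$rna_ng_ul >= 5))
})

test_that("default profiles separate benign from malignant under the fixed tree", {
  coh <- generate_cohort(cohort_config(profiles = scaled_profiles(500),
                                       seed = 101))
  pred <- apply_malignancy_tree(coh)$class
  benign_side <- mean(pred[coh$histotype %in% c("goiter", "FTA")] == "Benign")
  malignant_side <- mean(pred[coh$histotype %in% c("PTC", "MTC", "HCC")] ==
                           "Malignant")
  expect_gte(benign_side, 0.90)
  expect_gte(malignant_side, 0.90)
})
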