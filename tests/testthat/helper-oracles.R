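# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's own entropy/rank code paths.

# exhaustive gain-ratio maximization over every midpoint threshold
brute_best_split <- function(values, labels, min_leaf = 1) {
  ok <- !is.na(values)
  values <- values[ok]; labels <- labels[ok]
  ent <- function(l) {
    p <- table(l) / length(l)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  v <- sort(unique(values))
  if (length(v) < 2) return(NULL)
  n <- length(values)
  best <- NULL
  for (i in seq_len(length(v) - 1)) {
    th <- (v[i] + v[i + 1]) / 2
    left <- values < th
    nl <- sum(left); nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    gain <- ent(labels) - nl / n * ent(labels[left]) - nr / n * ent(labels[!left])
    if (gain <= 1e-12) next
    si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
    ratio <- gain / si
    if (is.null(best) || ratio > best$gain_ratio) {
      best <- list(threshold = th, gain_ratio = ratio, gain = gain)
    }
  }
  best
}

# AUC as the proportion of concordant positive/negative pairs (+ half ties)
brute_auc <- function(scores, labels, positive = TRUE) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# one-row marker panel with tree-relevant markers settable on their natural
# scales (linear for HMGA2/miR-221/miR-146b/mtDNA, log2 for miR-375)
panel_row <- function(hmga2_lin = 0.001, mir375_log2 = -16, mir221_lin = 0.001,
                      mir146b_lin = 0.1, mtdna_lin = 100,
                      histotype = "goiter", sample_id = "s1") {
  df <- data.frame(sample_id = sample_id, patient_id = "p1",
                   histotype = histotype, stringsAsFactors = FALSE)
  for (m in thyroclass::target_mirnas()) df[[paste0("level_", m)]] <- -5
  df$level_hmga2 <- log2(hmga2_lin)
  df$level_mir375 <- mir375_log2
  df$level_mir221 <- log2(mir221_lin)
  df$level_mir146b <- log2(mir146b_lin)
  df$mtdna_ratio <- mtdna_lin
  for (m in thyroclass::mutation_columns()) df[[m]] <- 0L
  df
}

# default profiles rescaled so every group has at least n_min samples,
# keeping the cohort's relative composition
scaled_profiles <- function(n_min = 500) {
  profs <- default_group_profiles()
  k <- ceiling(n_min / min(vapply(profs, `[[`, integer(1), "n_samples")))
  lapply(profs, function(p) {
    p$n_samples <- as.integer(p$n_samples * k)
    p
  })
}
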