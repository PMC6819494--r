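# End-to-end orchestration and tabular IO. All tables are UTF-8 TSV with a
# header row; missing values are empty fields.

.ID_COLUMNS <- c("sample_id", "patient_id", "histotype", "bethesda")

#' Read and write marker tables
#'
#' Marker tables are TSV files with one header row and one row per sample:
#' identifier columns (`sample_id`, `patient_id`, `histotype`, `bethesda`),
#' `rna_ng_ul`, either raw Cq columns (`cq_<marker>`) or normalized level
#' columns (`level_<marker>`, `mtdna_ratio`), and integer 0/1 mutation flags.
#' Missing values are written as empty fields; reading a non-numeric token in
#' a numeric column is an error naming the line.
#'
#' @param path TSV file path.
#' @return `read_marker_table()`: data.frame; `write_marker_table()`: `path`,
#'   invisibly.
#' @export
read_marker_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           check.names = FALSE, na.strings = NULL)
  mandatory <- c("sample_id", "histotype")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("marker table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  numeric_cols <- names(raw)[startsWith(names(raw), "cq_") |
                               startsWith(names(raw), "level_") |
                               names(raw) %in% c("mtdna_ratio", "rna_ng_ul",
                                                 mutation_columns())]
  for (col in numeric_cols) {
    txt <- raw[[col]]
    txt[txt == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad) > 0) {
      stop("malformed value '", txt[bad[1]], "' in column '", col,
           "' at line ", bad[1] + 1L, " of ", path)
    }
    raw[[col]] <- val
  }
  for (col in intersect(mutation_columns(), names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  raw
}

#' @rdname read_marker_table
#' @param table data.frame to write.
#' @export
write_marker_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input path to a marker table TSV, a data.frame, or a
#'   [cohort_config()] (the cohort is then generated in-memory).
#' @param outdir output directory for the report bundle.
#' @param thresholds [reclass_thresholds()].
#' @param c45 [c45_params()].
#' @param cv_k number of cross-validation folds.
#' @param seed integer seed (cross-validation; and cohort generation when
#'   `input` is a `cohort_config`, overriding its own seed).
#' @param rna_threshold low-RNA exclusion cutoff, ng/ul.
#' @param ... unknown arguments are rejected.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, outdir = NULL,
                            thresholds = reclass_thresholds(),
                            c45 = c45_params(), cv_k = 5, seed = 1L,
                            rna_threshold = 5, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  structure(list(input = input, outdir = outdir, thresholds = thresholds,
                 c45 = c45, cv_k = cv_k, seed = as.integer(seed),
                 rna_threshold = rna_threshold),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Normalizes (when given raw Cq data), applies the sample-level exclusions
#' (low RNA, anaplastic carcinoma, BRAF-discordant follicular-pattern
#' samples), assigns molecular classes, applies both fixed trees, trains and
#' cross-validates a C4.5 tree on the binary molecular labels, and summarizes
#' histology-vs-molecular discordance. When `config$outdir` is set, the
#' report bundle is written there as TSV/text/JSON artifacts; all outputs are
#' reproducible under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `panels` (analyzed samples), `exclusions`, `grouping`,
#'   `fixed_predictions`, `trained_tree`, `cv` ([kfold_cv()] result on the
#'   binary labels), `binary_metrics`, `typing_metrics`, `discordance`, and
#'   `n_analyzed`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config")
  }
  input <- config$input
  if (inherits(input, "cohort_config")) {
    input$seed <- config$seed
    input <- generate_cohort(input)
  } else if (is.character(input)) {
    input <- read_marker_table(input)
  }
  raw_mode <- any(startsWith(names(input), "cq_"))
  exclusions <- list()
  note_excluded <- function(df, stage, reason) {
    if (nrow(df) == 0) return(NULL)
    data.frame(sample_id = df$sample_id, stage = stage, reason = reason,
               stringsAsFactors = FALSE)
  }

  qc <- qc_low_rna(input, config$rna_threshold)
  exclusions$low_rna <- note_excluded(qc$excluded, "qc_low_rna",
                                      sprintf("total RNA below %g ng/ul",
                                              config$rna_threshold))
  work <- qc$retained

  panels <- if (raw_mode) normalize_cohort(work) else work

  ana <- panels$histotype == "anaplastic"
  exclusions$anaplastic <- note_excluded(panels[ana, , drop = FALSE],
                                         "cohort_filter",
                                         "anaplastic carcinoma (insufficient group size)")
  panels <- panels[!ana, , drop = FALSE]

  braf <- braf_discordance_filter(panels)
  exclusions$braf <- note_excluded(braf$excluded, "braf_discordance",
                                   "BRAF V600E in non-papillary histotype")
  panels <- braf$retained

  exclusions <- do.call(rbind, exclusions)
  if (is.null(exclusions)) {
    exclusions <- data.frame(sample_id = character(), stage = character(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  rownames(exclusions) <- NULL

  grouping <- molecular_grouping(panels, config$thresholds)

  mal_pred <- apply_malignancy_tree(panels)
  typ_pred <- apply_typing_tree(panels)
  fixed_predictions <- data.frame(
    sample_id = panels$sample_id,
    malignancy_call = mal_pred$class,
    malignancy_trace = mal_pred$trace,
    typing_call = ifelse(mal_pred$class == "Malignant", typ_pred$class,
                         NA_character_),
    typing_trace = ifelse(mal_pred$class == "Malignant", typ_pred$trace, ""),
    stringsAsFactors = FALSE)

  # samples whose molecular label cannot be assigned (missing trigger marker,
  # e.g. a non-detect Cq) are excluded from classifier training/CV
  labelled <- !is.na(grouping$binary_label)
  features <- panel_feature_matrix(panels[labelled, , drop = FALSE])
  cv <- kfold_cv(features, grouping$binary_label[labelled], config$c45,
                 k = config$cv_k, seed = config$seed)

  typing_cm <- confusion_table(
    grouping$molecular_class[grouping$binary_label == "malignant"],
    fixed_predictions$typing_call[grouping$binary_label == "malignant"])

  histology_binary <- ifelse(panels$histotype %in% .MALIGNANT_HISTOTYPES,
                             "malignant", "benign")
  discordance <- discordance_report(grouping$binary_label[labelled],
                                    histology_binary[labelled])

  result <- list(panels = panels, exclusions = exclusions,
                 grouping = grouping, fixed_predictions = fixed_predictions,
                 trained_tree = cv$tree, cv = cv,
                 binary_metrics = list(train = cv$train_metrics,
                                       cv = cv$cv_metrics,
                                       total_error = cv$total_error,
                                       cv_total_error = cv$cv_total_error),
                 typing_metrics = per_class_metrics(typing_cm),
                 discordance = discordance,
                 n_analyzed = nrow(panels))
  if (!is.null(config$outdir)) {
    .write_report_bundle(result, config$outdir)
  }
  result
}

.write_report_bundle <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outdir, name)
  write_marker_table(result$panels, out("normalized_panels.tsv"))
  write_marker_table(result$exclusions, out("exclusions.tsv"))
  write_marker_table(result$grouping, out("molecular_classes.tsv"))
  write_marker_table(result$fixed_predictions, out("fixed_tree_predictions.tsv"))
  writeLines(render_tree(result$trained_tree), out("trained_tree.txt"))
  bm <- merge(result$binary_metrics$train, result$binary_metrics$cv,
              by = "class", suffixes = c("_train", "_cv"))
  write_marker_table(bm, out("metrics_binary.tsv"))
  write_marker_table(result$typing_metrics, out("metrics_typing.tsv"))
  jsonlite::write_json(
    c(result$discordance,
      list(total_error = result$binary_metrics$total_error,
           cv_total_error = result$binary_metrics$cv_total_error,
           n_analyzed = result$n_analyzed)),
    out("discordance_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the [pipeline_config()] arguments; `thresholds` and `c45` may
#' be given as nested maps. Unknown keys are rejected.
#'
#' @param path YAML or JSON file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$thresholds)) {
    cfg$thresholds <- do.call(reclass_thresholds, cfg$thresholds)
  }
  if (!is.null(cfg$c45)) cfg$c45 <- do.call(c45_params, cfg$c45)
  do.call(pipeline_config, cfg)
}
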