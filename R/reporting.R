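#' Subtype count summary in the reporting-table shape
#'
#' Counts and percentages per label: EO and LO columns for GH, SPE and PE, a
#' single column for chronic hypertension and normotensive, and a Total row.
#' Percentages are computed with [format_percentage()] against the total and
#' therefore recompute exactly from the label file.
#'
#' @param labels Data frame with a `label` column (from [classify_cohort()]).
#' @return Data frame: `group`, `timing`, `n`, `pct`.
#' @export
summarize_labels <- function(labels) {
  n <- nrow(labels)
  cnt <- function(l) sum(labels$label == l)
  rows <- rbind(
    data.frame(group = "GH", timing = c("EO", "LO"),
               n = c(cnt("GH_EO"), cnt("GH_LO"))),
    data.frame(group = "SPE", timing = c("EO", "LO"),
               n = c(cnt("SPE_EO"), cnt("SPE_LO"))),
    data.frame(group = "PE", timing = c("EO", "LO"),
               n = c(cnt("PE_EO"), cnt("PE_LO"))),
    data.frame(group = "CH", timing = "", n = cnt("CH")),
    data.frame(group = "Normotensive", timing = "", n = cnt("NT")),
    data.frame(group = "Total", timing = "", n = n))
  rows$pct <- if (n > 0) format_percentage(rows$n, n) else NA_real_
  rows
}

hash_config <- function(x) {
  # order-stable digest of a config list; good enough for a run manifest
  s <- paste(deparse(x[order(names(unlist(x)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_manifest <- function(out_dir, cfg, counts) {
  manifest <- list(package = "hdpheno",
                   version = as.character(utils::packageVersion("hdpheno")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = cfg, config_hash = hash_config(cfg), counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the phenotyping pipeline end to end
#'
#' Reads the four cohort CSVs, applies the inclusion filter, mines notes,
#' classifies with the selected algorithm(s), and writes per-subject label
#' CSVs, an evidence JSON, the count summary, a discordance table when both
#' algorithms run, and a machine-readable run manifest.
#'
#' @param cohort_dir Directory with `subjects.csv`, `visits.csv`,
#'   `delivery.csv`, `notes.csv`.
#' @param out_dir Output directory (created).
#' @param algorithm `1`, `2` or `"both"`.
#' @param thresholds An [hdp_thresholds()].
#' @param dictionary An [flag_dictionary()].
#' @param lfd_table Percentile reference for algorithm 2.
#' @param withdrawn_ids Subjects who withdrew from the study.
#' @param schema A [cohort_schema()].
#' @return Invisibly, a list with the label data frames, the exclusion log
#'   and the summaries.
#' @export
run_phenotype <- function(cohort_dir, out_dir, algorithm = "both",
                          thresholds = hdp_thresholds(),
                          dictionary = flag_dictionary(),
                          lfd_table = read_lfd_table(),
                          withdrawn_ids = character(0),
                          schema = cohort_schema()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundles <- read_cohort(cohort_dir, schema)
  filt <- apply_inclusion_filters(bundles, withdrawn_ids)
  if (!length(filt$included))
    warning("no subjects remain after the inclusion filter", call. = FALSE)
  included <- mine_cohort(filt$included, dictionary)
  algos <- if (identical(algorithm, "both")) c(1, 2) else as.integer(algorithm)

  results <- list()
  for (a in algos) {
    res <- classify_cohort(included, thresholds, algorithm = a,
                           lfd_table = lfd_table)
    utils::write.csv(res, file.path(out_dir, sprintf("labels_algorithm%d.csv", a)),
                     row.names = FALSE)
    utils::write.csv(summarize_labels(res),
                     file.path(out_dir, sprintf("summary_algorithm%d.csv", a)),
                     row.names = FALSE)
    results[[paste0("algorithm", a)]] <- res
  }
  utils::write.csv(filt$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  evidence <- lapply(results, function(r) {
    stats::setNames(as.list(r$evidence), r$subject_id)
  })
  jsonlite::write_json(evidence, file.path(out_dir, "evidence.json"),
                       auto_unbox = TRUE)
  if (length(algos) == 2) {
    comp <- compare_algorithms(results$algorithm1, results$algorithm2)
    utils::write.csv(comp$discordant, file.path(out_dir, "discordant.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(comp$table),
                     file.path(out_dir, "crosstab.csv"), row.names = FALSE)
    results$comparison <- comp
  }
  write_manifest(out_dir,
                 list(cohort_dir = cohort_dir, algorithm = algorithm,
                      thresholds = unclass(thresholds),
                      n_withdrawn_ids = length(withdrawn_ids)),
                 list(ingested = length(bundles),
                      included = length(filt$included),
                      excluded = length(bundles) - length(filt$included)))
  message(sprintf("ingested %d, included %d, excluded %d subjects",
                  length(bundles), length(filt$included),
                  length(bundles) - length(filt$included)))
  invisible(c(results, list(exclusions = filt$exclusions)))
}

#' Validate predicted labels against a diagnosis file
#'
#' @param pred_path CSV with `subject_id`, `label`.
#' @param truth_path CSV with `subject_id`, `label` (reference-standard
#'   diagnoses, e.g. from chart review).
#' @param out_dir Output directory for the metric table and discordance
#'   ledger.
#' @return Invisibly, the [evaluate_all()] result.
#' @export
run_validate <- function(pred_path, truth_path, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pred <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
  truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  ev <- evaluate_all(pred, truth)
  disp <- ev$metrics
  for (m in c("ppv", "npv", "accuracy", "sensitivity", "specificity"))
    disp[[m]] <- round_metric(disp[[m]])
  utils::write.csv(disp, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(ev$discordant, file.path(out_dir, "discordant.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(pred = pred_path, truth = truth_path),
                 list(n = nrow(pred), discordant = nrow(ev$discordant)))
  invisible(ev)
}

#' Simulate a cohort and write it to disk
#'
#' @param config An [sim_config()].
#' @param out_dir Output directory for the four cohort CSVs plus `truth.csv`.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  write_simulated_cohort(sim, out_dir)
  write_manifest(out_dir, unclass(config),
                 list(n_subjects = config$n_subjects))
  invisible(sim)
}
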