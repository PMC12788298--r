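# File outputs for a completed experiment: metric tables, statistical
# tests, ROC points (CSV), and a run summary with red-flag tallies (JSON).

#' Write the standard report files for an experiment
#'
#' Emits `predictions.csv`, `metrics_pooled.csv`, `metrics_per_task.csv`,
#' `tests.csv` (paired Wilcoxon vs. the baseline with Holm adjustment,
#' when more than one method is present), `roc_pooled.csv`, and
#' `summary.json` (episode/method counts, undefined per-task AUC cells,
#' and red-flag tallies) into `out_dir`.
#'
#' @param results Output of [run_experiment()].
#' @param out_dir Output directory (created if needed).
#' @param baseline Baseline method for the statistical tests.
#' @param holm_family Passed to [compare_methods()].
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, baseline = "audio_only",
                         holm_family = "all") {
  stop_if(!requireNamespace("jsonlite", quietly = TRUE),
          "write_report needs the jsonlite package")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  preds <- results$predictions
  paths <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    paths <<- c(paths, path)
  }

  emit(preds, "predictions.csv")
  emit(pooled_metrics(preds), "metrics_pooled.csv")
  pt <- per_task_metrics(preds)
  emit(pt$table, "metrics_per_task.csv")
  if (length(unique(preds$method)) > 1 && baseline %in% preds$method) {
    emit(compare_methods(preds, baseline = baseline,
                         holm_family = holm_family), "tests.csv")
  }
  emit(export_roc(preds), "roc_pooled.csv")

  flags <- results$calibration$red_flags
  flags <- unlist(strsplit(flags[flags != ""], ";"))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    n_predictions = nrow(preds),
    methods = sort(unique(preds$method)),
    n_undefined_per_task_auc_cells = pt$n_undefined_auc_cells,
    red_flag_tally = as.list(table(flags)),
    fallback_rate = mean(results$calibration$fallback)
  ), summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, summary_path))
}
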