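# Classification metrics on calibrated probabilities: rank-statistic AUC
# (ties counted one half), threshold-dependent F1 / accuracy / precision /
# recall with PD as the positive class, fold summaries with Student-t
# confidence intervals, and ROC export.

# Mann-Whitney AUC with ties counted 1/2 (equals trapezoidal ROC area).
auc_rank <- function(probs, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(probs, labels, threshold) {
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Binary classification metrics
#'
#' AUC is the rank statistic on the probabilities (ties counted one half);
#' the remaining metrics use `probability >= threshold` with PD (label 1)
#' as the positive class.
#'
#' @param probs Calibrated probabilities.
#' @param labels 0/1 labels (1 = PD).
#' @param threshold Operating threshold.
#' @return Named list: `auc` (NA when a class is absent), `f1`, `accuracy`,
#'   `precision`, `recall`.
#' @export
binary_metrics <- function(probs, labels, threshold = 0.5) {
  stop_if(length(probs) == 0, "empty input")
  stopifnot(length(probs) == length(labels))
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  list(auc = auc_rank(probs, labels),
       f1 = f1_score(probs, labels, threshold),
       accuracy = (tp + tn) / length(labels),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Fold-level summary: mean, SD, and 95% Student-t confidence interval
#'
#' @param values Per-fold metric values (NA cells are dropped).
#' @return List: `mean`, `sd`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_folds <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  stop_if(n < 2, "need at least two fold values")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci_lo = m - half, ci_hi = m + half, n = n)
}

# Per-(method, fold[, task]) metrics from a prediction table.
fold_cell_metrics <- function(records) {
  cells <- split(records, list(records$method, records$fold), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    m <- binary_metrics(cell$probability, cell$label, cell$threshold[1])
    data.frame(method = cell$method[1], fold = cell$fold[1],
               auc = m$auc, f1 = m$f1, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled metric table over outer folds
#'
#' Computes each metric within every (method, fold) cell of a prediction
#' table, then summarizes over folds (mean, SD, 95% CI).
#'
#' @param records Prediction table from [run_experiment()].
#' @return data.frame with one row per method x metric.
#' @export
pooled_metrics <- function(records) {
  cells <- fold_cell_metrics(records)
  out <- list()
  for (method in unique(cells$method)) {
    sub <- cells[cells$method == method, ]
    for (metric in c("auc", "f1", "accuracy", "precision", "recall")) {
      s <- summarize_folds(sub[[metric]])
      out[[length(out) + 1]] <- data.frame(
        method = method, scope = "pooled", metric = metric,
        mean = s$mean, sd = s$sd, ci_lo = s$ci_lo, ci_hi = s$ci_hi,
        n_folds = s$n)
    }
  }
  do.call(rbind, out)
}

#' Per-task metric table over outer folds
#'
#' Metrics are computed within each (method, task, fold) cell and averaged
#' over folds. Cells whose AUC is undefined (single-class test episodes)
#' are recorded as missing and excluded from the fold mean; the number of
#' such cells is returned in `n_undefined_auc_cells`.
#'
#' @param records Prediction table carrying a `task` column.
#' @return List with `table` (method x task x metric rows) and
#'   `n_undefined_auc_cells`.
#' @export
per_task_metrics <- function(records) {
  stop_if(is.null(records$task), "records must carry task ids")
  out <- list()
  n_undef <- 0
  for (task in sort(unique(records$task))) {
    sub <- records[records$task == task, ]
    cells <- fold_cell_metrics(sub)
    n_undef <- n_undef + sum(is.na(cells$auc))
    for (method in unique(cells$method)) {
      mc <- cells[cells$method == method, ]
      for (metric in c("auc", "f1", "accuracy", "precision", "recall")) {
        vals <- mc[[metric]][!is.na(mc[[metric]])]
        out[[length(out) + 1]] <- data.frame(
          method = method, scope = task, metric = metric,
          mean = if (length(vals)) mean(vals) else NA_real_,
          n_folds = length(vals))
      }
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  list(table = tab, n_undefined_auc_cells = n_undef)
}

#' Pooled-across-folds ROC point sets
#'
#' Concatenates fold probabilities per method (and per task when a `task`
#' column is present) and emits the ROC polyline through all unique
#' thresholds.
#'
#' @param records Prediction table.
#' @param by `"method"` for pooled curves or `"method_task"` for per-task
#'   curves.
#' @return data.frame with `method`, `scope`, `fpr`, `tpr`, `threshold`.
#' @export
export_roc <- function(records, by = c("method", "method_task")) {
  by <- match.arg(by)
  roc_points <- function(probs, labels) {
    stop_if(length(unique(labels)) < 2, "ROC needs both classes")
    ths <- c(Inf, sort(unique(probs), decreasing = TRUE))
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    tpr <- vapply(ths, function(t) sum(probs >= t & labels == 1) / n1,
                  numeric(1))
    fpr <- vapply(ths, function(t) sum(probs >= t & labels == 0) / n0,
                  numeric(1))
    data.frame(fpr = fpr, tpr = tpr, threshold = ths)
  }
  groups <- if (by == "method") split(records, records$method)
  else split(records, list(records$method, records$task), drop = TRUE)
  out <- lapply(groups, function(g) {
    pts <- roc_points(g$probability, g$label)
    pts$method <- g$method[1]
    pts$scope <- if (by == "method") "pooled" else g$task[1]
    pts
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("method", "scope", "fpr", "tpr", "threshold")]
}
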