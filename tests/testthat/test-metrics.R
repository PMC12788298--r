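# Metrics: rank AUC against brute force, threshold metrics, fold
# summaries, per-task aggregation, ROC export self-consistency.

test_that("binary metrics match hand-computable cases", {
  m <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$accuracy, 1)

  expect_equal(binary_metrics(rep(0.4, 4), c(1, 0, 1, 0), 0.5)$auc, 0.5)

  # 2 concordant / 2 discordant of 4 pairs
  expect_equal(binary_metrics(c(0.7, 0.4, 0.6, 0.2),
                              c(1, 0, 0, 1), 0.5)$auc, 0.5)
  expect_error(binary_metrics(numeric(0), numeric(0)), "empty")
})

test_that("rank AUC equals brute-force pair counting on random instances", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    probs <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(binary_metrics(probs, labels)$auc,
                 auc_bruteforce(probs, labels))
  }
})

test_that("fold summaries use the Student-t interval", {
  s <- summarize_folds(c(1, 1, 1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_equal(c(s$ci_lo, s$ci_hi), c(1, 1))

  v <- c(0.8, 0.85, 0.9, 0.95, 1.0)
  s2 <- summarize_folds(v)
  expect_equal(s2$mean, 0.9)
  expect_equal(s2$sd, 0.0790569, tolerance = 1e-6)
  half <- qt(0.975, 4) * s2$sd / sqrt(5)
  expect_equal(s2$ci_hi - s2$mean, half)
  expect_equal(half, 0.0982, tolerance = 1e-3)

  s3 <- summarize_folds(v + 0.01)
  expect_equal(s3$mean, s2$mean + 0.01)
  expect_equal(s3$sd, s2$sd)
  expect_equal(s3$ci_lo, s2$ci_lo + 0.01)
  expect_error(summarize_folds(0.5), "at least two")
})

test_that("per-task tables aggregate fold cells and drop undefined AUCs", {
  recs <- expand.grid(fold = 1:5, i = 1:6)
  set.seed(11)
  recs <- data.frame(
    participant = paste0("P", recs$i), task = "T06", session = 1,
    method = "audio_only", fold = recs$fold,
    probability = runif(30), threshold = 0.5,
    label = rep(c(1, 0), 15))
  pt <- per_task_metrics(recs)
  pooled <- pooled_metrics(recs)
  for (metric in c("auc", "f1", "accuracy")) {
    expect_equal(pt$table$mean[pt$table$metric == metric],
                 pooled$mean[pooled$metric == metric])
  }

  # one fold with a single class loses its AUC cell only
  recs2 <- recs
  recs2$label[recs2$fold == 3] <- 0
  pt2 <- per_task_metrics(recs2)
  expect_equal(pt2$n_undefined_auc_cells, 1)
  expect_equal(pt2$table$n_folds[pt2$table$metric == "auc"], 4)
  expect_equal(pt2$table$n_folds[pt2$table$metric == "f1"], 5)
})

test_that("exported ROC is monotone and integrates to the rank AUC", {
  set.seed(12)
  recs <- data.frame(
    participant = paste0("P", 1:40), task = rep(c("T02", "T06"), 20),
    session = 1, method = "gated_early", fold = rep(1:5, 8),
    probability = runif(40), threshold = 0.5, label = rbinom(40, 1, 0.5))
  roc <- export_roc(recs)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(area, binary_metrics(recs$probability, recs$label)$auc,
               tolerance = 1e-9)

  # perfect separation passes through (0, 1)
  recs$probability <- ifelse(recs$label == 1, 0.9, 0.1)
  roc2 <- export_roc(recs)
  expect_true(any(roc2$fpr == 0 & roc2$tpr == 1))

  roc3 <- export_roc(recs, by = "method_task")
  expect_setequal(unique(roc3$scope), c("T02", "T06"))
})

test_that("write_report emits the standard file set", {
  set.seed(13)
  mk <- function(method) data.frame(
    participant = paste0("P", 1:20), task = rep(c("T03", "T06"), 10),
    session = 1, method = method, fold = rep(1:5, 4),
    probability = runif(20), threshold = 0.5, label = rep(c(1, 0), 10))
  results <- list(predictions = rbind(mk("audio_only"), mk("gated_early")),
                  calibration = data.frame(
                    method = "audio_only", fold = 1, rep = 1:3,
                    temperature = 1, threshold = 0.5, n_val = 15,
                    fallback = TRUE,
                    red_flags = c("fallback_small_val", "", "fallback_small_val"),
                    best_epoch = 3))
  dir <- withr::local_tempdir()
  paths <- write_report(results, dir)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("predictions.csv", "metrics_pooled.csv",
                    "metrics_per_task.csv", "tests.csv", "roc_pooled.csv",
                    "summary.json"))
  smry <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(smry$n_predictions, 40)
  expect_equal(smry$red_flag_tally$fallback_small_val, 2)
})
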