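# End-to-end experiment driver: preprocess episodes once, then for every
# variant x outer fold (x task in the task-wise regime) train three inner
# repetitions, calibrate each on its inner validation set, ensemble, and
# predict the held-out fold with test-time augmentation. Subject-wise
# separation of train / validation / test participants is asserted on
# every repetition.

#' Preprocess manifest episodes into model-ready features
#'
#' Loads audio (log-mel sequence) and IMU (normalized 100 Hz six-channel
#' stream) for each manifest record. The IMU stream requires both the
#' accelerometer and the gyroscope file; an episode missing either has
#' `imu = NULL`, and one missing its WAV has `mel = NULL`.
#'
#' @param manifest Manifest data.frame (paths resolved).
#' @return List of per-episode feature objects: `mel`, `imu`, `label`
#'   (1 = PD), `participant`, `task`, `session`, `key`.
#' @export
prepare_features <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    mel <- if (!is.na(rec$wav_path))
      compute_logmel(load_audio(rec$wav_path)) else NULL
    imu <- if (!is.na(rec$acc_path) && !is.na(rec$gyr_path))
      normalize_channels(to_100hz_six_channel(load_imu_table(rec$acc_path),
                                              load_imu_table(rec$gyr_path)))
    else NULL
    list(mel = mel, imu = imu,
         label = as.numeric(rec$group == "PD"),
         participant = rec$participant_id, task = rec$task_id,
         session = rec$session_index,
         key = paste(rec$participant_id, rec$task_id, rec$session_index,
                     sep = "|"))
  })
}

variant_eligible <- function(feats, variant) {
  vapply(feats, function(f) {
    switch(variant,
           audio_only = !is.null(f$mel),
           imu_only = !is.null(f$imu),
           !is.null(f$mel) && !is.null(f$imu))
  }, logical(1))
}

feats_field <- function(feats, field)
  vapply(feats, function(f) as.character(f[[field]]), character(1))

assert_disjoint <- function(train_p, val_p, test_p) {
  stop_if(length(intersect(train_p, val_p)) > 0 ||
            length(intersect(train_p, test_p)) > 0 ||
            length(intersect(val_p, test_p)) > 0,
          "participant leakage across train/validation/test")
}

run_one_cell <- function(feats, variant, fold_idx, test_participants,
                         all_participants, cfg, variant_idx) {
  part <- feats_field(feats, "participant")
  train_pool <- feats[!part %in% test_participants]
  test_feats <- feats[part %in% test_participants]
  if (length(test_feats) == 0 || length(train_pool) == 0) return(NULL)

  tp <- unique(data.frame(
    participant_id = feats_field(train_pool, "participant"),
    group = ifelse(vapply(train_pool, `[[`, numeric(1), "label") == 1,
                   "PD", "HC")))
  if (length(unique(tp$group)) < 2 || any(table(tp$group) < 2)) return(NULL)

  inner <- make_inner_splits(tp, reps = 3,
                             seed = derive_seed(cfg$seed, variant_idx,
                                                fold_idx))
  rep_outputs <- list()
  rep_logits <- list()
  calib_log <- list()
  pool_part <- feats_field(train_pool, "participant")
  for (r in seq_along(inner)) {
    tr_f <- train_pool[pool_part %in% inner[[r]]$train]
    va_f <- train_pool[pool_part %in% inner[[r]]$val]
    assert_disjoint(inner[[r]]$train, inner[[r]]$val, test_participants)
    if (length(unique(vapply(tr_f, `[[`, numeric(1), "label"))) < 2)
      return(NULL)

    rep_seed <- derive_seed(cfg$seed, variant_idx, fold_idx, r)
    cfg_rep <- cfg
    cfg_rep$seed <- rep_seed
    model <- build_model(model_config(variant), seed = rep_seed)
    fit <- train_model(model, tr_f, va_f, cfg_rep)

    val_logits <- tta_predict_many(
      fit$model, va_f, K = cfg$tta_k,
      seeds = vapply(seq_along(va_f), function(j)
        derive_seed(rep_seed, 100, j), integer(1)),
      window_s = cfg$window_s)
    cal <- calibrate_scores(val_logits,
                            vapply(va_f, `[[`, numeric(1), "label"))

    test_logits <- tta_predict_many(
      fit$model, test_feats, K = cfg$tta_k,
      seeds = vapply(seq_along(test_feats), function(j)
        derive_seed(rep_seed, 200, j), integer(1)),
      window_s = cfg$window_s)
    keys <- feats_field(test_feats, "key")
    rep_outputs[[r]] <- list(
      probs = stats::setNames(sigmoid(test_logits / cal$temperature), keys),
      threshold = cal$threshold, red_flags = cal$red_flags)
    rep_logits[[r]] <- stats::setNames(test_logits, keys)
    calib_log[[r]] <- data.frame(
      method = variant, fold = fold_idx, rep = r,
      temperature = cal$temperature, threshold = cal$threshold,
      n_val = cal$n_val, fallback = cal$fallback,
      red_flags = paste(cal$red_flags, collapse = ";"),
      best_epoch = fit$best_epoch)
  }

  ens <- ensemble_repetitions(rep_outputs)
  keys <- names(ens$probs)
  lm <- rowMeans(matrix(vapply(rep_logits, function(l) l[keys],
                               numeric(length(keys))), nrow = length(keys)))
  preds <- data.frame(
    participant = feats_field(test_feats, "participant"),
    task = feats_field(test_feats, "task"),
    session = vapply(test_feats, `[[`, numeric(1), "session"),
    method = variant, fold = fold_idx,
    raw_logit = lm,
    probability = unname(ens$probs),
    threshold = ens$threshold,
    label = vapply(test_feats, `[[`, numeric(1), "label"))
  list(predictions = preds, calibration = do.call(rbind, calib_log))
}

#' Run the full cross-validated fusion experiment
#'
#' For each requested variant (and each task in the task-wise regime),
#' runs 5-fold participant-grouped stratified cross-validation: per outer
#' fold, three grouped 70/30 inner repetitions are trained with early
#' stopping, calibrated with guard-railed temperature scaling, ensembled
#' (calibrated probabilities and thresholds averaged), and applied with
#' TTA to the held-out fold. Episodes are filtered per variant by modality
#' completeness. All seeds derive deterministically from `cfg$seed`, the
#' variant, the fold, and the repetition, so identical inputs reproduce an
#' identical prediction table.
#'
#' @param manifest Manifest data.frame with resolved paths.
#' @param variants Character vector of fusion variants to run.
#' @param regime `"pooled"` (one model over all tasks) or `"taskwise"`
#'   (separate models per task).
#' @param cfg A [train_config()].
#' @param k Outer folds.
#' @param features Optional precomputed [prepare_features()] output.
#' @return List with `predictions` (one row per test episode x method
#'   (x task model)), `calibration` (per fold x repetition log including
#'   red flags), and `splits` (outer fold participant lists).
#' @export
run_experiment <- function(manifest, variants = FUSION_VARIANTS,
                           regime = c("pooled", "taskwise"),
                           cfg = train_config(), k = 5, features = NULL) {
  regime <- match.arg(regime)
  stop_if(!all(variants %in% FUSION_VARIANTS), "unknown variant name")
  feats <- features %||% prepare_features(manifest)
  folds <- make_outer_splits(manifest, k = k, seed = cfg$seed)
  all_p <- unique(manifest$participant_id)

  preds <- list(); calib <- list()
  for (vi in seq_along(variants)) {
    variant <- variants[vi]
    elig <- feats[variant_eligible(feats, variant)]
    if (length(elig) == 0) {
      warning("variant ", variant, " has no eligible episodes; skipped")
      next
    }
    task_sets <- if (regime == "pooled") list(pooled = elig)
    else split(elig, feats_field(elig, "task"))
    for (ts_name in names(task_sets)) {
      ts_feats <- task_sets[[ts_name]]
      for (fold_idx in seq_along(folds)) {
        cell <- run_one_cell(ts_feats, variant, fold_idx, folds[[fold_idx]],
                             all_p, cfg, vi)
        if (is.null(cell)) next
        if (regime == "taskwise") cell$predictions$task_model <- ts_name
        preds[[length(preds) + 1]] <- cell$predictions
        calib[[length(calib) + 1]] <- cell$calibration
      }
    }
  }
  list(predictions = do.call(rbind, preds),
       calibration = do.call(rbind, calib),
       splits = folds)
}
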