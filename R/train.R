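# Training loop: class-weighted cross-entropy, AdamW, gradient clipping,
# early stopping on a smoothed validation AUC, per-epoch random crops,
# and test-time augmentation.

#' Training configuration
#'
#' Defaults are the fixed hyperparameters shared by every variant:
#' AdamW at constant learning rate 1e-3 with decoupled weight decay 1e-2,
#' batch size 32, at most 50 epochs, gradient-norm clipping at 1.0, early
#' stopping on the mean of the last three epochs' validation AUC with
#' patience 4, and 15 s crop windows with K = 3 test-time crops. The
#' `scaled_down` regime (3 s windows, 15-epoch cap) keeps continuous
#' integration runs short without touching any other setting.
#'
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Episodes per gradient step.
#' @param max_epochs Epoch cap.
#' @param clip_norm Global gradient-norm ceiling.
#' @param patience Epochs without smoothed-AUC improvement before stopping.
#' @param smoothing_window Epochs averaged into the smoothed AUC.
#' @param seed Master seed (splits, initialization, crops, dropout).
#' @param window_s Crop window length (seconds).
#' @param tta_k Test-time crops per episode.
#' @param scale `"full"` or `"scaled_down"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-2, batch_size = 32,
                         max_epochs = 50, clip_norm = 1.0, patience = 4,
                         smoothing_window = 3, seed = 42, window_s = 15,
                         tta_k = 3, scale = c("full", "scaled_down")) {
  scale <- match.arg(scale)
  if (scale == "scaled_down") {
    if (missing(window_s)) window_s <- 3
    if (missing(max_epochs)) max_epochs <- 15
    # at toy cohort sizes a batch of 32 collapses an epoch into a single
    # optimizer step; the reduced regime restores a useful step count
    if (missing(batch_size)) batch_size <- 4
  }
  if (missing(smoothing_window)) smoothing_window <- min(3L, max_epochs)
  stop_if(lr <= 0 || batch_size <= 0 || max_epochs <= 0 || patience <= 0,
          "training settings must be positive")
  stop_if(smoothing_window > max_epochs,
          "smoothing_window must not exceed max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), clip_norm = clip_norm,
                 patience = as.integer(patience),
                 smoothing_window = as.integer(smoothing_window),
                 seed = as.integer(seed), window_s = window_s,
                 tta_k = as.integer(tta_k), scale = scale),
            class = "train_config")
}

#' Inverse-frequency class weights normalized to mean one
#'
#' @param labels 0/1 integer labels (1 = PD).
#' @return Named numeric vector `c(neg, pos)` with mean 1.
#' @export
class_weights <- function(labels) {
  stop_if(length(unique(labels)) < 2, "training data must contain both classes")
  freq <- c(neg = mean(labels == 0), pos = mean(labels == 1))
  w <- 1 / freq
  w / mean(w)
}

# Assemble a batch of crops (all sharing T) into stacked matrices.
stack_crops <- function(crops) {
  list(Xa = if (!is.null(crops[[1]]$X_a)) do.call(rbind, lapply(crops, `[[`, "X_a")) else NULL,
       Xi = if (!is.null(crops[[1]]$X_i)) do.call(rbind, lapply(crops, `[[`, "X_i")) else NULL,
       T_len = crops[[1]]$T, B = length(crops))
}

# Evaluation-mode logits for an arbitrary list of crops: crops of equal
# length are grouped into batches of up to `batch_size` and forwarded
# together; the returned logits follow the input order.
predict_logits <- function(model, crops, batch_size = 32) {
  out <- numeric(length(crops))
  lens <- vapply(crops, `[[`, numeric(1), "T")
  for (T_val in unique(lens)) {
    members <- which(lens == T_val)
    for (chunk in split(members, ceiling(seq_along(members) / batch_size))) {
      bt <- stack_crops(crops[chunk])
      out[chunk] <- model_forward(model, bt$Xa, bt$Xi, bt$T_len, bt$B,
                                  train = FALSE, need_grad = FALSE)$logit
    }
  }
  out
}

#' Train one model on episode features
#'
#' Each epoch draws one fresh random crop per training episode, groups
#' crops of equal length into batches, and takes one AdamW step per batch
#' on the class-weighted binary cross-entropy. After each epoch the
#' validation AUC is computed from raw (uncalibrated) probabilities on a
#' deterministic centered crop per validation episode; training stops when
#' the smoothed AUC (mean of the last `smoothing_window` epochs) has not
#' improved for `patience` consecutive epochs, and the weights from the
#' best smoothed epoch are restored.
#'
#' @param model Output of [build_model()].
#' @param train_feats,val_feats Lists of episode features (see
#'   [prepare_features()]); each has `mel`, `imu`, and `label`.
#' @param cfg A [train_config()].
#' @return List with the trained `model` and a `history` data.frame
#'   (epoch, loss, val_auc, smoothed_auc).
#' @export
train_model <- function(model, train_feats, val_feats, cfg = train_config()) {
  labels <- vapply(train_feats, `[[`, numeric(1), "label")
  cw <- class_weights(labels)
  opt <- adamw_init(model$params)

  val_crops <- lapply(val_feats, function(f)
    center_crop(f$mel, f$imu, cfg$window_s))
  val_labels <- vapply(val_feats, `[[`, numeric(1), "label")

  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric(), smoothed_auc = numeric())
  best <- list(smoothed = -Inf, params = model$params, epoch = 0L)
  aucs <- numeric(0)
  since_improved <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    crops <- lapply(seq_along(train_feats), function(i)
      make_crops(train_feats[[i]]$mel, train_feats[[i]]$imu, "train",
                 seed = derive_seed(cfg$seed, epoch, i),
                 window_s = cfg$window_s)[[1]])
    ord <- with_seed(derive_seed(cfg$seed, epoch), sample.int(length(crops)))
    lens <- vapply(crops[ord], `[[`, numeric(1), "T")
    epoch_loss <- 0; n_seen <- 0; batch_id <- 0
    for (T_val in unique(lens)) {
      members <- ord[lens == T_val]
      for (chunk in split(members, ceiling(seq_along(members) / cfg$batch_size))) {
        batch_id <- batch_id + 1
        bt <- stack_crops(crops[chunk])
        y <- labels[chunk]
        w <- ifelse(y == 1, cw["pos"], cw["neg"])
        step <- with_seed(derive_seed(cfg$seed, epoch, 9000 + batch_id), {
          fw <- model_forward(model, bt$Xa, bt$Xi, bt$T_len, bt$B, train = TRUE)
          p <- sigmoid(fw$logit)
          loss <- mean(w * (softplus(fw$logit) - y * fw$logit))
          dlogit <- w * (p - y) / bt$B
          grads <- model_backward(model, fw$cache, dlogit)
          list(loss = loss, grads = grads)
        })
        grads <- clip_global_norm(step$grads, cfg$clip_norm)
        upd <- adamw_step(model$params, grads, opt, lr = cfg$lr,
                          weight_decay = cfg$weight_decay)
        model$params <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + step$loss * bt$B
        n_seen <- n_seen + bt$B
      }
    }

    val_logits <- predict_logits(model, val_crops)
    val_auc <- if (length(unique(val_labels)) < 2) 0.5
    else auc_rank(sigmoid(val_logits), val_labels)
    aucs <- c(aucs, val_auc)
    smoothed <- mean(utils::tail(aucs, cfg$smoothing_window))
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epoch_loss / n_seen,
      val_auc = val_auc, smoothed_auc = smoothed))

    if (smoothed > best$smoothed) {
      best <- list(smoothed = smoothed, params = model$params, epoch = epoch)
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
      if (since_improved >= cfg$patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Test-time-augmented prediction for one episode
#'
#' Draws `K` random crops in test mode (identical when the episode is
#' shorter than the window) and returns the arithmetic mean of the
#' per-crop logits.
#'
#' @param model Trained model.
#' @param feats One episode's features (`mel`, `imu`).
#' @param K Number of crops.
#' @param seed Integer seed for the crop starts.
#' @param window_s Crop window (seconds).
#' @return Mean raw logit (scalar).
#' @export
tta_predict <- function(model, feats, K = 3, seed = 1, window_s = 15) {
  crops <- make_crops(feats$mel, feats$imu, "test", K = K, seed = seed,
                      window_s = window_s)
  mean(predict_logits(model, crops))
}

# Batched TTA over a list of episodes: every episode's K test crops are
# predicted in shared batches; returns the per-episode mean logits.
tta_predict_many <- function(model, feats_list, K = 3, seeds, window_s = 15) {
  crops <- list(); owner <- integer(0)
  for (j in seq_along(feats_list)) {
    cj <- make_crops(feats_list[[j]]$mel, feats_list[[j]]$imu, "test",
                     K = K, seed = seeds[j], window_s = window_s)
    crops <- c(crops, cj)
    owner <- c(owner, rep(j, length(cj)))
  }
  logits <- predict_logits(model, crops)
  as.numeric(tapply(logits, owner, mean))
}
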