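# Post hoc probability calibration: temperature scaling with guard-rails,
# operating-threshold selection on calibrated probabilities, and
# repetition ensembling.

TEMP_RANGE <- c(0.300, 3.000)
THRESH_RANGE <- c(0.200, 0.800)

#' Temperature scaling and operating-threshold selection with guard-rails
#'
#' Fits the calibration temperature by minimizing the validation negative
#' log-likelihood of `sigmoid(logit / T)` over `T` in \[0.3, 3.0\], then
#' picks the smallest threshold in \[0.2, 0.8\] (over a grid of 0.01 steps
#' joined with the unique calibrated probabilities) that maximizes
#' validation F1. Small validation sets (`n < 20`) and single-class label
#' sets fall back to the conservative `T = 1, t = 0.5`; any fallback or
#' guard-rail clipping is recorded in `red_flags`.
#'
#' @param val_logits Raw validation logits (TTA-averaged).
#' @param val_labels 0/1 labels (1 = PD).
#' @return List of class `calibration_result`: `temperature`, `threshold`,
#'   `n_val`, `fallback`, `red_flags`.
#' @export
calibrate_scores <- function(val_logits, val_labels) {
  stopifnot(length(val_logits) == length(val_labels))
  n_val <- length(val_labels)
  flags <- character(0)

  fallback_result <- function(flags) {
    structure(list(temperature = 1.0, threshold = 0.5, n_val = n_val,
                   fallback = TRUE, red_flags = flags),
              class = "calibration_result")
  }
  if (n_val < 20) return(fallback_result(c(flags, "fallback_small_val")))
  if (length(unique(val_labels)) < 2)
    return(fallback_result(c(flags, "single_class_val")))

  nll <- function(temp) {
    p <- pmin(pmax(sigmoid(val_logits / temp), 1e-12), 1 - 1e-12)
    -sum(val_labels * log(p) + (1 - val_labels) * log(1 - p))
  }
  opt <- stats::optimize(nll, TEMP_RANGE, tol = 1e-4)
  cand_t <- c(opt$minimum, TEMP_RANGE)
  cand_v <- c(opt$objective, nll(TEMP_RANGE[1]), nll(TEMP_RANGE[2]))
  temp <- cand_t[which.min(cand_v)]
  if (min(abs(temp - TEMP_RANGE)) < 1e-3) {
    temp <- TEMP_RANGE[which.min(abs(temp - TEMP_RANGE))]
    flags <- c(flags, "temperature_clipped")
  }

  probs <- sigmoid(val_logits / temp)
  grid <- sort(unique(c(seq(THRESH_RANGE[1], THRESH_RANGE[2], by = 0.01),
                        probs[probs >= THRESH_RANGE[1] &
                                probs <= THRESH_RANGE[2]])))
  f1s <- vapply(grid, function(t) f1_score(probs, val_labels, t), numeric(1))
  thr <- grid[which.max(f1s)]  # which.max returns the first (smallest) maximizer
  if (thr <= THRESH_RANGE[1] + 1e-12 || thr >= THRESH_RANGE[2] - 1e-12)
    flags <- c(flags, "threshold_clipped")

  structure(list(temperature = temp, threshold = thr, n_val = n_val,
                 fallback = FALSE, red_flags = flags),
            class = "calibration_result")
}

#' Ensemble calibrated repetitions into fold-level predictions
#'
#' Per-episode probability is the mean of the repetitions' calibrated
#' probabilities, the operating threshold is the mean of the repetitions'
#' selected thresholds, and red flags are unioned.
#'
#' @param rep_outputs List (one per repetition) of lists with `probs`
#'   (named numeric vector keyed by episode), `threshold`, `red_flags`.
#' @return List with `probs`, `threshold`, `red_flags`.
#' @export
ensemble_repetitions <- function(rep_outputs) {
  stop_if(length(rep_outputs) < 1, "need at least one repetition")
  keys <- names(rep_outputs[[1]]$probs)
  pm <- vapply(rep_outputs, function(r) r$probs[keys],
               numeric(length(keys)))
  pm <- matrix(pm, nrow = length(keys))
  list(probs = stats::setNames(rowMeans(pm), keys),
       threshold = mean(vapply(rep_outputs, `[[`, numeric(1), "threshold")),
       red_flags = sort(unique(unlist(lapply(rep_outputs, `[[`, "red_flags")))))
}
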