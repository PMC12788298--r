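# Subject-grouped cross-validation splits: stratified group k-fold on the
# outside, grouped 70/30 shuffle splits on the inside. Participants, not
# episodes, are the unit of assignment throughout.

#' Stratified participant-grouped outer folds
#'
#' Assigns participants to `k` folds so that per-fold class proportions are
#' as balanced as integer constraints allow (round-robin deal of a seeded
#' shuffle within each class); all episodes of a participant follow their
#' fold.
#'
#' @param manifest Manifest data.frame with `participant_id` and `group`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of length `k`; element j is the character vector of test
#'   participants for fold j.
#' @export
make_outer_splits <- function(manifest, k = 5, seed = 42) {
  pt <- unique(manifest[c("participant_id", "group")])
  stop_if(anyDuplicated(pt$participant_id) > 0,
          "a participant appears with more than one group label")
  classes <- unique(pt$group)
  stop_if(length(classes) < 2, "both classes must be present in the cohort")
  for (cl in classes) {
    stop_if(sum(pt$group == cl) < k,
            paste0("class ", cl, " has fewer participants than folds"))
  }
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in classes) {
      ids <- pt$participant_id[pt$group == cl]
      ids <- ids[sample.int(length(ids))]
      assign_to <- (seq_along(ids) - 1L) %% k + 1L
      for (j in 1:k) folds[[j]] <- c(folds[[j]], ids[assign_to == j])
    }
  })
  folds
}

#' Grouped 70/30 inner train/validation splits
#'
#' Per repetition, about 30% of the training-fold participants form the
#' validation side; no participant appears on both sides, and both classes
#' are represented on each side whenever feasible.
#'
#' @param train_participants data.frame with `participant_id` and `group`
#'   for the outer-fold training participants.
#' @param reps Number of repetitions.
#' @param val_frac Validation fraction of participants.
#' @param seed Integer seed.
#' @return List of length `reps`; each element has `train` and `val`
#'   character vectors of participant ids.
#' @export
make_inner_splits <- function(train_participants, reps = 3, val_frac = 0.3,
                              seed = 42) {
  pt <- unique(train_participants[c("participant_id", "group")])
  n <- nrow(pt)
  stop_if(length(unique(pt$group)) < 2,
          "training fold must contain both classes")
  for (cl in unique(pt$group)) {
    stop_if(sum(pt$group == cl) < 2,
            paste0("training fold needs >= 2 participants of class ", cl))
  }
  n_val <- max(1L, round(val_frac * n))
  lapply(seq_len(reps), function(r) {
    with_seed(derive_seed(seed, r), {
      ord <- pt[sample.int(n), ]
      val <- ord$participant_id[seq_len(n_val)]
      train <- ord$participant_id[-seq_len(n_val)]
      # keep both classes on each side when feasible
      for (cl in unique(pt$group)) {
        cl_ids <- pt$participant_id[pt$group == cl]
        if (!any(val %in% cl_ids) && sum(train %in% cl_ids) >= 2) {
          mv <- train[train %in% cl_ids][1]
          other <- val[!val %in% cl_ids][1]
          val <- c(setdiff(val, other), mv)
          train <- c(setdiff(train, mv), other)
        }
        if (!any(train %in% cl_ids) && sum(val %in% cl_ids) >= 2) {
          mv <- val[val %in% cl_ids][1]
          other <- train[!train %in% cl_ids][1]
          train <- c(setdiff(train, other), mv)
          val <- c(setdiff(val, mv), other)
        }
      }
      list(train = train, val = val)
    })
  })
}
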