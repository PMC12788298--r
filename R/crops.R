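# Windowing: aligned 15 s crops with train-time random sampling and
# test-time augmentation (K random crops).

MEL_FPS <- 50  # mel frames per second (16000 / 320)

#' Extract aligned audio/IMU crops from one episode
#'
#' The usable overlap is `D = min(audio duration, IMU duration)` (a missing
#' modality does not constrain the overlap for unimodal use). If
#' `D > window_s`, crops of exactly `window_s` seconds are drawn with
#' uniformly random starts (one crop in train mode, `K` in test mode);
#' otherwise the full overlap forms the single possible crop and all `K`
#' test crops are identical. The IMU channels are interpolated onto the
#' cropped mel-frame timestamps, so both modalities share the first
#' dimension `T = round(50 * crop seconds)`.
#'
#' @param mel A `mel_sequence` from [compute_logmel()], or `NULL` for
#'   IMU-only use.
#' @param imu A normalized `imu_stream`, or `NULL` for audio-only use.
#' @param mode `"train"` (1 crop) or `"test"` (`K` crops).
#' @param K Number of test-time crops.
#' @param seed Integer seed for the crop starts.
#' @param window_s Crop window length in seconds (15 by default).
#' @return List of crops, each with `X_a` (T x 56 or NULL), `X_i`
#'   (T x 6 or NULL), `T`, and `crop_start` (seconds).
#' @export
make_crops <- function(mel, imu, mode = c("train", "test"), K = 3,
                       seed = 1, window_s = 15) {
  mode <- match.arg(mode)
  stop_if(is.null(mel) && is.null(imu), "at least one modality is required")
  audio_dur <- if (!is.null(mel)) nrow(mel$values) / MEL_FPS else Inf
  imu_dur <- if (!is.null(imu)) length(imu$times) / imu$rate else Inf
  D <- min(audio_dur, imu_dur)
  stop_if(!is.finite(D) || D <= 0, "empty overlap between modalities")

  frame_times <- if (!is.null(mel)) mel$frame_times
  else (0:(round(MEL_FPS * D) - 1)) / MEL_FPS
  n_frames_total <- length(frame_times)

  n_crops <- if (mode == "train") 1L else as.integer(K)
  if (D > window_s) {
    T_crop <- round(MEL_FPS * window_s)
    s_max <- min(floor((D - window_s) * MEL_FPS), n_frames_total - T_crop)
    starts <- with_seed(seed, sample.int(s_max + 1, n_crops, replace = TRUE) - 1L)
  } else {
    T_crop <- min(n_frames_total, round(MEL_FPS * D))
    starts <- rep(0L, n_crops)
  }

  lapply(starts, function(s0) {
    rows <- (s0 + 1):(s0 + T_crop)
    ft <- frame_times[rows]
    list(X_a = if (!is.null(mel)) mel$values[rows, , drop = FALSE] else NULL,
         X_i = if (!is.null(imu)) align_to_mel_grid(imu, ft) else NULL,
         T = T_crop, crop_start = ft[1])
  })
}

# Deterministic centered crop (used for per-epoch validation AUC).
center_crop <- function(mel, imu, window_s = 15) {
  audio_dur <- if (!is.null(mel)) nrow(mel$values) / MEL_FPS else Inf
  imu_dur <- if (!is.null(imu)) length(imu$times) / imu$rate else Inf
  D <- min(audio_dur, imu_dur)
  frame_times <- if (!is.null(mel)) mel$frame_times
  else (0:(round(MEL_FPS * D) - 1)) / MEL_FPS
  n_frames_total <- length(frame_times)
  if (D > window_s) {
    T_crop <- round(MEL_FPS * window_s)
    s0 <- max(0, floor((n_frames_total - T_crop) / 2))
  } else {
    T_crop <- min(n_frames_total, round(MEL_FPS * D))
    s0 <- 0
  }
  rows <- (s0 + 1):(s0 + T_crop)
  ft <- frame_times[rows]
  list(X_a = if (!is.null(mel)) mel$values[rows, , drop = FALSE] else NULL,
       X_i = if (!is.null(imu)) align_to_mel_grid(imu, ft) else NULL,
       T = T_crop, crop_start = ft[1])
}
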