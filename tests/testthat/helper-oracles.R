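# Independent oracles used to cross-check the package's implementations.

# Welch power spectral density: mean periodogram over 50%-overlapping
# Hann-windowed segments. Returns freq (Hz) and power density.
welch_psd <- function(x, fs, seg_len = 1024) {
  seg_len <- min(seg_len, length(x))
  hop <- seg_len %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / seg_len)
  u <- sum(win^2)
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  acc <- numeric(seg_len %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * win
    sp <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + sp[1:(seg_len %/% 2 + 1)]
  }
  list(freq = (0:(seg_len %/% 2)) * fs / seg_len, power = acc / length(starts))
}

band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  mean(psd$power[sel])
}

# Autocorrelation pitch estimate over 40-400 Hz, taking the shortest lag
# whose correlation is within 10% of the maximum (octave-error guard).
acf_pitch <- function(x, fs) {
  x <- x - mean(x)
  lags <- floor(fs / 400):ceiling(fs / 40)
  ac <- vapply(lags, function(l) {
    a <- x[1:(length(x) - l)]; b <- x[(l + 1):length(x)]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  fs / lags[which(ac >= 0.9 * max(ac))[1]]
}

# Brute-force AUC by concordant-pair counting (ties = 1/2).
auc_bruteforce <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon signed-rank p by direct enumeration of all
# 2^m sign assignments (small m only).
wilcoxon_enumerate <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(code)[1:m])
    ws[code + 1] <- sum(r[signs == 1])
  }
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Small in-memory episode features with directly constructed log-mel and
# IMU streams (class-shifted Gaussian features), for fast model/driver
# tests that do not need the audio synthesis path.
make_toy_features <- function(n_participants = 10, eps_per = 2, T_frames = 100,
                              shift = 1.5, seed = 1, tasks = c("T04", "T06")) {
  set.seed(seed)
  feats <- list()
  rows <- list()
  for (p in seq_len(n_participants)) {
    group <- if (p <= n_participants / 2) "PD" else "HC"
    lab <- as.numeric(group == "PD")
    for (e in seq_len(eps_per)) {
      task <- tasks[(e - 1) %% length(tasks) + 1]
      mel <- structure(list(
        values = matrix(rnorm(T_frames * 56, mean = lab * shift), T_frames, 56),
        frame_times = (0:(T_frames - 1)) / 50), class = "mel_sequence")
      n_i <- round(T_frames / 50 * 100)
      imu <- structure(list(
        values = matrix(rnorm(n_i * 6, mean = lab * shift), n_i, 6),
        times = (0:(n_i - 1)) / 100, rate = 100L), class = "imu_stream")
      id <- sprintf("P%03d", p)
      feats[[length(feats) + 1]] <- list(
        mel = mel, imu = imu, label = lab, participant = id, task = task,
        session = e, key = paste(id, task, e, sep = "|"))
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = id, group = group, task_id = task, session_index = e,
        wav_path = "x.wav", acc_path = "a.csv", gyr_path = "g.csv",
        age = 65, sex = "F")
    }
  }
  list(features = feats, manifest = do.call(rbind, rows))
}

# Episode records reproducing the per-group session/modality inventory of
# the motivating cohort (HC: 464 sessions, 216 audio / 218 accel /
# 218 gyro / 211 complete; PD: 358 sessions, 175 / 182 / 181 / 175).
published_inventory_records <- function() {
  build_group <- function(group, n_participants, sessions, audio, accel,
                          gyro, complete) {
    n_audio_only <- audio - complete
    n_accel_only <- accel - complete
    n_gyro_only <- gyro - complete
    present <- matrix(FALSE, sessions, 3)
    present[seq_len(complete), ] <- TRUE
    at <- complete
    present[at + seq_len(n_audio_only), 1] <- TRUE; at <- at + n_audio_only
    present[at + seq_len(n_accel_only), 2] <- TRUE; at <- at + n_accel_only
    present[at + seq_len(n_gyro_only), 3] <- TRUE
    data.frame(participant_id =
                 paste0(group, (seq_len(sessions) - 1) %% n_participants + 1),
               group = group, task_id = "T06",
               session_index = seq_len(sessions),
               wav_path = ifelse(present[, 1], "w.wav", NA),
               acc_path = ifelse(present[, 2], "a.csv", NA),
               gyr_path = ifelse(present[, 3], "g.csv", NA))
  }
  rbind(build_group("HC", 93, 464, 216, 218, 218, 211),
        build_group("PD", 72, 358, 175, 182, 181, 175))
}

fold_mean_auc <- function(preds) {
  cells <- parkfuse:::fold_cell_metrics(preds)
  mean(cells$auc, na.rm = TRUE)
}
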