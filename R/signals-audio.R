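# Audio front end: loading at 16 kHz and log-mel extraction.
#
# Log-mel convention: centered Hann-window STFT (NFFT = 1024, hop = 320),
# power spectrum, Slaney-style area-normalized mel filterbank (56 filters,
# 0-8 kHz), natural log with a 1e-10 floor. Frame count is truncated to
# floor(n_samples / hop) so a 15 s crop at 16 kHz yields exactly 750
# frames; frame k is timestamped at k * hop / rate.

AUDIO_RATE <- 16000L
MEL_NFFT <- 1024L
MEL_HOP <- 320L
N_MELS <- 56L
LOG_FLOOR <- 1e-10

#' Load an audio file as a 16 kHz mono peak-normalized waveform
#'
#' Files at other rates are low-pass filtered (8th-order Butterworth below
#' the target Nyquist) before linear resampling onto the 16 kHz grid;
#' channels are averaged to mono; the result is divided by its peak
#' absolute value (all-zero audio is returned unchanged).
#'
#' @param path Path to a WAV file (PCM-16 or float-32).
#' @return List with `samples` (numeric vector in \[-1, 1\]) and `rate`
#'   (16000).
#' @export
load_audio <- function(path) {
  w <- read_wav(path)
  x <- rowMeans(w$samples)
  stop_if(length(x) == 0, "zero-length audio")
  if (w$rate != AUDIO_RATE) {
    if (w$rate > AUDIO_RATE) {
      bf <- signal::butter(8, (0.45 * AUDIO_RATE) / (w$rate / 2))
      x <- as.numeric(signal::filtfilt(bf, x))
    }
    n_out <- round(length(x) / w$rate * AUDIO_RATE)
    t_in <- (seq_along(x) - 1) / w$rate
    t_out <- (seq_len(n_out) - 1) / AUDIO_RATE
    x <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  list(samples = x, rate = AUDIO_RATE)
}

# Slaney mel scale (linear below 1 kHz, logarithmic above).
hz_to_mel <- function(hz) {
  mel <- hz / (200 / 3)
  log_region <- hz >= 1000
  mel[log_region] <- 15 + log(hz[log_region] / 1000) / (log(6.4) / 27)
  mel
}
mel_to_hz <- function(mel) {
  hz <- mel * (200 / 3)
  log_region <- mel >= 15
  hz[log_region] <- 1000 * exp((mel[log_region] - 15) * log(6.4) / 27)
  hz
}

#' Mel filterbank matrix
#'
#' Triangular area-normalized (Slaney) filters on the 0-8 kHz range.
#'
#' @param n_mels Number of filters.
#' @param nfft FFT size.
#' @param rate Sampling rate (Hz).
#' @return `(nfft/2 + 1) x n_mels` weight matrix.
#' @export
mel_filterbank <- function(n_mels = N_MELS, nfft = MEL_NFFT, rate = AUDIO_RATE) {
  f_max <- rate / 2
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(f_max), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_f <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, nfft / 2 + 1, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_f - lo) / (ctr - lo)
    down <- (hi - bin_f) / (hi - ctr)
    fb[, m] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

#' Compute a log-mel spectrogram
#'
#' @param waveform Output of [load_audio()], or a numeric vector of 16 kHz
#'   samples.
#' @return List of class `mel_sequence` with `values` (T x 56 matrix of log
#'   power) and `frame_times` (seconds; frame k at `k * hop / rate`).
#' @export
compute_logmel <- function(waveform) {
  x <- if (is.list(waveform)) waveform$samples else waveform
  n <- length(x)
  stop_if(n < MEL_HOP, "waveform shorter than one hop")
  n_frames <- floor(n / MEL_HOP)

  half <- MEL_NFFT / 2
  xp <- c(rep(0, half), x, rep(0, half))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(MEL_NFFT - 1)) / MEL_NFFT)  # periodic Hann

  # Frame k (0-based) is centered at sample k * hop, i.e. starts at
  # k * hop in the padded signal.
  starts <- (0:(n_frames - 1)) * MEL_HOP
  idx <- outer(1:MEL_NFFT, starts, "+")
  frames <- matrix(xp[idx], nrow = MEL_NFFT) * win
  spec <- stats::mvfft(frames)[1:(half + 1), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2

  fb <- mel_filterbank()
  mel <- crossprod(power, fb)  # n_frames x n_mels
  structure(list(values = log(mel + LOG_FLOOR),
                 frame_times = starts / AUDIO_RATE),
            class = "mel_sequence")
}
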