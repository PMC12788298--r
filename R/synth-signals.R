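# Synthetic signal generators.
#
# Speech: a glottal-like pulse train whose fundamental follows a slow
# random-walk contour, shaped by a cascade of fixed second-order formant
# resonators, amplitude-modulated at syllabic and tremor rates, with
# additive noise at a target SNR and final peak normalization. This is a
# caricature of hypokinetic dysarthria markers (monopitch, monoloudness,
# vocal amplitude tremor), not acoustically realistic speech.
#
# IMU: per axis, low-frequency drift + broadband Gaussian noise + a tremor
# sinusoid at a fixed frequency in the 3-7 Hz band with random phase.

#' Synthesize a speech waveform
#'
#' @param params A [speech_params()] object.
#' @param seed Integer seed for the episode's random draws.
#' @param rate Output sampling rate in Hz (16000 by default; 48000 available
#'   to exercise the front end's rate conversion).
#' @return Numeric vector of mono samples with peak absolute value 1.
#' @export
synth_speech <- function(params, seed = 1, rate = 16000) {
  stopifnot(inherits(params, "speech_params"))
  stop_if(params$duration_s <= 0, "duration_s must be positive")
  n <- round(params$duration_s * rate)
  with_seed(seed, {
    t <- (0:(n - 1)) / rate

    # F0 contour: random walk at 100 Hz control rate, rescaled to f0_sd.
    nf <- max(2L, ceiling(params$duration_s * 100))
    walk <- cumsum(stats::rnorm(nf))
    walk <- walk - mean(walk)
    sdw <- stats::sd(walk)
    contour <- if (sdw > 0) walk / sdw * params$f0_sd else rep(0, nf)
    f0 <- stats::approx(seq(0, params$duration_s, length.out = nf), contour,
                        xout = t, rule = 2)$y + params$f0_mean
    f0 <- pmax(f0, 40)

    # Glottal pulse train from the accumulated phase.
    phase <- cumsum(f0) / rate
    src <- c(0, diff(floor(phase)))

    # Cascade of second-order resonators (fixed vowel-like formants).
    formants <- c(600, 1200, 2500)
    bws <- c(90, 110, 160)
    y <- src
    for (j in seq_along(formants)) {
      if (formants[j] >= rate / 2) next
      r <- exp(-pi * bws[j] / rate)
      th <- 2 * pi * formants[j] / rate
      y <- stats::filter(y * (1 - r), c(2 * r * cos(th), -r^2),
                         method = "recursive")
      y <- as.numeric(y)
    }

    # Amplitude envelope: syllabic (or slow loudness) x tremor modulation.
    f_mod <- if (params$syllable_rate > 0) params$syllable_rate else 0.3
    env_syl <- 1 - params$intensity_mod_depth *
      (0.5 + 0.5 * sin(2 * pi * f_mod * t + stats::runif(1, 0, 2 * pi)))
    env_trem <- 1 + params$amp_tremor_depth *
      sin(2 * pi * params$amp_tremor_freq * t + stats::runif(1, 0, 2 * pi))
    y <- y * env_syl * env_trem

    rms <- sqrt(mean(y^2))
    if (rms > 0) {
      noise_sd <- rms / 10^(params$noise_snr_db / 20)
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak
    y
  })
}

#' Synthesize accelerometer and gyroscope streams
#'
#' @param params An [imu_params()] object.
#' @param seed Integer seed for the episode's random draws.
#' @return List with `acc` and `gyr`, each a data.frame with columns
#'   `timestamp` (seconds, strictly increasing from 0), `x`, `y`, `z`.
#' @export
synth_imu <- function(params, seed = 1) {
  stopifnot(inherits(params, "imu_params"))
  stop_if(params$duration_s <= 0, "duration_s must be positive")
  one_stream <- function(fs, stream_seed) {
    n <- round(params$duration_s * fs)
    stop_if(n < 2, "duration too short for the sampling rate")
    with_seed(stream_seed, {
      t <- (0:(n - 1)) / fs
      amp <- sqrt(2 * params$tremor_power)
      ax <- lapply(1:3, function(k) {
        drift <- cumsum(stats::rnorm(n, 0, params$drift_rate / sqrt(fs))) +
          params$drift_rate * t * stats::runif(1, -1, 1)
        tremor <- amp * sin(2 * pi * params$tremor_freq * t +
                              stats::runif(1, 0, 2 * pi))
        drift + tremor + stats::rnorm(n, 0, params$noise_sd)
      })
      data.frame(timestamp = t, x = ax[[1]], y = ax[[2]], z = ax[[3]])
    })
  }
  list(acc = one_stream(params$acc_rate, derive_seed(seed, 1)),
       gyr = one_stream(params$gyr_rate, derive_seed(seed, 2)))
}
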