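ALL_TASKS <- c("T02", "T03", "T04", "T05", "T06")

#' Specification of a synthetic voice + head-IMU cohort
#'
#' Defines the study conditions the generator emulates: two diagnostic
#' groups (PD and HC), one to five standardized speech tasks per session,
#' episode durations spanning the 15 s analysis window, occasional missing
#' modality files, and per-task group-effect magnitudes on speech
#' (pitch/loudness variability, amplitude tremor) and on head-motion
#' tremor-band power.
#'
#' By default the speech effect is strong on every task (slightly stronger
#' on the story-recall and syllable-repetition tasks T04/T05), while the
#' inertial effect is present only on the movement-engaging tasks T03 and
#' T06. Setting an effect to 0 makes the two groups statistically
#' indistinguishable on that channel.
#'
#' @param n_pd,n_hc Number of PD / HC participants.
#' @param tasks Character vector of task ids, subset of `T02`..`T06`.
#' @param sessions_per_participant Episodes of each task per participant.
#' @param duration_range_s Length-2 numeric, min/max episode duration (s).
#' @param missing_modality_rate Probability that any one modality file is
#'   absent from an episode, independently per modality.
#' @param audio_effect Named numeric (per task) group-effect magnitude on
#'   speech parameters, >= 0; a scalar is recycled over `tasks`.
#' @param imu_effect Named numeric (per task) group-effect magnitude on
#'   tremor-band power, >= 0; a scalar is recycled over `tasks`.
#' @param seed Integer seed controlling all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 12, n_hc = 12,
                        tasks = ALL_TASKS,
                        sessions_per_participant = 1,
                        duration_range_s = c(8, 20),
                        missing_modality_rate = 0,
                        audio_effect = NULL,
                        imu_effect = NULL,
                        seed = 42) {
  stop_if(n_pd < 0 || n_hc < 0, "participant counts must be non-negative")
  stop_if(length(tasks) == 0, "task list must be non-empty")
  stop_if(!all(tasks %in% ALL_TASKS),
          paste("tasks must be among", paste(ALL_TASKS, collapse = ", ")))
  stop_if(missing_modality_rate < 0 || missing_modality_rate > 1,
          "missing_modality_rate must be in [0, 1]")
  stop_if(length(duration_range_s) != 2 || duration_range_s[1] <= 0 ||
            duration_range_s[2] < duration_range_s[1],
          "duration_range_s must be (min, max) with 0 < min <= max")

  expand_effect <- function(eff, default_map) {
    if (is.null(eff)) return(default_map[tasks])
    if (length(eff) == 1 && is.null(names(eff))) {
      eff <- stats::setNames(rep(as.numeric(eff), length(tasks)), tasks)
    }
    stop_if(!all(tasks %in% names(eff)),
            "every task must appear in the effect map")
    stop_if(any(eff < 0), "effect magnitudes must be >= 0")
    eff[tasks]
  }
  # audio-dominated tasks (T04/T05) carry the strongest speech effect;
  # the movement-engaging tasks (T03/T06) leave audio headroom and carry
  # the head-tremor effect instead
  default_audio <- stats::setNames(c(1, 0.7, 1.25, 1.25, 0.7), ALL_TASKS)
  default_imu   <- stats::setNames(c(0, 1, 0, 0, 1), ALL_TASKS)

  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    tasks = tasks,
    sessions_per_participant = as.integer(sessions_per_participant),
    duration_range_s = as.numeric(duration_range_s),
    missing_modality_rate = missing_modality_rate,
    audio_effect = expand_effect(audio_effect, default_audio),
    imu_effect = expand_effect(imu_effect, default_imu),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Parameters of one synthetic speech episode
#'
#' @param f0_mean Mean fundamental frequency (Hz), > 0.
#' @param f0_sd Standard deviation of the slow F0 contour (Hz); low values
#'   emulate parkinsonian monopitch.
#' @param intensity_mod_depth Depth of the loudness modulation in \[0, 1\];
#'   low values emulate monoloudness.
#' @param amp_tremor_freq Amplitude-tremor frequency (Hz).
#' @param amp_tremor_depth Amplitude-tremor depth in \[0, 1\].
#' @param syllable_rate Syllabic modulation rate (Hz); 0 for sustained vowel.
#' @param noise_snr_db Additive-noise SNR (dB).
#' @param duration_s Episode duration (s), > 0.
#' @return An object of class `speech_params`.
#' @export
speech_params <- function(f0_mean = 130, f0_sd = 12, intensity_mod_depth = 0.6,
                          amp_tremor_freq = 5, amp_tremor_depth = 0.02,
                          syllable_rate = 4, noise_snr_db = 30,
                          duration_s = 10) {
  stop_if(f0_mean <= 0, "f0_mean must be positive")
  stop_if(f0_sd < 0, "f0_sd must be non-negative")
  stop_if(intensity_mod_depth < 0 || intensity_mod_depth > 1,
          "intensity_mod_depth must be in [0, 1]")
  stop_if(amp_tremor_depth < 0 || amp_tremor_depth > 1,
          "amp_tremor_depth must be in [0, 1]")
  stop_if(duration_s <= 0, "duration_s must be positive")
  structure(as.list(environment()), class = "speech_params")
}

#' Parameters of one synthetic head-IMU episode
#'
#' Accelerometer and gyroscope streams at HoloLens-like native rates
#' (about 1.1 kHz and 3.8 kHz), each axis a sum of low-frequency drift,
#' broadband noise, and a tremor sinusoid in the 3-7 Hz band.
#'
#' @param acc_rate,gyr_rate Native sampling rates (Hz), > 200.
#' @param tremor_freq Tremor frequency (Hz) in \[3, 7\].
#' @param tremor_power Tremor sinusoid power (variance units); the sinusoid
#'   amplitude is `sqrt(2 * tremor_power)`.
#' @param drift_rate Low-frequency drift scale (units/s).
#' @param noise_sd Broadband noise standard deviation.
#' @param duration_s Episode duration (s), > 0.
#' @return An object of class `imu_params`.
#' @export
imu_params <- function(acc_rate = 1100, gyr_rate = 3800, tremor_freq = 5,
                       tremor_power = 0.05, drift_rate = 0.02, noise_sd = 1,
                       duration_s = 10) {
  stop_if(acc_rate <= 200 || gyr_rate <= 200, "IMU rates must exceed 200 Hz")
  stop_if(tremor_freq < 3 || tremor_freq > 7, "tremor_freq must be in [3, 7] Hz")
  stop_if(tremor_power < 0, "tremor_power must be non-negative")
  stop_if(duration_s <= 0, "duration_s must be positive")
  structure(as.list(environment()), class = "imu_params")
}
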