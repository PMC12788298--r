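# Cohort-level generation: manifest of episodes with group- and
# task-conditioned generation parameters, dataset writer, and the
# modality-completeness summary.

# PD effect model: relative to HC draws for the same task,
#   f0_sd              *= (1 - 0.6 * audio_effect)   (monopitch)
#   intensity_mod_depth *= (1 - 0.6 * audio_effect)  (monoloudness)
#   amp_tremor_depth    += 0.3 * audio_effect        (vocal tremor)
#   noise_snr_db        -= 8 * audio_effect          (breathiness / low HNR)
#   tremor_power        += 0.4 * imu_effect          (head tremor band)
draw_episode_params <- function(group, task, spec) {
  ae <- unname(spec$audio_effect[task])
  ie <- unname(spec$imu_effect[task])
  dur <- stats::runif(1, spec$duration_range_s[1], spec$duration_range_s[2])

  f0_sd <- stats::rlnorm(1, log(12), 0.3)
  imd <- stats::runif(1, 0.55, 0.85)
  atd <- stats::runif(1, 0, 0.05)
  snr <- stats::runif(1, 25, 35)
  if (group == "PD") {
    f0_sd <- f0_sd * max(0, 1 - 0.6 * ae)
    imd <- imd * max(0, 1 - 0.6 * ae)
    atd <- min(1, atd + 0.3 * ae)
    snr <- snr - 8 * ae
  }
  # syllabic rates sit below the 5-7 Hz vocal-tremor band so the two
  # amplitude modulations remain spectrally identifiable
  syl <- if (task == "T06") 0
  else if (task == "T05") stats::runif(1, 4, 5)
  else stats::runif(1, 2.5, 4.5)

  sp <- speech_params(
    f0_mean = max(75, stats::rnorm(1, 130, 25)),
    f0_sd = f0_sd,
    intensity_mod_depth = min(1, max(0, imd)),
    amp_tremor_freq = stats::runif(1, 5, 7),
    amp_tremor_depth = atd,
    syllable_rate = syl,
    noise_snr_db = snr,
    duration_s = dur)

  # the tremor-shift draw is consumed unconditionally so that two specs
  # differing only in imu_effect share identical audio and baseline IMU
  # draws (paired cohorts differing purely in head-tremor injection)
  tp <- stats::rlnorm(1, log(0.05), 0.4)
  tp_shift <- stats::runif(1, 0.7, 1.3)
  if (group == "PD") tp <- tp + 0.4 * ie * tp_shift
  ip <- imu_params(
    tremor_freq = stats::runif(1, 3.5, 6.5),
    tremor_power = tp,
    drift_rate = stats::runif(1, 0.01, 0.04),
    noise_sd = stats::runif(1, 0.8, 1.2),
    duration_s = dur)

  list(speech = sp, imu = ip)
}

#' Generate a synthetic cohort manifest
#'
#' Draws one episode per participant x session x task, with generation
#' parameters conditioned on diagnostic group and task (the PD effect model
#' reduces pitch and loudness variability and adds vocal and head tremor,
#' scaled by the spec's per-task effect magnitudes). Each modality file is
#' independently dropped with the spec's missing-modality rate; dropped
#' modalities have `NA` paths.
#'
#' @param spec A [cohort_spec()] object.
#' @return List with `records` (data.frame: participant_id, group, task_id,
#'   session_index, wav_path, acc_path, gyr_path, age, sex) and `params`
#'   (per-record list of `speech`/`imu` parameter objects plus a per-record
#'   `seed`). File paths are bare file names until [write_dataset()]
#'   resolves them against an output directory.
#' @export
make_cohort_manifest <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_pd + spec$n_hc
  groups <- c(rep("PD", spec$n_pd), rep("HC", spec$n_hc))
  ids <- sprintf("P%03d", seq_len(n))

  with_seed(spec$seed, {
    ages <- round(stats::runif(n, 55, 75))
    sexes <- rep_len(c("M", "F"), n)[sample.int(n)]

    rows <- list(); params <- list(); i <- 0
    for (p in seq_len(n)) {
      for (s in seq_len(spec$sessions_per_participant)) {
        for (task in spec$tasks) {
          i <- i + 1
          pp <- draw_episode_params(groups[p], task, spec)
          present <- stats::runif(3) >= spec$missing_modality_rate
          base <- sprintf("%s_%s_s%d", ids[p], task, s)
          rows[[i]] <- data.frame(
            participant_id = ids[p], group = groups[p], task_id = task,
            session_index = s,
            wav_path = if (present[1]) paste0(base, ".wav") else NA_character_,
            acc_path = if (present[2]) paste0(base, "_acc.csv") else NA_character_,
            gyr_path = if (present[3]) paste0(base, "_gyr.csv") else NA_character_,
            age = ages[p], sex = sexes[p],
            stringsAsFactors = FALSE)
          pp$seed <- derive_seed(spec$seed, i)
          params[[i]] <- pp
        }
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    list(records = records, params = params)
  })
}

#' Write a synthetic cohort to disk
#'
#' Materializes WAV and IMU CSV files for every present modality and writes
#' `manifest.csv` in the output directory. IMU timestamps are written either
#' as float seconds (`timestamp` column) or as 100 ns integer ticks
#' (`ticks` column; 1 s = 1e7 ticks).
#'
#' @param cohort Output of [make_cohort_manifest()].
#' @param out_dir Writable output directory (created if needed).
#' @param dialect `"seconds"` or `"ticks"` timestamp dialect for IMU CSVs.
#' @param bits WAV sample width: 16 (PCM) or 32 (IEEE float).
#' @param rate Audio sampling rate written to disk (16000 or 48000).
#' @return The manifest data.frame with path columns resolved to `out_dir`,
#'   invisibly; also written as `out_dir/manifest.csv`.
#' @export
write_dataset <- function(cohort, out_dir, dialect = c("seconds", "ticks"),
                          bits = 16, rate = 16000) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stop_if(!dir.exists(out_dir), paste("cannot create directory", out_dir))
  records <- cohort$records

  write_imu_csv <- function(stream, path) {
    if (dialect == "ticks") {
      stream <- data.frame(ticks = as.integer(round(stream$timestamp * 1e7)),
                           x = stream$x, y = stream$y, z = stream$z)
    }
    data.table::fwrite(stream, path, showProgress = FALSE)
  }

  for (i in seq_len(nrow(records))) {
    pp <- cohort$params[[i]]
    if (!is.na(records$wav_path[i])) {
      records$wav_path[i] <- file.path(out_dir, records$wav_path[i])
      w <- synth_speech(pp$speech, seed = derive_seed(pp$seed, 10), rate = rate)
      write_wav(w, records$wav_path[i], rate = rate, bits = bits)
    }
    needs_imu <- !is.na(records$acc_path[i]) || !is.na(records$gyr_path[i])
    if (needs_imu) {
      imu <- synth_imu(pp$imu, seed = derive_seed(pp$seed, 20))
      if (!is.na(records$acc_path[i])) {
        records$acc_path[i] <- file.path(out_dir, records$acc_path[i])
        write_imu_csv(imu$acc, records$acc_path[i])
      }
      if (!is.na(records$gyr_path[i])) {
        records$gyr_path[i] <- file.path(out_dir, records$gyr_path[i])
        write_imu_csv(imu$gyr, records$gyr_path[i])
      }
    }
  }
  utils::write.csv(records, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(records)
}

#' Generate and materialize a synthetic cohort in one call
#'
#' @inheritParams write_dataset
#' @param spec A [cohort_spec()] object.
#' @return The resolved manifest data.frame.
#' @export
synth_cohort <- function(spec, out_dir, dialect = "seconds", bits = 16) {
  cohort <- make_cohort_manifest(spec)
  write_dataset(cohort, out_dir, dialect = dialect, bits = bits)
}

#' Summarize modality completeness per group
#'
#' A session (episode record) counts as complete iff all three modality
#' paths are present. The overall complete fraction is
#' `complete / sessions` pooled over groups, in percent.
#'
#' @param records Manifest data.frame with `participant_id`, `group`,
#'   `wav_path`, `acc_path`, `gyr_path` columns.
#' @return List with `table` (one row per group: participants, sessions,
#'   audio, accel, gyro, complete) and `complete_fraction_pct`.
#' @export
summarize_completeness <- function(records) {
  per_group <- lapply(split(records, records$group), function(g) {
    data.frame(
      group = g$group[1],
      participants = length(unique(g$participant_id)),
      sessions = nrow(g),
      audio = sum(!is.na(g$wav_path)),
      accel = sum(!is.na(g$acc_path)),
      gyro = sum(!is.na(g$gyr_path)),
      complete = sum(!is.na(g$wav_path) & !is.na(g$acc_path) &
                       !is.na(g$gyr_path)))
  })
  tab <- do.call(rbind, per_group)
  rownames(tab) <- NULL
  frac <- if (sum(tab$sessions) > 0)
    100 * sum(tab$complete) / sum(tab$sessions) else NA_real_
  list(table = tab, complete_fraction_pct = frac)
}
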