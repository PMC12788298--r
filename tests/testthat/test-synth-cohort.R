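# Synthetic cohort generator: manifest structure, modality dropping,
# determinism, group-identity under zero effects, and signal properties.

test_that("manifest has the right episode counts and uniqueness", {
  spec <- cohort_spec(n_pd = 2, n_hc = 2, tasks = "T06",
                      sessions_per_participant = 1,
                      missing_modality_rate = 0, seed = 1)
  ch <- make_cohort_manifest(spec)
  expect_equal(nrow(ch$records), 4)
  expect_true(all(!is.na(ch$records$wav_path)))
  expect_true(all(!is.na(ch$records$acc_path)))
  expect_true(all(!is.na(ch$records$gyr_path)))
  key <- with(ch$records, paste(participant_id, task_id, session_index))
  expect_equal(anyDuplicated(key), 0)
  expect_equal(length(unique(ch$records$group[ch$records$participant_id ==
                                                ch$records$participant_id[1]])), 1)

  spec2 <- cohort_spec(n_pd = 3, n_hc = 2, tasks = c("T02", "T05"),
                       sessions_per_participant = 2, seed = 1)
  ch2 <- make_cohort_manifest(spec2)
  expect_equal(nrow(ch2$records), 5 * 2 * 2)
})

test_that("degenerate missing-modality rates behave as stated", {
  spec <- cohort_spec(n_pd = 3, n_hc = 3, tasks = c("T03", "T06"),
                      missing_modality_rate = 1, seed = 2)
  ch <- make_cohort_manifest(spec)
  expect_true(all(is.na(ch$records$wav_path)))
  expect_true(all(is.na(ch$records$acc_path)))
  expect_true(all(is.na(ch$records$gyr_path)))
})

test_that("per-modality presence tallies match the missing rate", {
  spec <- cohort_spec(n_pd = 50, n_hc = 50, tasks = c("T02", "T06"),
                      missing_modality_rate = 0.3, seed = 11)
  ch <- make_cohort_manifest(spec)
  for (col in c("wav_path", "acc_path", "gyr_path")) {
    frac <- mean(!is.na(ch$records[[col]]))
    expect_gt(frac, 0.65)
    expect_lt(frac, 0.75)
  }
})

test_that("generation is deterministic for a fixed spec and seed", {
  spec <- cohort_spec(n_pd = 4, n_hc = 4, seed = 33)
  a <- make_cohort_manifest(spec)
  b <- make_cohort_manifest(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$params, b$params)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(tasks = character(0)), "non-empty")
  expect_error(cohort_spec(n_pd = -1), "non-negative")
  expect_error(cohort_spec(missing_modality_rate = 1.5), "\\[0, 1\\]")
  expect_error(cohort_spec(tasks = "T99"), "among")
})

test_that("zero effects make parameter draws identical in law across groups", {
  passes <- 0
  for (s in 1:10) {
    spec <- cohort_spec(n_pd = 200, n_hc = 200, tasks = "T03",
                        audio_effect = 0, imu_effect = 0, seed = 100 + s)
    ch <- make_cohort_manifest(spec)
    pd <- ch$records$group == "PD"
    f0sd_pd <- vapply(ch$params[pd], function(p) p$speech$f0_sd, numeric(1))
    f0sd_hc <- vapply(ch$params[!pd], function(p) p$speech$f0_sd, numeric(1))
    tp_pd <- vapply(ch$params[pd], function(p) p$imu$tremor_power, numeric(1))
    tp_hc <- vapply(ch$params[!pd], function(p) p$imu$tremor_power, numeric(1))
    ok <- suppressWarnings(ks.test(f0sd_pd, f0sd_hc)$p.value) > 0.01 &&
      suppressWarnings(ks.test(tp_pd, tp_hc)$p.value) > 0.01
    passes <- passes + ok
  }
  expect_gte(passes, 9)
})

test_that("PD effect model shifts draws in the documented directions", {
  spec <- cohort_spec(n_pd = 150, n_hc = 150, tasks = "T06",
                      audio_effect = 1, imu_effect = 1, seed = 5)
  ch <- make_cohort_manifest(spec)
  pd <- ch$records$group == "PD"
  get <- function(sel, field, mod = "speech")
    vapply(ch$params[sel], function(p) p[[mod]][[field]], numeric(1))
  expect_lt(mean(get(pd, "f0_sd")), mean(get(!pd, "f0_sd")))
  expect_lt(mean(get(pd, "intensity_mod_depth")),
            mean(get(!pd, "intensity_mod_depth")))
  expect_gt(mean(get(pd, "amp_tremor_depth")),
            mean(get(!pd, "amp_tremor_depth")))
  expect_gt(mean(get(pd, "tremor_power", "imu")),
            mean(get(!pd, "tremor_power", "imu")))
})

test_that("speech synthesis honors duration, pitch, and normalization", {
  p <- speech_params(duration_s = 10)
  w <- synth_speech(p, seed = 1)
  expect_length(w, 160000)
  expect_equal(max(abs(w)), 1)

  p2 <- speech_params(f0_mean = 120, f0_sd = 0, amp_tremor_depth = 0,
                      syllable_rate = 0, intensity_mod_depth = 0,
                      noise_snr_db = 60, duration_s = 2)
  w2 <- synth_speech(p2, seed = 2)
  expect_lt(abs(acf_pitch(w2, 16000) - 120) / 120, 0.02)

  expect_error(synth_speech(speech_params(duration_s = 1),
                            seed = 1, rate = 16000), NA)
  expect_error(speech_params(duration_s = 0), "positive")
})

test_that("IMU synthesis has the stated sample counts and spectra", {
  p <- imu_params(acc_rate = 1100, duration_s = 15, tremor_power = 0)
  s <- synth_imu(p, seed = 3)
  expect_lte(abs(nrow(s$acc) - 16500), 1)
  expect_true(all(diff(s$acc$timestamp) > 0))
  expect_identical(s$acc$timestamp[1], 0)

  # flat spectrum without tremor: 3-7 Hz band within 3 dB of 8-12 Hz band
  psd <- welch_psd(s$acc$x, 1100, seg_len = 4096)
  ratio_db <- 10 * log10(band_power(psd, 3, 7) / band_power(psd, 8, 12))
  expect_lt(abs(ratio_db), 3)

  # dominant tremor peak lands at the injected frequency
  p2 <- imu_params(tremor_freq = 5, tremor_power = 50, noise_sd = 0.5,
                   duration_s = 15)
  s2 <- synth_imu(p2, seed = 4)
  psd2 <- welch_psd(s2$gyr$y, 3800, seg_len = 8192)
  sel <- psd2$freq > 0.5 & psd2$freq < 20
  peak <- psd2$freq[sel][which.max(psd2$power[sel])]
  expect_gte(peak, 4.5)
  expect_lte(peak, 5.5)
})

test_that("tremor-band power grows with injected tremor power", {
  grid <- c(0, 0.25, 0.5, 1, 2)
  bp <- vapply(grid, function(tp) {
    mean(vapply(1:20, function(s) {
      st <- synth_imu(imu_params(tremor_power = tp, duration_s = 4,
                                 gyr_rate = 400), seed = s)
      band_power(welch_psd(st$acc$x, 1100, 2048), 3, 7)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(bp) >= 0))
})

test_that("dataset writing round-trips signals and the manifest", {
  spec <- cohort_spec(n_pd = 1, n_hc = 1, tasks = "T06",
                      duration_range_s = c(2, 3), seed = 9)
  ch <- make_cohort_manifest(spec)
  dir <- withr::local_tempdir()
  man <- write_dataset(ch, dir, dialect = "seconds", bits = 16)
  expect_equal(nrow(utils::read.csv(file.path(dir, "manifest.csv"))), 2)

  w_orig <- synth_speech(ch$params[[1]]$speech,
                         seed = parkfuse:::derive_seed(ch$params[[1]]$seed, 10))
  w_read <- read_wav(man$wav_path[1])
  expect_lte(max(abs(w_orig - w_read$samples[, 1])), 1 / 32767)

  dir2 <- withr::local_tempdir()
  man2 <- write_dataset(ch, dir2, dialect = "ticks")
  tab <- utils::read.csv(man2$acc_path[1])
  expect_named(tab, c("ticks", "x", "y", "z"))
  i1s <- which.min(abs(tab$ticks - 1e7))
  expect_equal(tab$ticks[i1s], 1e7, tolerance = 1e-7)
  parsed <- load_imu_table(man2$acc_path[1])
  expect_equal(parsed$timestamp[i1s], 1, tolerance = 1e-6)
})

test_that("completeness summary reproduces the published cohort fraction", {
  records <- published_inventory_records()
  s <- summarize_completeness(records)
  expect_equal(sum(s$table$sessions), 822)
  expect_equal(sum(s$table$complete), 386)
  expect_equal(round(s$complete_fraction_pct), 47)

  all_complete <- records[!is.na(records$wav_path) & !is.na(records$acc_path) &
                            !is.na(records$gyr_path), ]
  expect_equal(summarize_completeness(all_complete)$complete_fraction_pct, 100)

  no_gyro <- records
  no_gyro$gyr_path <- NA
  expect_equal(sum(summarize_completeness(no_gyro)$table$complete), 0)
})
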