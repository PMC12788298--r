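# Signal front end: audio loading, log-mel extraction, IMU parsing and
# resampling, normalization, mel-grid alignment, and windowing.

test_that("WAV round trip preserves samples within quantization", {
  x <- sin(2 * pi * 440 * (0:15999) / 16000) * 0.8
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f, rate = 16000, bits = 16)
  w <- read_wav(f)
  expect_equal(w$rate, 16000)
  expect_lte(max(abs(w$samples[, 1] - x)), 1 / 32767)

  write_wav(x, f, rate = 16000, bits = 32)
  expect_lte(max(abs(read_wav(f)$samples[, 1] - x)), 1e-7)
})

test_that("audio loading averages channels, resamples, and normalizes", {
  f <- withr::local_tempfile(fileext = ".wav")
  # opposite-phase stereo cancels to silence without a normalization blow-up
  st <- cbind(rep(0.5, 8000), rep(-0.5, 8000))
  write_wav(st, f, rate = 16000, bits = 32)
  a <- load_audio(f)
  expect_true(all(a$samples == 0))

  # 48 kHz, 3 s in -> 48,000 samples out at 16 kHz
  x48 <- sin(2 * pi * 440 * (0:(3 * 48000 - 1)) / 48000)
  write_wav(x48, f, rate = 48000, bits = 32)
  a48 <- load_audio(f)
  expect_length(a48$samples, 48000)

  write_wav(0.25 * sin(2 * pi * 100 * (0:7999) / 16000), f,
            rate = 16000, bits = 32)
  expect_equal(max(abs(load_audio(f)$samples)), 1)
})

test_that("log-mel has exact frame counts, floor, and tone localization", {
  x <- stats::rnorm(240000) / 10
  m <- compute_logmel(x / max(abs(x)))
  expect_equal(nrow(m$values), 750)
  expect_equal(ncol(m$values), 56)
  expect_equal(m$frame_times[2] - m$frame_times[1], 320 / 16000)

  z <- compute_logmel(rep(0, 16000))
  expect_true(all(abs(z$values - log(1e-10)) < 1e-12))

  tone <- sin(2 * pi * 1000 * (0:31999) / 16000)
  mt <- compute_logmel(tone)
  peaks <- apply(mt$values[10:90, ], 1, which.max)
  expect_equal(length(unique(peaks)), 1)
  # the winning filter's center frequency brackets 1 kHz
  fb <- mel_filterbank()
  centers <- (0:512) * 16000 / 1024
  ctr <- centers[which.max(fb[, unique(peaks)])]
  expect_lt(abs(ctr - 1000), 150)

  expect_error(compute_logmel(rep(0, 100)), "shorter than one hop")
})

test_that("IMU CSV parsing handles dialects, gaps, and errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z", "0,1,2,3", "0.5,4,5,6", "1,7,8,9"), f)
  tab <- load_imu_table(f)
  expect_equal(tab$timestamp, c(0, 0.5, 1))
  expect_equal(tab$x, c(1, 4, 7))

  writeLines(c("ticks,ax,ay,az", "0,1,1,1", "10000000,2,2,2"), f)
  tab2 <- load_imu_table(f)
  expect_equal(tab2$timestamp, c(0, 1))

  writeLines(c("t,x,y,z", "5,1,2,3", "6,4,5,6"), f)
  expect_equal(load_imu_table(f)$timestamp, c(0, 1))  # re-based

  writeLines(c("timestamp,x,y,z", "0,1,2,3", "0.5,,5,6", "1,7,8,9"), f)
  expect_equal(load_imu_table(f)$x, c(1, 1, 7))  # forward fill
  writeLines(c("timestamp,x,y,z", "0,,2,3", "0.5,4,5,6"), f)
  expect_equal(load_imu_table(f)$x, c(4, 4))  # back fill at the head

  writeLines(c("a,b,c,d", "0,1,2,3"), f)
  expect_error(load_imu_table(f), "time-like")
  writeLines(c("timestamp,x", "0,1"), f)
  expect_error(load_imu_table(f), "axis columns")
})

test_that("100 Hz resampling stacks six channels on a common grid", {
  t_acc <- (0:16499) / 1100
  t_gyr <- (0:56999) / 3800
  acc <- data.frame(timestamp = t_acc, x = 2 * t_acc, y = 1, z = 0)
  gyr <- data.frame(timestamp = t_gyr, x = 0, y = -1, z = 3 * t_gyr)
  s <- to_100hz_six_channel(acc, gyr)
  expect_equal(nrow(s$values), 1500)          # 15 s window at 100 Hz
  expect_equal(ncol(s$values), 6)
  expect_equal(s$rate, 100)
  expect_true(all(abs(diff(s$times) - 0.01) < 1e-12))
  expect_true(all(s$values[, "acc_y"] == 1))  # constant stays constant
  expect_lt(max(abs(s$values[, "acc_x"] - 2 * s$times)), 1e-9)  # ramp exact
  expect_lt(max(abs(s$values[, "gyr_z"] - 3 * s$times)), 1e-9)

  expect_error(to_100hz_six_channel(acc[1, ], gyr), ">= 2 samples")
})

test_that("channel normalization centers medians with a guarded SD", {
  set.seed(1)
  acc <- data.frame(timestamp = (0:9999) / 1000, x = rnorm(10000, 5, 2),
                    y = 7, z = rnorm(10000))
  gyr <- data.frame(timestamp = (0:9999) / 1000, x = rnorm(10000),
                    y = rnorm(10000), z = rnorm(10000))
  s <- normalize_channels(to_100hz_six_channel(acc, gyr))
  meds <- apply(s$values, 2, median)
  expect_true(all(abs(meds) < 1e-10))
  expect_true(all(s$values[, "acc_y"] == 0))  # constant channel -> zeros
  sd_x <- sd(s$values[, "acc_x"])
  expect_gt(sd_x, 0.9)
  expect_lt(sd_x, 1.1)

  # idempotence: renormalizing an already normalized stream barely moves it
  s2 <- normalize_channels(s)
  expect_lt(max(abs(s2$values[, "acc_x"] - s$values[, "acc_x"])), 0.05)
})

test_that("large-sample normalized SD is close to one", {
  set.seed(2)
  n <- 10000
  acc <- data.frame(timestamp = (0:(n - 1)) / 1000, x = rnorm(n),
                    y = rnorm(n), z = rnorm(n))
  s <- normalize_channels(to_100hz_six_channel(acc, acc))
  expect_gt(sd(s$values[, 1]), 0.97)
  expect_lt(sd(s$values[, 1]), 1.03)
})

test_that("mel-grid alignment interpolates linearly and clamps edges", {
  acc <- data.frame(timestamp = (0:999) / 100, x = 4 * (0:999) / 100,
                    y = 0, z = 0)
  s <- to_100hz_six_channel(acc, acc)
  # knots reproduce exactly
  v <- align_to_mel_grid(s, s$times[1:50])
  expect_equal(v[, 1], s$values[1:50, 1])
  # analytic ramp at a 0.02 s grid
  ft <- seq(0, 5, by = 0.02)
  v2 <- align_to_mel_grid(s, ft)
  expect_lt(max(abs(v2[, 1] - 4 * ft)), 1e-9)
  # clamping beyond the support
  v3 <- align_to_mel_grid(s, c(100, 200))
  expect_equal(v3[1, 1], v3[2, 1])
  expect_equal(v3[1, 1], s$values[nrow(s$values), 1])
})

test_that("crops respect the overlap rule and the frame-rate constant", {
  mk_mel <- function(secs) structure(list(
    values = matrix(0, secs * 50, 56),
    frame_times = (0:(secs * 50 - 1)) / 50), class = "mel_sequence")
  mk_imu <- function(secs) structure(list(
    values = matrix(rnorm(secs * 100 * 6), secs * 100, 6),
    times = (0:(secs * 100 - 1)) / 100, rate = 100L), class = "imu_stream")

  tr <- make_crops(mk_mel(20), mk_imu(20), "train", seed = 1)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$T, 750)
  expect_equal(nrow(tr[[1]]$X_i), 750)

  # 12 s audio against 20 s IMU: min-overlap rule gives 600 frames
  cr <- make_crops(mk_mel(12), mk_imu(20), "train", seed = 1)
  expect_equal(cr[[1]]$T, 600)

  # short episode: all test crops identical
  te <- make_crops(mk_mel(10), mk_imu(10), "test", K = 3, seed = 2)
  expect_length(te, 3)
  expect_identical(te[[1]], te[[2]])
  expect_identical(te[[2]], te[[3]])

  # seed determinism and alignment consistency
  a <- make_crops(mk_mel(30), mk_imu(30), "test", K = 3, seed = 9)
  b <- make_crops(mk_mel(30), mk_imu(30), "test", K = 3, seed = 9)
  expect_identical(lapply(a, `[[`, "crop_start"),
                   lapply(b, `[[`, "crop_start"))
  for (cr in a) {
    expect_equal(nrow(cr$X_a), nrow(cr$X_i))
    expect_equal(cr$T, round(50 * 15))
  }

  expect_error(make_crops(NULL, NULL), "at least one modality")
})
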