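# IMU front end: heuristic CSV parsing, resampling to a uniform 100 Hz
# six-channel stream, per-episode normalization, and interpolation onto
# the mel frame grid.

IMU_RATE <- 100L
TICKS_PER_SECOND <- 1e7  # 100 ns ticks

#' Load a raw timestamped 3-axis IMU table
#'
#' The time column is the first header matching `time`, `timestamp`,
#' `ticks`, or `t` case-insensitively; tick timestamps (100 ns units) are
#' converted to seconds. The axis columns are the first three remaining
#' numeric columns in file order. Missing samples are forward-filled then
#' back-filled, and time is re-based to start at 0.
#'
#' @param path Path to a CSV file with a header row.
#' @return data.frame with columns `timestamp` (seconds from 0), `x`, `y`,
#'   `z`.
#' @export
load_imu_table <- function(path) {
  stop_if(!file.exists(path), paste("file not found:", path))
  tab <- as.data.frame(data.table::fread(path, check.names = FALSE,
                                         showProgress = FALSE))
  names_lc <- tolower(names(tab))
  time_idx <- which(names_lc %in% c("time", "timestamp", "ticks", "t"))[1]
  stop_if(is.na(time_idx), "no time-like column (time/timestamp/ticks/t)")

  tt <- as.numeric(tab[[time_idx]])
  if (names_lc[time_idx] == "ticks") tt <- tt / TICKS_PER_SECOND

  rest <- setdiff(seq_along(tab), time_idx)
  numeric_rest <- rest[vapply(tab[rest], is.numeric, logical(1))]
  stop_if(length(numeric_rest) < 3, "fewer than 3 numeric axis columns")
  axes <- tab[numeric_rest[1:3]]

  fill <- function(v) {
    if (anyNA(v)) {
      idx <- seq_along(v)
      ok <- !is.na(v)
      stop_if(!any(ok), "axis column entirely missing")
      # forward fill then back fill
      last <- cummax(ifelse(ok, idx, 0L))
      v <- ifelse(last > 0, v[pmax(last, 1L)], NA)
      if (anyNA(v)) v[is.na(v)] <- v[which(!is.na(v))[1]]
    }
    v
  }
  out <- data.frame(timestamp = tt - tt[1],
                    x = fill(as.numeric(axes[[1]])),
                    y = fill(as.numeric(axes[[2]])),
                    z = fill(as.numeric(axes[[3]])))
  stop_if(any(diff(out$timestamp) < 0), "non-monotone time after rebase")
  out
}

#' Resample accelerometer + gyroscope tables to a 100 Hz six-channel stream
#'
#' Each stream is independently linearly interpolated onto a uniform 100 Hz
#' grid from 0 to its last timestamp; the two grids are truncated to their
#' common length and stacked with accelerometer channels first. The result
#' is not yet normalized (see [normalize_channels()]).
#'
#' @param acc_table,gyr_table Output of [load_imu_table()] (>= 2 samples).
#' @return Object of class `imu_stream`: `values` (T x 6 matrix, columns
#'   ACC x/y/z then GYR x/y/z), `times` (seconds from 0, 10 ms spacing),
#'   `rate` (100).
#' @export
to_100hz_six_channel <- function(acc_table, gyr_table) {
  interp_stream <- function(tab) {
    stop_if(is.null(tab) || nrow(tab) < 2, "IMU table needs >= 2 samples")
    grid <- seq(0, tab$timestamp[nrow(tab)], by = 1 / IMU_RATE)
    vapply(c("x", "y", "z"), function(ch)
      stats::approx(tab$timestamp, tab[[ch]], xout = grid, rule = 2)$y,
      numeric(length(grid)))
  }
  acc <- interp_stream(acc_table)
  gyr <- interp_stream(gyr_table)
  t_common <- min(nrow(acc), nrow(gyr))
  values <- cbind(acc[1:t_common, , drop = FALSE],
                  gyr[1:t_common, , drop = FALSE])
  colnames(values) <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  structure(list(values = values,
                 times = (0:(t_common - 1)) / IMU_RATE,
                 rate = IMU_RATE),
            class = "imu_stream")
}

#' Median-center and standardize each IMU channel
#'
#' Statistics are computed over the full episode (so train and test crops
#' of one episode share scaling); the standard deviation has a 1e-6 floor
#' so constant channels map to all zeros instead of blowing up.
#'
#' @param stream An `imu_stream`.
#' @return The normalized `imu_stream`.
#' @export
normalize_channels <- function(stream) {
  v <- stream$values
  med <- apply(v, 2, stats::median)
  sds <- pmax(apply(v, 2, stats::sd), 1e-6)
  stream$values <- sweep(sweep(v, 2, med), 2, sds, "/")
  stream
}

#' Interpolate an IMU stream onto mel-frame timestamps
#'
#' Linear interpolation per channel; query times beyond the stream's
#' support are clamped to the edge values.
#'
#' @param stream An `imu_stream`.
#' @param frame_times Nondecreasing numeric vector of query times (s).
#' @return `length(frame_times)` x 6 matrix.
#' @export
align_to_mel_grid <- function(stream, frame_times) {
  stop_if(length(stream$times) == 0, "empty IMU stream")
  stop_if(is.unsorted(frame_times), "frame_times must be nondecreasing")
  out <- apply(stream$values, 2, function(ch)
    stats::approx(stream$times, ch, xout = frame_times, rule = 2)$y)
  matrix(out, nrow = length(frame_times),
         dimnames = list(NULL, colnames(stream$values)))
}
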