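# Pre-processing and sensor fusion for a single-arm recording.
#
# A "recording" is a tibble with a `time` column (seconds, uniform grid)
# and sensor columns `ax, ay, az` (g), `gx, gy, gz` (deg/s) and optionally
# `mx, my, mz` (arbitrary units).

sampling_rate <- function(time) {
  if (length(time) < 2L) abort("need at least two samples to infer a rate")
  dt <- median(diff(time))
  if (!is.finite(dt) || dt <= 0) abort("timestamps must be strictly increasing")
  1 / dt
}

#' Detect rest periods from gyroscope data
#'
#' A rest period is a run of at least `min_duration` seconds over which the
#' gyroscope variance on every axis stays below `variance_threshold`.  The
#' record is scanned in non-overlapping 1 s blocks; runs of consecutive
#' quiet blocks of sufficient total length become rest intervals.
#'
#' @param data recording tibble with `time` and `gx, gy, gz` in deg/s on a
#'   uniform grid.
#' @param min_duration minimum rest length in seconds (default 10).
#' @param variance_threshold per-axis sample-variance threshold in
#'   (deg/s)^2 (default 0.15).
#' @return tibble with columns `start`, `end` (seconds), non-overlapping and
#'   sorted; zero rows when no rest is found.
#' @export
detect_rest_periods <- function(data, min_duration = 10,
                                variance_threshold = 0.15) {
  rate <- sampling_rate(data$time)
  block <- max(1L, round(rate))  # 1 s blocks
  n <- nrow(data)
  n_blocks <- floor(n / block)
  if (n_blocks * 1 < min_duration) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  g <- as.matrix(data[, c("gx", "gy", "gz")])
  quiet <- vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * block + 1L):(b * block)
    all(apply(g[idx, , drop = FALSE], 2, var) < variance_threshold)
  }, logical(1))
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * block / rate) >= min_duration
  tibble::tibble(
    start = data$time[(starts[keep] - 1L) * block + 1L],
    end = data$time[pmin(n, ends[keep] * block)]
  )
}

#' Correct a constant gyroscope offset using rest periods
#'
#' For each rest interval the per-axis mean angular velocity over the
#' interval is taken as the offset and subtracted from all samples from the
#' interval's start up to (but not including) the next interval's start, or
#' the end of the record.  Samples before the first rest interval are left
#' unchanged.  With no rest intervals the data are returned as-is.
#'
#' @param data recording tibble with `time` and `gx, gy, gz`.
#' @param rest tibble of rest intervals as returned by
#'   [detect_rest_periods()].
#' @return the recording with de-biased gyroscope columns.
#' @export
correct_gyro_offset <- function(data, rest) {
  if (is.null(rest) || nrow(rest) == 0L) return(data)
  rest <- dplyr::arrange(rest, .data$start)
  axes <- c("gx", "gy", "gz")
  out <- data
  for (k in seq_len(nrow(rest))) {
    in_rest <- data$time >= rest$start[k] & data$time <= rest$end[k]
    seg_end <- if (k < nrow(rest)) rest$start[k + 1L] else Inf
    seg <- data$time >= rest$start[k] & data$time < seg_end
    for (ax in axes) {
      offset <- mean(data[[ax]][in_rest])
      out[[ax]][seg] <- out[[ax]][seg] - offset
    }
  }
  out
}

#' Median-filter accelerometer data
#'
#' Fifth-order (5-sample) running median applied per axis to suppress sharp
#' jumps and outliers.  Edges use a shrinking window; non-finite samples are
#' ignored within each window.
#'
#' @param data recording tibble with `ax, ay, az`.
#' @param order window length in samples (odd, default 5).
#' @return the recording with filtered accelerometer columns.
#' @export
median_filter_accel <- function(data, order = 5L) {
  out <- data
  for (ax in c("ax", "ay", "az")) {
    out[[ax]] <- zoo::rollapply(
      data[[ax]], width = order,
      FUN = function(v) {
        v <- v[is.finite(v)]
        if (length(v) == 0L) NA_real_ else median(v)
      },
      partial = TRUE, align = "center"
    )
  }
  out
}

#' Estimate forearm orientation by sensor fusion
#'
#' Runs a Madgwick (gradient-descent) or Mahony (explicit complementary)
#' filter over the recording and extracts yaw and pitch.  With magnetometer
#' columns present (and `use_mag = TRUE`) the 9-DOF update is used,
#' otherwise the 6-DOF (accelerometer + gyroscope) update.  The quaternion
#' is initialised from the first finite accelerometer sample (tilt only).
#'
#' @param data recording tibble (`time`, `ax..az` in g, `gx..gz` in deg/s,
#'   optionally `mx..mz`).
#' @param algorithm `"madgwick"` or `"mahony"`.
#' @param use_mag use the magnetometer if available.  Defaults to `TRUE`
#'   for Mahony and `FALSE` for Madgwick, mirroring the 9-DOF activity-count
#'   pipeline and the 6-DOF gross-movement pipeline respectively.
#' @param beta Madgwick filter gain (default 0.1).
#' @param kp,ki Mahony proportional and integral gains (defaults 1 and 0.3).
#' @return a tibble with columns `time`, `qw, qx, qy, qz` (unit quaternions,
#'   body to earth), and `yaw`, `pitch`, `roll` in degrees.
#' @export
estimate_orientation <- function(data, algorithm = c("madgwick", "mahony"),
                                 use_mag = NULL, beta = 0.1,
                                 kp = 1, ki = 0.3) {
  algorithm <- match.arg(algorithm)
  rate <- sampling_rate(data$time)
  acc <- as.matrix(data[, c("ax", "ay", "az")])
  gyr <- as.matrix(data[, c("gx", "gy", "gz")]) * pi / 180
  if (nrow(acc) != nrow(gyr)) abort("sensor columns must share length")
  has_mag <- all(c("mx", "my", "mz") %in% names(data)) &&
    any(is.finite(data$mx))
  if (is.null(use_mag)) use_mag <- (algorithm == "mahony") && has_mag
  mag <- NULL
  if (use_mag) {
    if (!has_mag) abort("9-DOF fusion requested but magnetometer columns (mx, my, mz) are missing")
    mag <- as.matrix(data[, c("mx", "my", "mz")])
  }
  first_ok <- which(apply(is.finite(acc), 1, all))[1]
  q0 <- if (is.na(first_ok)) c(1, 0, 0, 0) else tilt_quaternion(acc[first_ok, ])
  q <- fusion_filter_cpp(acc, gyr, mag, rate, algorithm, beta, kp, ki, q0)
  eul <- quat_to_euler(q)
  tibble::tibble(
    time = data$time,
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
    yaw = eul$yaw, pitch = eul$pitch, roll = eul$roll
  )
}

#' Remove gravity from accelerometer data
#'
#' Rotates each accelerometer sample into the earth frame using the fused
#' orientation and subtracts the 1 g vertical, leaving earth-frame linear
#' (movement) acceleration.
#'
#' @param data recording tibble with `ax, ay, az` in g.
#' @param orientation orientation tibble from [estimate_orientation()],
#'   aligned sample-wise with `data`.
#' @return a tibble with `time` and earth-frame linear acceleration
#'   `lx, ly, lz` in g.
#' @export
gravity_subtract <- function(data, orientation) {
  if (nrow(data) != nrow(orientation)) {
    abort("recording and orientation must be aligned sample-wise")
  }
  acc <- as.matrix(data[, c("ax", "ay", "az")])
  q <- as.matrix(orientation[, c("qw", "qx", "qy", "qz")])
  earth <- quat_rotate(q, acc)
  tibble::tibble(
    time = data$time,
    lx = earth[, 1], ly = earth[, 2], lz = earth[, 3] - 1
  )
}
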