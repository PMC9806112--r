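# Dataset schema, CSV reader/writer, zero-order-hold resampling, and
# ground-truth consensus.
#
# The on-disk dataset is a single CSV, one row per 50 Hz timestamp, with
# columns: subject, group, arm, time, ax, ay, az, gx, gy, gz, mx, my, mz,
# use_a1p1, use_a1p2, use_a2p1, use_a2p2, task, movement_type.
# Accelerometer in g, gyroscope in deg/s, magnetometer in arbitrary units;
# the four `use_*` columns are the two annotators' two passes (binary),
# already zero-order-hold upsampled from 30 Hz to the sensor grid.

dataset_sensor_cols <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
dataset_use_cols <- c("use_a1p1", "use_a1p2", "use_a2p1", "use_a2p2")
dataset_cols <- c("subject", "group", "arm", "time",
                  dataset_sensor_cols, dataset_use_cols,
                  "task", "movement_type")

#' Validate an IMU dataset table
#'
#' Checks the documented schema: all mandatory columns present, timestamps
#' strictly increasing within each subject and arm, annotation tracks
#' binary.  Non-finite sensor samples are allowed (they are handled by the
#' median filter and zero-order-hold resampling downstream).
#'
#' @param data a dataset tibble.
#' @return the data, invisibly, on success; otherwise an error.
#' @export
validate_imu_dataset <- function(data) {
  missing <- setdiff(dataset_cols, names(data))
  if (length(missing) > 0L) {
    abort(paste0("dataset is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "limbuse_schema_error")
  }
  bad_time <- data %>%
    dplyr::group_by(.data$subject, .data$arm) %>%
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop")
  if (!all(bad_time$ok)) {
    abort("timestamps must be strictly increasing within each subject and arm",
          class = "limbuse_validation_error")
  }
  for (col in dataset_use_cols) {
    v <- data[[col]]
    if (!all(v %in% c(0L, 1L))) {
      abort(paste0("annotation column ", col, " must be binary (0/1)"),
            class = "limbuse_validation_error")
    }
  }
  invisible(data)
}

#' Read an IMU dataset from CSV
#'
#' @param path path to a CSV file in the documented schema.
#' @return a validated dataset tibble; sensor columns are numeric,
#'   annotation columns integer.
#' @export
read_imu_dataset <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      group = readr::col_character(),
      arm = readr::col_character(),
      time = readr::col_double(),
      task = readr::col_character(),
      movement_type = readr::col_character(),
      use_a1p1 = readr::col_integer(),
      use_a1p2 = readr::col_integer(),
      use_a2p1 = readr::col_integer(),
      use_a2p2 = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_imu_dataset(data)
  data
}

#' Write an IMU dataset to CSV
#'
#' @param data a dataset tibble in the documented schema.
#' @param path output path.
#' @return the input data, invisibly.
#' @export
write_imu_dataset <- function(data, path) {
  validate_imu_dataset(data)
  readr::write_csv(data[, dataset_cols], path, progress = FALSE)
  invisible(data)
}

#' Split a dataset into per-arm recordings
#'
#' @param data a dataset tibble.
#' @return a tibble with one row per (subject, group, arm) and a
#'   list-column `recording` holding each arm's time series.
#' @export
dataset_arms <- function(data) {
  data %>%
    dplyr::group_by(.data$subject, .data$group, .data$arm) %>%
    tidyr::nest(recording = -c("subject", "group", "arm")) %>%
    dplyr::ungroup()
}

#' Zero-order-hold resampling onto a uniform grid
#'
#' Resamples every non-time column of `data` onto a uniform grid at
#' `target_rate` spanning the input time range.  Each output sample equals
#' the most recent input sample at or before its timestamp, so the output
#' never contains values absent from the input (no interpolation).  The
#' grid origin is the first input timestamp.
#'
#' @param data tibble with a `time` column (strictly increasing) and any
#'   number of value columns.
#' @param target_rate output rate in Hz.
#' @return a tibble on the uniform grid.
#' @export
resample_zoh <- function(data, target_rate) {
  if (nrow(data) == 0L) abort("cannot resample an empty series")
  if (any(diff(data$time) <= 0)) abort("timestamps must be strictly increasing")
  t0 <- data$time[1]
  span <- data$time[nrow(data)] - t0
  grid <- t0 + seq(0, floor(span * target_rate + 1e-9)) / target_rate
  # tolerate floating-point jitter so grid points that nominally coincide
  # with input samples pick those samples, not their predecessors
  idx <- findInterval(grid + 1e-6 / target_rate, data$time)
  out <- data[idx, , drop = FALSE]
  out$time <- grid
  tibble::as_tibble(out)
}

#' Majority-vote consensus of four annotation tracks
#'
#' Combines the four binary functional-use tracks (two annotators, two
#' passes each) into a single ground-truth label by majority vote; a 2-2
#' tie is labelled non-functional (0).
#'
#' @param a1p1,a1p2,a2p1,a2p2 binary vectors of equal length.
#' @return an integer vector of consensus labels in \{0, 1\}.
#' @export
consensus_label <- function(a1p1, a1p2, a2p1, a2p2) {
  labs <- cbind(a1p1, a1p2, a2p1, a2p2)
  if (!all(labs %in% c(0, 1))) abort("annotation labels must be binary (0/1)")
  as.integer(rowSums(labs) >= 3)
}

#' Consensus ground truth for one arm's recording
#'
#' @param recording an arm's rows of the dataset (with the four `use_*`
#'   columns on the sensor grid).
#' @return tibble with `time` and the consensus binary `label`.
#' @export
consensus_ground_truth <- function(recording) {
  tibble::tibble(
    time = recording$time,
    label = consensus_label(recording$use_a1p1, recording$use_a1p2,
                            recording$use_a2p1, recording$use_a2p2)
  )
}
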