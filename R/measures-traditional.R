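# The four non-machine-learning upper-limb-use measures.
#
# All counts signals are emitted on a uniform 1 Hz grid anchored at the
# recording's first timestamp; the gross-movement score is emitted at 2 Hz
# (2 s windows, 0.5 s hop).  Band-pass filtering is zero-phase
# (forward-backward Butterworth), appropriate for offline analysis where
# the detector output must stay aligned with the annotations.

#' Dead-band filter
#'
#' Zeroes samples whose magnitude does not exceed the threshold.
#'
#' @param x numeric vector (g).
#' @param threshold dead-band half-width (default 0.068 g).
#' @return the filtered vector.
#' @export
deadband <- function(x, threshold = 0.068) {
  ifelse(abs(x) <= threshold, 0, x)
}

#' Quantize acceleration magnitudes into integer counts
#'
#' @param x non-negative magnitudes (g).
#' @param step quantization step (default 0.017 g).
#' @return integer counts, `floor(x / step)`.
#' @export
quantize_counts <- function(x, step = 0.017) {
  if (any(x < 0, na.rm = TRUE)) abort("magnitudes must be non-negative")
  as.integer(floor(x / step))
}

# Zero-phase band-pass, 0.25-2.5 Hz.  `order` is the analogue prototype
# order; the resulting band-pass has twice as many poles.
bandpass_025_25 <- function(x, rate, order = 2L) {
  bf <- signal::butter(order, c(0.25, 2.5) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Sum (or mean) over non-overlapping 1 s bins anchored at the first
# timestamp; returns a tibble with bin-end timestamps at exactly 1 Hz.
bin_1s <- function(time, x, fun = sum) {
  rate <- sampling_rate(time)
  per <- round(rate)
  n_bins <- floor(length(x) / per)
  if (n_bins < 1L) abort("record shorter than one 1 s bin")
  idx <- rep(seq_len(n_bins), each = per)
  vals <- vapply(split(x[seq_len(n_bins * per)], idx), fun, numeric(1))
  tibble::tibble(time = time[1] + seq_len(n_bins), value = unname(vals))
}

#' Vector-magnitude activity counts
#'
#' Implements the vector-magnitude counting pipeline: resample the
#' accelerometer to 30 Hz (zero-order hold), remove gravity using 6-DOF
#' Madgwick fusion, band-pass each axis 0.25-2.5 Hz (4th-order zero-phase
#' Butterworth), resample to 10 Hz, dead-band at ±0.068 g, sum each axis
#' over non-overlapping 1 s bins, take the 2-norm across axes, and smooth
#' with a 5 s moving average with 4 s overlap, yielding counts at 1 Hz.
#'
#' @param recording arm recording tibble (`time`, `ax..az`, `gx..gz`).
#' @param deadband_threshold dead-band half-width in g.
#' @param ma_window moving-average window in seconds.
#' @param beta Madgwick gain for the gravity-direction estimate.
#' @return tibble `time`, `counts` at 1 Hz (non-negative reals).
#' @export
vector_magnitude_counts <- function(recording, deadband_threshold = 0.068,
                                    ma_window = 5, beta = 0.1) {
  if (nrow(recording) < 2L ||
      (recording$time[nrow(recording)] - recording$time[1]) < ma_window + 1) {
    abort("record shorter than one moving-average window")
  }
  r30 <- resample_zoh(recording, 30)
  orient <- estimate_orientation(r30, algorithm = "madgwick",
                                 use_mag = FALSE, beta = beta)
  lin <- gravity_subtract(r30, orient)
  for (col in c("lx", "ly", "lz")) {
    lin[[col]] <- bandpass_025_25(lin[[col]], 30)
  }
  l10 <- resample_zoh(lin, 10)
  for (col in c("lx", "ly", "lz")) {
    l10[[col]] <- deadband(l10[[col]], deadband_threshold)
  }
  bx <- bin_1s(l10$time, l10$lx)
  by <- bin_1s(l10$time, l10$ly)
  bz <- bin_1s(l10$time, l10$lz)
  norm1 <- sqrt(bx$value^2 + by$value^2 + bz$value^2)
  # moving average: 5 s window, 1 s hop, stamped at the window end
  w <- round(ma_window)
  if (length(norm1) < w) abort("record shorter than one moving-average window")
  counts <- zoo::rollmean(norm1, w, align = "right")
  tibble::tibble(time = bx$time[seq(w, length(norm1))], counts = counts)
}

#' Binary use from vector-magnitude counts
#'
#' @param counts tibble `time`, `counts` from [vector_magnitude_counts()].
#' @return tibble `time`, `use` (1 where counts exceed zero).
#' @export
vm_use <- function(counts) {
  tibble::tibble(time = counts$time, use = as.integer(counts$counts > 0))
}

#' Quantized activity counts
#'
#' Implements the activity-counting pipeline: remove gravity using 9-DOF
#' Mahony fusion, take the magnitude of the linear acceleration, band-pass
#' it 0.25-2.5 Hz (4th-order zero-phase Butterworth), average the rectified
#' magnitudes over non-overlapping 1 s bins, and quantize by 0.017 g into
#' integer counts at 1 Hz.
#'
#' @param recording arm recording tibble; magnetometer columns are required
#'   for the 9-DOF fusion.
#' @param step quantization step in g.
#' @param kp,ki Mahony gains.
#' @return tibble `time`, `counts` at 1 Hz (non-negative integers).
#' @export
activity_counts <- function(recording, step = 0.017, kp = 1, ki = 0.3) {
  if (!all(c("mx", "my", "mz") %in% names(recording))) {
    abort("activity counts require 9-DOF data: magnetometer columns (mx, my, mz) are missing")
  }
  orient <- estimate_orientation(recording, algorithm = "mahony",
                                 use_mag = TRUE, kp = kp, ki = ki)
  lin <- gravity_subtract(recording, orient)
  mag <- sqrt(lin$lx^2 + lin$ly^2 + lin$lz^2)
  rate <- sampling_rate(recording$time)
  filt <- bandpass_025_25(mag, rate)
  bins <- bin_1s(recording$time, abs(filt), fun = mean)
  tibble::tibble(time = bins$time, counts = quantize_counts(bins$value, step))
}

#' Laterality index and per-arm use from bilateral activity counts
#'
#' Computes the laterality index LI = (dominant - non-dominant) /
#' (dominant + non-dominant) from the two arms' 1 Hz counts and thresholds
#' it: LI > -0.95 flags dominant (or unaffected) arm use, LI < 0.95 flags
#' non-dominant (or affected) arm use.  Seconds in which both arms have
#' zero counts have an undefined index and no use on either arm.
#'
#' @param counts_dom,counts_nondom tibbles `time`, `counts` on the same
#'   1 Hz grid.
#' @param threshold laterality threshold (default 0.95).
#' @return tibble `time`, `laterality`, `use_dominant`, `use_nondominant`.
#' @export
laterality_use <- function(counts_dom, counts_nondom, threshold = 0.95) {
  n <- min(nrow(counts_dom), nrow(counts_nondom))
  cd <- counts_dom[seq_len(n), ]
  cn <- counts_nondom[seq_len(n), ]
  if (!isTRUE(all.equal(cd$time, cn$time))) {
    abort("both arms' counts must share the same 1 Hz grid")
  }
  tot <- cd$counts + cn$counts
  li <- ifelse(tot > 0, (cd$counts - cn$counts) / tot, NA_real_)
  tibble::tibble(
    time = cd$time,
    laterality = li,
    use_dominant = as.integer(!is.na(li) & li > -threshold),
    use_nondominant = as.integer(!is.na(li) & li < threshold)
  )
}

#' Gross-movement (GM) score
#'
#' For 2 s windows with 75% overlap (0.5 s hop), the window is scored 1
#' when the summed yaw and pitch ranges exceed `angle_threshold` and the
#' window-mean pitch lies within ±`pitch_limit` (the "functional space"),
#' else 0.  Yaw is unwrapped before windowing so the range is not inflated
#' by ±180° wrapping.
#'
#' @param orientation tibble with `time`, `yaw`, `pitch` in degrees at the
#'   sensor rate.
#' @param window_s window length (s).
#' @param hop_s hop between windows (s).
#' @param angle_threshold threshold on the summed angular ranges (deg).
#' @param pitch_limit half-width of the functional pitch band (deg).
#' @return tibble `time` (window end), `use`, at `1 / hop_s` Hz.
#' @export
gm_use <- function(orientation, window_s = 2, hop_s = 0.5,
                   angle_threshold = 30, pitch_limit = 30) {
  rate <- sampling_rate(orientation$time)
  w <- round(window_s * rate)
  hop <- round(hop_s * rate)
  n <- nrow(orientation)
  if (n < w) abort("record shorter than one GM window")
  yaw <- unwrap_deg(orientation$yaw)
  pitch <- orientation$pitch
  starts <- seq(1L, n - w + 1L, by = hop)
  use <- vapply(starts, function(s) {
    i <- s:(s + w - 1L)
    dyaw <- diff(range(yaw[i]))
    dpitch <- diff(range(pitch[i]))
    as.integer((dyaw + dpitch) > angle_threshold &&
                 abs(mean(pitch[i])) < pitch_limit)
  }, integer(1))
  tibble::tibble(time = orientation$time[starts + w - 1L], use = use)
}

#' Hybrid GM and activity-counting (GMAC) score
#'
#' Per 1 s bin: use = 1 when the counts exceed zero and the bin-mean
#' forearm pitch lies within ±`pitch_limit`.
#'
#' @param counts tibble `time`, `counts` at 1 Hz (vector-magnitude counts).
#' @param pitch tibble with `time` and `pitch` (deg) covering the counts'
#'   span at any rate of at least 1 Hz.
#' @param pitch_limit half-width of the functional pitch band (deg).
#' @return tibble `time`, `use` at 1 Hz.
#' @export
gmac_use <- function(counts, pitch, pitch_limit = 30) {
  if (max(pitch$time) < min(counts$time) - 1 ||
      min(pitch$time) > max(counts$time)) {
    abort("pitch series does not cover the counts' span")
  }
  mean_pitch <- vapply(counts$time, function(tb) {
    sel <- pitch$time > tb - 1 - 1e-9 & pitch$time <= tb + 1e-9
    if (!any(sel)) NA_real_ else mean(pitch$pitch[sel])
  }, numeric(1))
  tibble::tibble(
    time = counts$time,
    use = as.integer(counts$counts > 0 & !is.na(mean_pitch) &
                       abs(mean_pitch) < pitch_limit)
  )
}
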