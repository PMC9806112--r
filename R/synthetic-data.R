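# Synthetic two-arm IMU data with frame-accurate ground truth.
#
# Each arm is scripted as a state machine over epochs:
#   FUNCTIONAL-ARM  -- goal-directed reaching in the functional space
#                      (forearm pitch within +/-30 deg), large yaw
#                      excursions and 0.1-0.5 g movement accelerations;
#   FUNCTIONAL-HAND -- in-place hand activity (writing, typing): forearm in
#                      the functional space but nearly still, with small
#                      intermittent accelerations;
#   GAIT            -- arm hanging (pitch around -75 deg) and swinging at
#                      about 1 Hz with pendular accelerations;
#   REST            -- static posture, at least 10 s, so rest detection and
#                      gyroscope offset correction are exercised.
#
# The scripted yaw/pitch profile (zero roll) is the orientation ground
# truth; body-frame angular rates are derived from it, the accelerometer
# reads specific force (gravity + movement acceleration) rotated into the
# body frame, and the magnetometer reads a fixed earth field in the body
# frame.  Annotations are the true use labels emitted at 30 Hz with
# independent symmetric flip noise per annotator-pass.

#' Simulation configuration
#'
#' @param duration recording length in seconds.
#' @param rate sensor rate in Hz.
#' @param ann_rate annotation (video) rate in Hz.
#' @param functional_share target fraction of time in functional epochs.
#' @param p_hand fraction of functional time that is hand-dominant.
#' @param gait_share fraction of non-functional epochs that are gait
#'   (the rest are static rest).
#' @param amplitude scale on movement accelerations and angular excursions
#'   (patients' affected arms use < 1).
#' @param accel_noise_sd accelerometer noise, g.
#' @param gyro_noise_sd gyroscope noise, deg/s.
#' @param gyro_offset constant per-axis gyroscope bias, deg/s.
#' @param mag_noise_sd magnetometer noise, arbitrary units.
#' @param annotator_flip probability that an annotator-pass flips a label.
#' @param arm_label one of `left`, `right`, `affected`, `unaffected`.
#' @param pitch_only plant the class difference only in forearm pitch:
#'   every epoch gets identical movement statistics and the classes differ
#'   solely in base pitch (functional in the functional space,
#'   non-functional hanging).  Used for interpretation experiments.
#' @param seed optional integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration = 180, rate = 50, ann_rate = 30,
                       functional_share = 0.6, p_hand = 0.4,
                       gait_share = 0.5, amplitude = 1,
                       accel_noise_sd = 0.01, gyro_noise_sd = 0.2,
                       gyro_offset = c(0.2, -0.1, 0.15),
                       mag_noise_sd = 0.02, annotator_flip = 0.02,
                       arm_label = "right", pitch_only = FALSE,
                       seed = NULL) {
  stopifnot(duration > 0, functional_share >= 0, functional_share < 1)
  structure(list(
    duration = duration, rate = rate, ann_rate = ann_rate,
    functional_share = functional_share, p_hand = p_hand,
    gait_share = gait_share, amplitude = amplitude,
    accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
    gyro_offset = gyro_offset, mag_noise_sd = mag_noise_sd,
    annotator_flip = annotator_flip, arm_label = arm_label,
    pitch_only = pitch_only, seed = seed
  ), class = "sim_config")
}

sim_tasks <- list(
  arm = c("drinkcup", "openbottle", "wipe", "eat"),
  hand = c("type", "write"),
  gait = "walk",
  rest = "rest"
)

# Greedy epoch scheduler steering the running functional share towards the
# target.  Non-functional movement epochs alternate gait and rest so both
# are always represented; functional epochs track the hand-dominant quota.
schedule_epochs <- function(config) {
  dur <- config$duration
  epochs <- list(list(type = "rest", dur = if (dur >= 48) 12 else min(10, dur)))
  f_time <- 0
  total <- epochs[[1]]$dur
  n_hand <- 0L; n_fun <- 0L; gait_next <- TRUE
  while (total < dur) {
    d_f <- runif(1, 8, 15)
    d_n <- runif(1, 10, 18)
    err_f <- abs((f_time + d_f) / (total + d_f) - config$functional_share)
    err_n <- abs(f_time / (total + d_n) - config$functional_share)
    if (err_f <= err_n) {
      type <- if (n_fun == 0L || n_hand / n_fun >= config$p_hand) "arm" else "hand"
      n_fun <- n_fun + 1L
      if (type == "hand") n_hand <- n_hand + 1L
      d <- min(d_f, dur - total)
      f_time <- f_time + d
      epochs <- c(epochs, list(list(type = type, dur = d)))
    } else {
      type <- if (gait_next && config$gait_share > 0) "gait" else "rest"
      gait_next <- !gait_next
      d <- min(d_n, dur - total)
      epochs <- c(epochs, list(list(type = type, dur = d)))
    }
    total <- total + d
  }
  achieved <- f_time / total
  # epoch granularity bounds how closely short records can hit the target
  tol <- max(0.1, 12 / dur)
  if (abs(achieved - config$functional_share) > tol) {
    abort(sprintf(
      "could not reach functional share %.2f (achieved %.2f) with this task mix",
      config$functional_share, achieved))
  }
  epochs
}

# Raised-cosine on/off ramp confined to an epoch, 0.5 s at each edge.
epoch_ramp <- function(n, rate) {
  k <- min(n %/% 2, round(0.5 * rate))
  r <- rep(1, n)
  if (k > 0) {
    edge <- 0.5 * (1 - cos(pi * seq_len(k) / k))
    r[seq_len(k)] <- edge
    r[n + 1 - seq_len(k)] <- rev(edge)
  }
  r
}

#' Simulate one arm's IMU recording with ground truth
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `recording` (50 Hz sensor tibble),
#'   `annotations` (30 Hz annotation tibble with four noisy use tracks,
#'   task and movement-type tracks), `truth` (per-sample true yaw, pitch,
#'   use label, task and movement type at the sensor rate) and `epochs`
#'   (the scheduled epoch table).
#' @export
simulate_arm <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  rate <- config$rate
  epochs <- schedule_epochs(config)
  n_tot <- round(config$duration * rate)
  time <- (seq_len(n_tot) - 1L) / rate

  base_pitch <- numeric(n_tot); base_yaw <- numeric(n_tot)
  osc_pitch <- numeric(n_tot); osc_yaw <- numeric(n_tot)
  acc_earth <- matrix(0, n_tot, 3)
  use <- integer(n_tot)
  task <- character(n_tot); mtype <- character(n_tot)
  epoch_rows <- list()

  amp <- config$amplitude
  prev_type <- ""; prev_bp <- 0; prev_by <- 0
  pos <- 0
  for (e in epochs) {
    i0 <- floor(pos * rate) + 1L
    i1 <- min(n_tot, floor((pos + e$dur) * rate))
    pos <- pos + e$dur
    if (i1 < i0) next
    idx <- i0:i1
    n <- length(idx)
    tl <- (seq_len(n) - 1L) / rate
    ramp <- epoch_ramp(n, rate)

    if (config$pitch_only) {
      bp <- if (e$type %in% c("arm", "hand")) runif(1, -20, 20) else runif(1, -85, -55)
      by <- runif(1, -60, 60)
      oy <- runif(1, 15, 25) * sin(2 * pi * runif(1, 0.4, 0.8) * tl + runif(1, 0, 2 * pi))
      op <- runif(1, 4, 8) * sin(2 * pi * runif(1, 0.4, 0.8) * tl + runif(1, 0, 2 * pi))
      for (ax in 1:3) {
        acc_earth[idx, ax] <- runif(1, 0.1, 0.3) *
          sin(2 * pi * runif(1, 0.5, 2) * tl + runif(1, 0, 2 * pi)) * ramp
      }
    } else if (e$type == "arm") {
      bp <- runif(1, -20, 20)
      by <- runif(1, -60, 60)
      oy <- amp * runif(1, 25, 45) * sin(2 * pi * runif(1, 0.3, 0.7) * tl + runif(1, 0, 2 * pi))
      op <- amp * runif(1, 5, 12) * sin(2 * pi * runif(1, 0.4, 0.8) * tl + runif(1, 0, 2 * pi))
      for (ax in 1:3) {
        acc_earth[idx, ax] <- amp * runif(1, 0.1, 0.5) *
          sin(2 * pi * runif(1, 0.5, 2) * tl + runif(1, 0, 2 * pi)) * ramp
      }
    } else if (e$type == "hand") {
      bp <- runif(1, -20, 20)
      by <- runif(1, -60, 60)
      oy <- amp * runif(1, 2, 6) * sin(2 * pi * runif(1, 0.5, 1.5) * tl + runif(1, 0, 2 * pi))
      op <- amp * runif(1, 1, 3) * sin(2 * pi * runif(1, 0.5, 1.5) * tl + runif(1, 0, 2 * pi))
      duty <- 0.5 * (1 + sign(sin(2 * pi * 0.25 * tl + runif(1, 0, 2 * pi))))
      for (ax in 1:3) {
        acc_earth[idx, ax] <- amp * runif(1, 0.05, 0.14) *
          sin(2 * pi * runif(1, 1, 2.5) * tl + runif(1, 0, 2 * pi)) * duty * ramp
      }
    } else if (e$type == "gait") {
      bp <- runif(1, -80, -70)
      by <- runif(1, -60, 60)
      f_gait <- runif(1, 0.85, 1.1)
      ph <- runif(1, 0, 2 * pi)
      op <- amp * runif(1, 10, 16) * sin(2 * pi * f_gait * tl + ph)
      oy <- amp * runif(1, 2, 5) * sin(2 * pi * f_gait * tl + runif(1, 0, 2 * pi))
      a_g <- amp * runif(1, 0.15, 0.35)
      acc_earth[idx, 1] <- a_g * sin(2 * pi * f_gait * tl + ph) * ramp
      acc_earth[idx, 3] <- 0.6 * a_g * sin(4 * pi * f_gait * tl + ph) * ramp
    } else {  # rest: hold the previous rest posture if resting back-to-back
      if (identical(prev_type, "rest")) {
        bp <- prev_bp; by <- prev_by
      } else {
        bp <- if (runif(1) < 0.5) runif(1, -15, 15) else runif(1, -80, -55)
        by <- runif(1, -60, 60)
      }
      oy <- 0; op <- 0
    }
    prev_type <- e$type; prev_bp <- bp; prev_by <- by

    base_pitch[idx] <- bp
    base_yaw[idx] <- by
    osc_pitch[idx] <- op * ramp
    osc_yaw[idx] <- oy * ramp

    functional <- e$type %in% c("arm", "hand")
    use[idx] <- as.integer(functional)
    mtype[idx] <- switch(e$type, arm = "Arm", hand = "Hand", "NonFunctional")
    task[idx] <- sample(sim_tasks[[e$type]], 1)
    # transition zone at the epoch start is an unknown task
    k <- min(n, round(0.5 * rate))
    if (i0 > 1L) task[idx[seq_len(k)]] <- "unknown"
    epoch_rows[[length(epoch_rows) + 1L]] <-
      tibble::tibble(type = e$type, start = time[i0], end = time[i1])
  }

  # smooth the piecewise-constant bases so transitions are continuous
  sm <- max(1L, round(rate))  # 1 s boxcar
  base_pitch <- zoo::rollapply(base_pitch, sm, mean, partial = TRUE, align = "center")
  base_yaw <- zoo::rollapply(base_yaw, sm, mean, partial = TRUE, align = "center")
  pitch <- pmin(89, pmax(-89, base_pitch + osc_pitch))
  yaw <- base_yaw + osc_yaw

  # body angular rates from the scripted Euler profile (zero roll):
  # omega = (yaw_dot sin(pitch), -pitch_dot, yaw_dot cos(pitch))
  dyaw <- c(0, diff(yaw)) * rate
  dpitch <- c(0, diff(pitch)) * rate
  pr <- pitch * pi / 180
  wx <- dyaw * sin(pr); wy <- -dpitch; wz <- dyaw * cos(pr)

  q <- euler_to_quat(yaw, pitch)
  spec_force <- acc_earth + matrix(rep(c(0, 0, 1), each = n_tot), ncol = 3)
  acc_body <- quat_rotate(q, spec_force, inverse = TRUE) +
    matrix(rnorm(3 * n_tot, sd = config$accel_noise_sd), ncol = 3)
  gyro_body <- cbind(wx, wy, wz) +
    matrix(rep(config$gyro_offset, each = n_tot), ncol = 3) +
    matrix(rnorm(3 * n_tot, sd = config$gyro_noise_sd), ncol = 3)
  mag_body <- quat_rotate(q, matrix(rep(c(0.6, 0, -0.8), each = n_tot), ncol = 3),
                          inverse = TRUE) +
    matrix(rnorm(3 * n_tot, sd = config$mag_noise_sd), ncol = 3)

  recording <- tibble::tibble(
    time = time,
    ax = acc_body[, 1], ay = acc_body[, 2], az = acc_body[, 3],
    gx = gyro_body[, 1], gy = gyro_body[, 2], gz = gyro_body[, 3],
    mx = mag_body[, 1], my = mag_body[, 2], mz = mag_body[, 3]
  )
  truth <- tibble::tibble(
    time = time, yaw = yaw, pitch = pitch, use = use,
    task = task, movement_type = mtype
  )

  # annotations at the video rate, with independent symmetric flip noise
  ann_grid <- time[1] + seq(0, floor((time[n_tot] - time[1]) * config$ann_rate)) /
    config$ann_rate
  gi <- findInterval(ann_grid, time)
  ann_use <- use[gi]
  flip <- function(u) {
    f <- runif(length(u)) < config$annotator_flip
    as.integer(ifelse(f, 1L - u, u))
  }
  annotations <- tibble::tibble(
    time = ann_grid,
    use_a1p1 = flip(ann_use), use_a1p2 = flip(ann_use),
    use_a2p1 = flip(ann_use), use_a2p2 = flip(ann_use),
    task = task[gi], movement_type = mtype[gi]
  )

  list(recording = recording, annotations = annotations, truth = truth,
       epochs = dplyr::bind_rows(epoch_rows))
}

arm_to_dataset <- function(sim, subject, group, arm, rate = 50) {
  ann50 <- resample_zoh(sim$annotations, rate)
  n <- min(nrow(sim$recording), nrow(ann50))
  dplyr::bind_cols(
    tibble::tibble(subject = subject, group = group, arm = arm),
    sim$recording[seq_len(n), ],
    ann50[seq_len(n), c("use_a1p1", "use_a1p2", "use_a2p1", "use_a2p2",
                        "task", "movement_type")]
  )
}

#' Simulate a two-arm cohort
#'
#' Generates independent subjects, each with two arms of equal duration.
#' Controls (right-dominant) get a higher functional share on the dominant
#' arm; patients get a reduced functional share and attenuated movement
#' amplitude on the affected arm.
#'
#' @param n_subjects number of subjects.
#' @param n_patients number of patients (default: one third, rounded).
#' @param duration per-arm recording length in seconds.
#' @param seed integer seed driving the whole cohort.
#' @param pitch_only forwarded to [sim_config()].
#' @param annotator_flip forwarded to [sim_config()].
#' @param functional_share optional fixed functional-share target applied to
#'   every arm (by default shares are drawn per group).
#' @return a dataset tibble in the documented CSV schema (50 Hz rows for
#'   every subject and arm, annotations upsampled by zero-order hold).
#' @export
simulate_cohort <- function(n_subjects = 15, n_patients = NULL,
                            duration = 180, seed = 1, pitch_only = FALSE,
                            annotator_flip = 0.02,
                            functional_share = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(n_patients)) n_patients <- round(n_subjects / 3)
  set.seed(seed)
  arm_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
                      ncol = 2L)
  shares <- lapply(seq_len(n_subjects), function(i) {
    patient <- i > (n_subjects - n_patients)
    if (patient) {
      list(dom = runif(1, 0.5, 0.65), nondom = runif(1, 0.25, 0.4))
    } else {
      list(dom = runif(1, 0.55, 0.7), nondom = runif(1, 0.45, 0.6))
    }
  })
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    patient <- i > (n_subjects - n_patients)
    group <- if (patient) "patient" else "control"
    arms <- if (patient) c("unaffected", "affected") else c("right", "left")
    sh <- shares[[i]]
    cfg_dom <- sim_config(
      duration = duration,
      functional_share = if (is.null(functional_share)) sh$dom else functional_share,
      arm_label = arms[1], pitch_only = pitch_only,
      annotator_flip = annotator_flip, seed = arm_seeds[i, 1]
    )
    cfg_non <- sim_config(
      duration = duration,
      functional_share = if (is.null(functional_share)) sh$nondom else functional_share,
      amplitude = if (patient) 0.6 else 1,
      arm_label = arms[2], pitch_only = pitch_only,
      annotator_flip = annotator_flip, seed = arm_seeds[i, 2]
    )
    id <- sprintf("S%02d", i)
    out[[i]] <- dplyr::bind_rows(
      arm_to_dataset(simulate_arm(cfg_dom), id, group, arms[1]),
      arm_to_dataset(simulate_arm(cfg_non), id, group, arms[2])
    )
  }
  dplyr::bind_rows(out)
}
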