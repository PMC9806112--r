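# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The default synthetic cohort: 15 subjects (10 controls, 5 patients),
# 180 s per arm, fixed seed.
default_cohort <- function() {
  cached("cohort", simulate_cohort(n_subjects = 15, duration = 180, seed = 1))
}

default_eval <- function() {
  cached("eval", evaluate_measures(default_cohort()))
}

default_tables <- function() {
  cached("tables", ml_window_tables(default_cohort()))
}

# One arm's preprocessed recording + consensus ground truth + window table,
# with task labels attached (for ablation experiments).
arm_fixture <- function(seed = 55, duration = 180, ...) {
  key <- paste0("arm_", seed, "_", duration, "_",
                paste(unlist(list(...)), collapse = "_"))
  cached(key, {
    sim <- simulate_arm(sim_config(duration = duration, seed = seed, ...))
    rec <- preprocess_recording(sim$recording)
    ann50 <- resample_zoh(sim$annotations, 50)
    n <- min(nrow(rec), nrow(ann50))
    rec <- rec[seq_len(n), ]
    gt <- tibble::tibble(
      time = rec$time,
      label = consensus_label(ann50$use_a1p1, ann50$use_a1p2,
                              ann50$use_a2p1, ann50$use_a2p2)[seq_len(n)])
    rec$task <- sim$truth$task[seq_len(n)]
    list(sim = sim, recording = rec, gt = gt,
         table = build_window_table(rec, gt))
  })
}

# Synthetic feature tables for exercising the learning protocol without
# the signal pipeline: class 1 is shifted along a few features, with
# Gaussian overlap controlled by `sep`.
make_ml_table <- function(n = 200, sep = 2, seed = 1, subject = "S01",
                          flip = FALSE) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  shift <- label * sep
  nrm <- abs(rnorm(n, 1, 0.1))
  tab <- tibble::tibble(
    win_start = (seq_len(n) - 1) * 0.25,
    subject = subject, arm = "right",
    mean_ax = shift + rnorm(n), mean_ay = rnorm(n), mean_az = rnorm(n),
    var_ax = abs(rnorm(n)), var_ay = abs(rnorm(n)), var_az = abs(rnorm(n)),
    mean_norm = nrm + 0.3 * shift, var_norm = abs(rnorm(n, 0.05, 0.02)),
    min_norm = nrm - 0.1, max_norm = nrm + 0.1,
    entropy_norm = rnorm(n),
    label = if (flip) 1L - label else label
  )
  tab
}

# A static recording in a fixed pose (pitch in degrees), with optional
# earth-frame sinusoidal acceleration injected through the true attitude.
static_recording <- function(duration = 30, rate = 50, pitch = 0,
                             accel_earth = NULL, noise_sd = 0,
                             with_mag = TRUE, seed = 1) {
  set.seed(seed)
  n <- duration * rate
  time <- (seq_len(n) - 1) / rate
  q <- euler_to_quat(rep(0, n), rep(pitch, n))
  ae <- if (is.null(accel_earth)) matrix(0, n, 3) else accel_earth
  spec_force <- ae + matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  acc <- quat_rotate(q, spec_force, inverse = TRUE) +
    matrix(rnorm(3 * n, sd = noise_sd), ncol = 3)
  out <- tibble::tibble(time = time,
                        ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                        gx = 0, gy = 0, gz = 0)
  if (with_mag) {
    m <- quat_rotate(q, matrix(rep(c(0.6, 0, -0.8), each = n), ncol = 3),
                     inverse = TRUE)
    out$mx <- m[, 1]; out$my <- m[, 2]; out$mz <- m[, 3]
  }
  out
}
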