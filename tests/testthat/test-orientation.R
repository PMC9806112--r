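# Rest detection, gyro offset correction, median filtering, sensor fusion
# and gravity subtraction.

gyro_frame <- function(g, rate = 50) {
  n <- nrow(g)
  tibble::tibble(time = (seq_len(n) - 1) / rate,
                 gx = g[, 1], gy = g[, 2], gz = g[, 3])
}

test_that("rest detection finds quiet runs of sufficient length", {
  rate <- 50
  zero <- gyro_frame(matrix(0, 60 * rate, 3))
  r <- detect_rest_periods(zero)
  expect_equal(nrow(r), 1L)
  expect_gte(sum(r$end - r$start), 58)

  t <- (seq_len(60 * rate) - 1) / rate
  loud <- gyro_frame(matrix(10 * sin(2 * pi * t), ncol = 3, nrow = length(t)))
  expect_equal(nrow(detect_rest_periods(loud)), 0L)

  # 12 s quiet between two 30 s movement bouts
  set.seed(1)
  seg <- c(10 * sin(2 * pi * seq(0, 30, by = 1 / rate))[1:(30 * rate)],
           rnorm(12 * rate, sd = 0.1),
           10 * sin(2 * pi * seq(0, 30, by = 1 / rate))[1:(30 * rate)])
  mixed <- gyro_frame(matrix(rep(seg, 3), ncol = 3))
  r <- detect_rest_periods(mixed)
  expect_equal(nrow(r), 1L)
  expect_equal(r$end - r$start, 12, tolerance = 0.2)
})

test_that("rest detection agrees with a brute-force block scan", {
  set.seed(42)
  rate <- 20
  n <- 2000
  g <- matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
  g[400:900, ] <- rnorm(3 * 501, sd = 0.05)       # quiet stretch
  g[1300:1900, ] <- rnorm(3 * 601, sd = 0.05)     # another
  d <- gyro_frame(g, rate)
  got <- detect_rest_periods(d, min_duration = 10, variance_threshold = 0.15)

  # oracle: independent loop over 1 s blocks then merge runs
  per <- rate
  nb <- floor(n / per)
  quiet <- logical(nb)
  for (b in seq_len(nb)) {
    i <- ((b - 1) * per + 1):(b * per)
    quiet[b] <- all(var(g[i, 1]) < 0.15, var(g[i, 2]) < 0.15,
                    var(g[i, 3]) < 0.15)
  }
  runs <- rle(quiet)
  stops <- cumsum(runs$lengths)
  exp_rows <- which(runs$values & runs$lengths >= 10)
  expect_equal(nrow(got), length(exp_rows))
  for (j in seq_along(exp_rows)) {
    b1 <- stops[exp_rows[j]] - runs$lengths[exp_rows[j]] + 1
    expect_equal(got$start[j], d$time[(b1 - 1) * per + 1])
  }
})

test_that("gyro offset correction de-biases piecewise from each rest", {
  rate <- 50
  n <- 60 * rate
  base <- matrix(rep(c(0.1, -0.05, 0.02), each = n), ncol = 3)
  d <- gyro_frame(base, rate)
  rest <- detect_rest_periods(d)
  corrected <- correct_gyro_offset(d, rest)
  expect_equal(mean(corrected$gx), 0, tolerance = 1e-12)
  expect_equal(mean(corrected$gy), 0, tolerance = 1e-12)

  # no rest -> identity
  expect_identical(correct_gyro_offset(d, rest[0, ]), d)

  # two rest segments with different offsets, applied until the next rest
  g <- rbind(matrix(rep(c(0.1, 0, 0), each = 15 * rate), ncol = 3),
             matrix(rep(c(0.2, 0, 0), each = 15 * rate), ncol = 3))
  d2 <- gyro_frame(g, rate)
  rest2 <- tibble::tibble(start = c(0, 15), end = c(12, 27))
  c2 <- correct_gyro_offset(d2, rest2)
  expect_equal(mean(c2$gx[d2$time >= 0 & d2$time <= 12]), 0, tolerance = 1e-12)
  expect_equal(mean(c2$gx[d2$time >= 15 & d2$time <= 27]), 0, tolerance = 1e-12)
  # the difference to the input is piecewise constant
  delta <- d2$gx - c2$gx
  expect_setequal(round(unique(delta), 10), c(0.1, 0.2))
})

test_that("median filter removes spikes and tolerates missing samples", {
  rec <- tibble::tibble(time = (0:9) / 50, ax = 0, ay = 1, az = 1)
  expect_equal(median_filter_accel(rec)$ay, rep(1, 10))
  rec$ax[5] <- 10
  expect_equal(median_filter_accel(rec)$ax[5], 0)
  # NaN inside the window: median of the remaining values
  rec2 <- tibble::tibble(time = (0:6) / 50,
                         ax = c(1, 2, NA, 4, 5, 6, 7), ay = 0, az = 1)
  f <- median_filter_accel(rec2)
  expect_equal(f$ax[3], median(c(1, 2, 4, 5)))   # shrunk window around NaN
  expect_equal(f$ax[1], median(c(1, 2)))         # edge window
})

test_that("fusion recovers static attitudes under the pitch convention", {
  flat <- static_recording(duration = 10, pitch = 0, with_mag = FALSE)
  up <- static_recording(duration = 10, pitch = 90, with_mag = FALSE)
  o1 <- estimate_orientation(flat, "madgwick")
  o2 <- estimate_orientation(up, "madgwick")
  expect_lt(abs(o1$pitch[nrow(o1)]), 1)
  expect_lt(abs(o2$pitch[nrow(o2)] - 90), 1)
  qn <- sqrt(o1$qw^2 + o1$qx^2 + o1$qy^2 + o1$qz^2)
  expect_true(all(abs(qn - 1) < 1e-6))
  short <- flat[1:10, ]
  short$ax <- NULL
  expect_error(estimate_orientation(short))
})

test_that("fusion tracks a scripted trajectory within 3 degrees RMSE", {
  sim <- simulate_arm(sim_config(duration = 60, seed = 12))
  rec <- preprocess_recording(sim$recording)
  for (alg in c("madgwick", "mahony")) {
    o <- estimate_orientation(rec, alg)
    sel <- o$time > 5
    rmse <- sqrt(mean((o$pitch[sel] - sim$truth$pitch[sel])^2))
    expect_lt(rmse, 3)
  }
})

test_that("gravity subtraction leaves small residuals and recovers motion", {
  st <- static_recording(duration = 20, pitch = -40, noise_sd = 0.003)
  o <- estimate_orientation(st, "madgwick")
  lin <- gravity_subtract(st, o)
  resid <- sqrt(lin$lx^2 + lin$ly^2 + lin$lz^2)
  expect_lt(max(resid[lin$time > 5]), 0.05)

  # identity pose: (0,0,1) g maps to zero linear acceleration exactly
  one <- tibble::tibble(time = 0, ax = 0, ay = 0, az = 1)
  q_id <- tibble::tibble(time = 0, qw = 1, qx = 0, qy = 0, qz = 0)
  z <- gravity_subtract(one, q_id)
  expect_equal(unlist(z[, c("lx", "ly", "lz")]), c(lx = 0, ly = 0, lz = 0))

  # known earth-frame sinusoid injected through the true attitude
  n <- 20 * 50
  t <- (seq_len(n) - 1) / 50
  ae <- cbind(0.3 * sin(2 * pi * 1 * t), 0, 0)
  dyn <- static_recording(duration = 20, pitch = 20, accel_earth = ae)
  od <- estimate_orientation(dyn, "madgwick")
  ld <- gravity_subtract(dyn, od)
  sel <- t > 5
  amp <- sqrt(2) * sd(ld$lx[sel])
  expect_lt(abs(amp - 0.3) / 0.3, 0.1)
})
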