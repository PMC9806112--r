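# Vector-magnitude counts, activity counts, laterality, GM and GMAC.

test_that("dead-band and quantization follow their thresholds", {
  expect_equal(deadband(c(0.05, 0.10, 0, -0.05, -0.2)),
               c(0, 0.10, 0, 0, -0.2))
  expect_identical(quantize_counts(c(0.034, 0.0169, 0)), c(2L, 0L, 0L))
  expect_error(quantize_counts(-0.1), "non-negative")
})

test_that("vector-magnitude counts are 1 Hz and silent at rest", {
  st <- static_recording(duration = 30, pitch = -30, noise_sd = 0.005,
                         with_mag = FALSE)
  vmc <- vector_magnitude_counts(st)
  expect_true(all(vmc$counts < 0.01))
  expect_equal(diff(vmc$time), rep(1, nrow(vmc) - 1), tolerance = 1e-9)

  # in-band earth-frame sinusoid produces strictly positive counts
  n <- 30 * 50; t <- (seq_len(n) - 1) / 50
  ae <- cbind(0.5 * sin(2 * pi * 1 * t), 0, 0)
  dyn <- static_recording(duration = 30, pitch = 0, accel_earth = ae,
                          with_mag = FALSE)
  vmd <- vector_magnitude_counts(dyn)
  expect_true(all(vmd$counts[vmd$time > 8] > 0))

  expect_error(vector_magnitude_counts(st[1:100, ]), "window")
})

test_that("vm_use thresholds counts at zero", {
  cnt <- tibble::tibble(time = 1:3, counts = c(0, 0.3, 5))
  expect_equal(vm_use(cnt)$use, c(0L, 1L, 1L))
  zero <- tibble::tibble(time = 1:3, counts = c(0, 0, 0))
  expect_true(all(vm_use(zero)$use == 0L))
})

test_that("activity counts are integer, 1 Hz, and need a magnetometer", {
  st <- static_recording(duration = 20, pitch = 10, noise_sd = 0.005)
  ac <- activity_counts(st)
  expect_true(all(ac$counts == 0L))
  expect_type(ac$counts, "integer")
  expect_equal(diff(ac$time), rep(1, nrow(ac) - 1), tolerance = 1e-9)

  n <- 20 * 50; t <- (seq_len(n) - 1) / 50
  ae <- cbind(0.2 * sin(2 * pi * 1 * t), 0, 0)
  dyn <- static_recording(duration = 20, pitch = 0, accel_earth = ae)
  acd <- activity_counts(dyn)
  expect_true(all(acd$counts[acd$time > 5 & acd$time < 18] >= 1L))
  expect_true(all(acd$counts >= 0L))

  no_mag <- st[, setdiff(names(st), c("mx", "my", "mz"))]
  expect_error(activity_counts(no_mag), "9-DOF")
})

test_that("laterality index reproduces the threshold semantics", {
  grid <- tibble::tibble(time = 1:3)
  lat <- laterality_use(
    dplyr::mutate(grid, counts = c(10, 5, 0)),
    dplyr::mutate(grid, counts = c(0, 5, 0))
  )
  expect_equal(lat$laterality, c(1, 0, NA))
  expect_equal(lat$use_dominant, c(1L, 1L, 0L))
  expect_equal(lat$use_nondominant, c(0L, 1L, 0L))
  expect_error(
    laterality_use(dplyr::mutate(grid, counts = 1),
                   tibble::tibble(time = 1:3 + 0.5, counts = 1)),
    "grid")
})

test_that("GM scores windows by angular range inside the functional space", {
  rate <- 50; n <- 2 * rate; t <- (seq_len(n) - 1) / rate
  # triangular sweeps give an exact range
  tri <- function(range) range * abs(2 * t / max(t) - 1)
  o1 <- tibble::tibble(time = t, yaw = tri(25), pitch = 5 + tri(15) - 7.5)
  expect_equal(gm_use(o1)$use[1], 1L)   # 40 deg total, mean pitch ~5
  o2 <- tibble::tibble(time = t, yaw = tri(40), pitch = 60 + tri(20) - 10)
  expect_equal(gm_use(o2)$use[1], 0L)   # out of the functional space
  still <- tibble::tibble(time = t, yaw = 0, pitch = 5)
  expect_equal(gm_use(still)$use[1], 0L)
  expect_error(gm_use(still[1:10, ]), "window")

  # 2 Hz output on 60 s of 50 Hz input
  t60 <- (seq_len(60 * rate) - 1) / rate
  o60 <- tibble::tibble(time = t60, yaw = 40 * sin(2 * pi * 0.5 * t60),
                        pitch = 10 * sin(2 * pi * 0.5 * t60))
  g <- gm_use(o60)
  expect_equal(diff(g$time), rep(0.5, nrow(g) - 1), tolerance = 1e-9)

  # yaw wrapping at +/-180 does not inflate the range
  wrap <- tibble::tibble(time = t, yaw = ifelse(t < 1, 179, -179), pitch = 0)
  expect_equal(gm_use(wrap)$use[1], 0L)
})

test_that("GMAC requires both positive counts and functional pitch", {
  counts <- tibble::tibble(time = c(1, 2, 3), counts = c(3, 3, 0))
  pitch <- tibble::tibble(time = seq(0, 3, by = 0.02),
                          pitch = rep(c(5, -60, 0), length.out = 151))
  pitch$pitch <- c(rep(5, 51), rep(-60, 50), rep(0, 50))
  g <- gmac_use(counts, pitch)
  expect_equal(g$use, c(1L, 0L, 0L))
  expect_error(
    gmac_use(tibble::tibble(time = 100, counts = 1), pitch), "span")
})

test_that("GMAC never exceeds the vector-magnitude use signal", {
  fx <- arm_fixture(seed = 21, duration = 120)
  m <- arm_measures(fx$recording, measures = c("vm", "gmac"))
  expect_true(all(m$gmac$use <= m$vm$use))
})

test_that("gait segments fool the counts but not the orientation rules", {
  fx <- arm_fixture(seed = 55, duration = 180)
  m <- arm_measures(fx$recording, measures = c("vm", "gm", "gmac"))
  gait <- dplyr::filter(fx$sim$epochs, .data$type == "gait")
  expect_gt(nrow(gait), 0)
  for (i in seq_len(nrow(gait))) {
    lo <- gait$start[i]; hi <- gait$end[i]
    # interior windows only: clear of transition smoothing and of windows
    # that straddle the epoch boundary
    gm_in <- m$gm$use[m$gm$time >= lo + 3.5 & m$gm$time <= hi - 1]
    gmac_in <- m$gmac$use[m$gmac$time >= lo + 7 & m$gmac$time <= hi - 1]
    vm_in <- m$vm$use[m$vm$time >= lo + 7 & m$vm$time <= hi - 1]
    expect_true(all(gm_in == 0L))
    expect_true(all(gmac_in == 0L))
    expect_true(all(vm_in == 1L))
  }
})
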