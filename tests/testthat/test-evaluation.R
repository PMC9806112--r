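# Confusion alignment, Youden index, group statistics, feature correlates,
# proportion regression and the task ablation.

test_that("confusion aligns lower-rate signals by zero-order hold", {
  gt <- tibble::tibble(time = (0:499) / 50,
                       label = as.integer((0:499) / 50 >= 5))
  perfect <- tibble::tibble(time = seq(1, 9, by = 1),
                            use = as.integer(seq(1, 9, by = 1) >= 5))
  m <- confusion(perfect, gt)
  expect_equal(m$fp + m$fn, 0)
  expect_equal(m$tp + m$fp + m$tn + m$fn, sum(gt$time >= 0 & gt$time <= 9))

  always_on <- tibble::tibble(time = seq(1, 9), use = 1L)
  m2 <- confusion(always_on, gt)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  expect_error(confusion(tibble::tibble(time = 100, use = 1L), gt), "overlap")
})

test_that("the Youden index is affine, symmetric and bounded", {
  expect_identical(youden(1, 1), 1)
  expect_identical(youden(0.5, 0.5), 0)
  expect_identical(youden(0, 0), -1)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
  set.seed(2)
  s <- runif(50); p <- runif(50)
  expect_equal(youden(s, p), youden(p, s))
  # affine in each argument
  expect_equal(youden(s, 0.5) - youden(0, 0.5), s)
})

test_that("group comparison runs ANOVA with Bonferroni-corrected t-tests", {
  set.seed(3)
  d <- tibble::tibble(
    family = rep(c("traditional", "inter", "intra"), each = 10),
    youden = c(rnorm(10, 0.1, 0.05), rnorm(10, 0.5, 0.05),
               rnorm(10, 0.9, 0.05)))
  res <- compare_measure_groups(d)
  expect_lt(res$anova$p, 0.001)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, 3 * res$pairwise$p))
  expect_error(compare_measure_groups(d[c(1, 11:30), ]), "at least 2")

  # type-I behaviour when every family is drawn from one distribution
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    d0 <- tibble::tibble(family = rep(c("a", "b", "c"), each = 8),
                         youden = rnorm(24, 0.5, 0.1))
    compare_measure_groups(d0)$anova$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("feature correlates use rank correlation and flag constants", {
  set.seed(5)
  f <- tibble::tibble(mean_ax = rnorm(1000))
  v <- tibble::tibble(mean_pitch = exp(f$mean_ax),  # monotone transform
                      noise = rnorm(1000))
  res <- feature_correlates(f, v)
  expect_equal(res$rho[res$variable == "mean_pitch"], 1)
  expect_lt(abs(res$rho[res$variable == "noise"]), 0.1)
  expect_warning(
    resc <- feature_correlates(f, tibble::tibble(flat = rep(1, 1000))),
    "constant")
  expect_true(is.na(resc$rho))
})

test_that("proportion regression recovers fabricated slopes", {
  pf <- c(10, 30, 50, 70, 90)
  d <- tibble::tibble(pct_functional = pf,
                      sensitivity = 0.5 + 0.004 * pf,
                      specificity = rep(0.8, 5))
  res <- suppressWarnings(proportion_regression(d))  # noiseless fit
  sens <- res[res$response == "sensitivity", ]
  expect_equal(sens$slope, 0.004, tolerance = 1e-10)
  expect_lt(sens$p_value, 0.01)
  set.seed(6)
  flat <- tibble::tibble(pct_functional = pf,
                         sensitivity = 0.8 + rnorm(5, sd = 0.02),
                         specificity = 0.8 + rnorm(5, sd = 0.02))
  resf <- proportion_regression(flat)
  expect_gt(min(resf$p_value), 0.05)
  expect_error(proportion_regression(d[1:2, ]), "3 subjects")
})

test_that("the task ablation builds exactly the four compositions", {
  fx <- arm_fixture(seed = 55, duration = 180)
  ab <- task_ablation(fx$table, "walk", seed = 9)
  expect_equal(nrow(ab), 4L)
  expect_setequal(ab$condition, c("tr.te", "tr_.te", "tr.te_", "tr_.te_"))
  expect_error(task_ablation(fx$table, "juggle"), "not present")

  # a redundant functional task barely moves specificity when withheld
  arm_tasks <- intersect(unique(fx$table$task),
                         c("drinkcup", "openbottle", "wipe", "eat"))
  redundant <- arm_tasks[1]
  ab2 <- task_ablation(fx$table, redundant, seed = 9)
  base <- ab2$specificity[ab2$condition == "tr.te"]
  withheld <- ab2$specificity[ab2$condition == "tr_.te"]
  expect_lt(abs(base - withheld), 0.05)

  # unknown-task windows are excluded from the analysis
  n_known <- sum(fx$table$task != "unknown")
  expect_gt(sum(fx$table$task == "unknown"), 0)
  cc <- ab$sensitivity  # smoke: metrics are defined
  expect_true(all(is.finite(cc)))
})
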