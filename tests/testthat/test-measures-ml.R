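# Window features, the entropy estimator, and the nested-CV protocol.

test_that("kernel-density entropy has its closed forms and invariances", {
  # point mass: entropy is the log-height of one Gaussian bump
  expect_equal(entropy_kde(rep(1.3, 5)), -log(1 / (sqrt(2 * pi) * 0.2)),
               tolerance = 1e-12)
  set.seed(4)
  spread <- rnorm(100, sd = 1)
  tight <- rnorm(100, sd = 0.05)
  expect_gt(entropy_kde(spread), entropy_kde(tight))
  v <- rnorm(20)
  expect_equal(entropy_kde(v), entropy_kde(rev(v)))
  expect_equal(entropy_kde(v), entropy_kde(sample(v)))
  expect_error(entropy_kde(1), "at least 2")
})

test_that("feature extraction matches an independent per-formula oracle", {
  oracle_features <- function(w) {
    # deliberately different arithmetic path: explicit sums and loops
    n <- nrow(w)
    m <- function(x) sum(x) / n
    vp <- function(x) sum((x - m(x))^2) / n
    nrm <- numeric(n)
    for (i in seq_len(n)) nrm[i] <- sqrt(w[i, 1]^2 + w[i, 2]^2 + w[i, 3]^2)
    h <- 0.2
    logp <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        s <- s + exp(-(nrm[i] - nrm[j])^2 / (2 * h^2)) / (h * sqrt(2 * pi))
      }
      logp[i] <- log(s / n)
    }
    c(m(w[, 1]), m(w[, 2]), m(w[, 3]), vp(w[, 1]), vp(w[, 2]), vp(w[, 3]),
      m(nrm), vp(nrm), min(nrm), max(nrm), -sum(logp) / n)
  }
  set.seed(11)
  for (k in c(2, 5, 12, 13)) {
    w <- matrix(rnorm(3 * k, sd = 0.5), ncol = 3)
    got <- as.numeric(extract_features(w))
    expect_equal(got, oracle_features(w), tolerance = 1e-10)
    expect_length(got, 11L)
  }
  # constant window
  cw <- matrix(rep(c(0, 0, 1), each = 4), ncol = 3)
  f <- extract_features(cw)
  expect_equal(unname(unlist(f[, c("mean_ax", "mean_ay", "mean_az")])),
               c(0, 0, 1))
  expect_equal(f$var_ax + f$var_ay + f$var_az + f$var_norm, 0)
  expect_equal(f$min_norm, 1); expect_equal(f$max_norm, 1)
  expect_error(extract_features(cw[1, , drop = FALSE]), "2 samples")
})

test_that("window tables tile the record and label from the window centre", {
  rate <- 50; n <- 10 * rate
  rec <- tibble::tibble(time = (seq_len(n) - 1) / rate,
                        ax = rnorm(n, sd = 0.1), ay = 0, az = 1)
  gt <- tibble::tibble(time = rec$time, label = rep(1L, n))
  tab <- build_window_table(rec, gt, window_s = 0.25)
  expect_equal(nrow(tab), 40L)
  expect_true(all(tab$label == 1L))
  expect_equal(diff(tab$win_start), rep(0.25, 39), tolerance = 1e-9)

  # a flip mid-window: the centre sample decides, not the majority
  gt2 <- gt
  first_win <- rec$time < 0.25
  gt2$label[first_win] <- as.integer(rec$time[first_win] >= 0.12)
  # centre instant 0.125 s -> label 1 even though 6/12 samples are 0
  tab2 <- build_window_table(rec, gt2, window_s = 0.25)
  expect_equal(tab2$label[1], 1L)
  gt3 <- gt2
  gt3$label[first_win] <- as.integer(rec$time[first_win] >= 0.14)
  expect_equal(build_window_table(rec, gt3)$label[1], 0L)

  expect_error(build_window_table(rec, gt[-1, ]), "aligned")
})

test_that("all three learners separate a separable table", {
  tab <- make_ml_table(n = 200, sep = 4, seed = 2)
  for (model in c("rf", "svm", "mlp")) {
    cv <- train_eval_intra(tab, model, iterations = 2, seed = 5)
    expect_gt(glance(cv)$mean_youden, 0.9)
  }
})

test_that("permuted labels score at chance", {
  tab <- make_ml_table(n = 300, sep = 3, seed = 6)
  set.seed(9)
  tab$label <- sample(tab$label)
  cv <- train_eval_intra(tab, "rf", iterations = 10, seed = 10)
  expect_lt(abs(glance(cv)$mean_youden), 0.1)
})

test_that("identical seeds give identical folds and metrics", {
  tab <- make_ml_table(n = 150, sep = 2, seed = 3)
  a <- train_eval_intra(tab, "rf", iterations = 2, seed = 99)
  b <- train_eval_intra(tab, "rf", iterations = 2, seed = 99)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$bookkeeping, b$bookkeeping)
  expect_error(train_eval_intra(dplyr::mutate(tab, label = 1L), "rf"),
               "single class")
})

test_that("hyper-parameter selection never touches outer-test rows", {
  tab <- make_ml_table(n = 150, sep = 2, seed = 3)
  cv <- train_eval_intra(tab, "rf", iterations = 3, seed = 1)
  for (b in cv$bookkeeping) {
    expect_length(intersect(b$outer_test, b$selection), 0L)
    expect_setequal(c(b$outer_test, b$selection), seq_len(nrow(tab)))
  }
  inter_tab <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_ml_table(n = 80, sep = 2, seed = i, subject = paste0("S", i))
  }))
  cvi <- train_eval_inter(inter_tab, "rf", seed = 2)
  for (b in cvi$bookkeeping) {
    expect_length(intersect(b$outer_test, b$selection), 0L)
  }
})

test_that("leave-one-subject-out tracks intra performance on homogeneous data", {
  tabs <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_ml_table(n = 150, sep = 2, seed = 20 + i, subject = paste0("S", i))
  }))
  inter <- train_eval_inter(tabs, "rf", seed = 4)
  expect_equal(nrow(tidy(inter)), 4L)
  intra <- train_eval_intra(tabs[tabs$subject == "S1", ], "rf",
                            iterations = 2, seed = 4)
  expect_lt(abs(glance(inter)$mean_youden - glance(intra)$mean_youden), 0.15)
  expect_error(train_eval_inter(tabs[tabs$subject %in% c("S1", "S2"), ]),
               "3 subjects")
})

test_that("an inverted-label subject scores negative without harming others", {
  tabs <- dplyr::bind_rows(
    lapply(1:3, function(i) {
      make_ml_table(n = 150, sep = 3, seed = 30 + i, subject = paste0("S", i))
    }),
    make_ml_table(n = 150, sep = 3, seed = 34, subject = "S4", flip = TRUE)
  )
  inter <- train_eval_inter(tabs, "rf", seed = 8)
  r <- tidy(inter)
  expect_lt(r$youden[r$subject == "S4"], 0)
  expect_gt(min(r$youden[r$subject != "S4"]), 0.5)
})

test_that("Gini importances are normalised and find planted signal", {
  tab <- make_ml_table(n = 400, sep = 0, seed = 40)
  tab$mean_ax <- tab$label * 2 + rnorm(400, sd = 0.3)
  gi <- gini_importances(fit_rf(tab, seed = 1))
  expect_equal(sum(gi$importance), 1, tolerance = 1e-9)
  expect_equal(gi$feature[1], "mean_ax")
  expect_error(gini_importances(lm(label ~ mean_ax, tab)), "ranger")

  # pure noise: no feature dominates (10 seeds)
  maxima <- vapply(1:10, function(s) {
    noise <- make_ml_table(n = 300, sep = 0, seed = 50 + s)
    gi <- gini_importances(fit_rf(noise, seed = s))
    max(gi$importance)
  }, numeric(1))
  expect_true(all(maxima < 3 / 11))
})

test_that("reduced models use the stated subsets and nest correctly", {
  sets <- feature_sets()
  expect_equal(unname(lengths(sets)), c(1L, 3L, 6L, 11L))
  tab <- make_ml_table(n = 150, sep = 2, seed = 60)
  red <- reduced_model_eval(tab, subsets = c("full"), iterations = 2, seed = 7)
  full <- train_eval_intra(tab, "rf", iterations = 2, seed = 7)
  expect_identical(tidy(red$full), tidy(full))
  expect_error(reduced_model_eval(tab, subsets = c("bogus")), "unknown")
})
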