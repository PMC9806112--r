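# Windowed accelerometer features and the supervised-learning protocol:
# random forest, weighted RBF support vector machine and a three-layer
# (single hidden layer) multi-layer perceptron, evaluated intra-subject
# (stratified k-fold, repeated) and inter-subject (leave-one-subject-out),
# with nested hyper-parameter selection that only ever touches the outer
# training rows.

feature_names <- c("mean_ax", "mean_ay", "mean_az",
                   "var_ax", "var_ay", "var_az",
                   "mean_norm", "var_norm", "min_norm", "max_norm",
                   "entropy_norm")

#' Named feature subsets for reduced models
#'
#' @return a named list of feature-name vectors: the single `mean_ax`
#'   feature, the three axis means, the six axis means and variances, and
#'   the full 11-feature set.
#' @export
feature_sets <- function() {
  list(
    mean_ax = "mean_ax",
    means = c("mean_ax", "mean_ay", "mean_az"),
    means_vars = c("mean_ax", "mean_ay", "mean_az",
                   "var_ax", "var_ay", "var_az"),
    full = feature_names
  )
}

#' Kernel-density Shannon entropy
#'
#' Estimates the density of the values with a Gaussian kernel of the given
#' bandwidth, evaluates it at the sample points, and returns the entropy
#' `-(1/n) sum log p(x_i)` in nats.  For identical values this reduces to
#' `-log(1 / (sqrt(2 pi) h))`, the log-height of a single kernel bump.
#'
#' @param values numeric vector, at least 2 values.
#' @param bandwidth Gaussian kernel bandwidth (default 0.2).
#' @return entropy in nats.
#' @export
entropy_kde <- function(values, bandwidth = 0.2) {
  if (length(values) < 2L) abort("entropy needs at least 2 values")
  d <- outer(values, values, "-")
  p <- rowMeans(dnorm(d, sd = bandwidth))
  -mean(log(p))
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Extract the 11 window features
#'
#' Mean and (population) variance of the acceleration along each axis, and
#' mean, variance, minimum, maximum and kernel-density Shannon entropy of
#' the per-sample 2-norm.
#'
#' @param window matrix or data frame with columns/axes `ax, ay, az`
#'   (k x 3, k >= 2), in g.
#' @param entropy_bandwidth bandwidth for [entropy_kde()].
#' @return a one-row tibble with the 11 features.
#' @export
extract_features <- function(window, entropy_bandwidth = 0.2) {
  w <- as.matrix(window)
  if (nrow(w) < 2L) abort("feature window needs at least 2 samples")
  nrm <- sqrt(rowSums(w^2))
  tibble::tibble(
    mean_ax = mean(w[, 1]), mean_ay = mean(w[, 2]), mean_az = mean(w[, 3]),
    var_ax = var_pop(w[, 1]), var_ay = var_pop(w[, 2]), var_az = var_pop(w[, 3]),
    mean_norm = mean(nrm), var_norm = var_pop(nrm),
    min_norm = min(nrm), max_norm = max(nrm),
    entropy_norm = entropy_kde(nrm, entropy_bandwidth)
  )
}

#' Build the per-window feature table for one recording
#'
#' Tiles the record with non-overlapping windows of `window_s` seconds
#' (trailing partial window dropped), extracts the 11 features per window,
#' and takes each window's label from the ground-truth sample at the window
#' centre (`window_s / 2` from the start).  Metadata columns present on the
#' recording (`subject`, `group`, `arm`, `task`, `movement_type`) are
#' carried over from the centre sample.
#'
#' @param recording arm recording tibble with `time`, `ax..az` (50 Hz).
#' @param gt tibble `time`, `label` on the same grid as the recording.
#' @param window_s window length in seconds (default 0.25).
#' @param gyro_features also include mean and variance of `gx, gy, gz`.
#' @return a tibble, one row per window: `win_start`, metadata, features,
#'   `label`.
#' @export
build_window_table <- function(recording, gt, window_s = 0.25,
                               gyro_features = FALSE) {
  if (nrow(gt) != nrow(recording) ||
      !isTRUE(all.equal(gt$time, recording$time))) {
    abort("ground truth must be aligned to the recording grid")
  }
  rate <- sampling_rate(recording$time)
  t0 <- recording$time[1]
  n_win <- floor(nrow(recording) / (window_s * rate) + 1e-9)
  if (n_win < 1L) abort("record shorter than one feature window")
  win <- floor((recording$time - t0) / window_s + 1e-9)
  keep <- win < n_win
  idx_by_win <- split(which(keep), win[keep])

  acc <- as.matrix(recording[, c("ax", "ay", "az")])
  gyr <- if (gyro_features) as.matrix(recording[, c("gx", "gy", "gz")])
  fcols <- c(feature_names,
             if (gyro_features) c("mean_gx", "mean_gy", "mean_gz",
                                  "var_gx", "var_gy", "var_gz"))
  fm <- t(vapply(idx_by_win, function(i) {
    w <- acc[i, , drop = FALSE]
    nrm <- sqrt(rowSums(w^2))
    v <- c(colMeans(w), apply(w, 2, var_pop),
           mean(nrm), var_pop(nrm), min(nrm), max(nrm), entropy_kde(nrm))
    if (gyro_features) {
      g <- gyr[i, , drop = FALSE]
      v <- c(v, colMeans(g), apply(g, 2, var_pop))
    }
    v
  }, numeric(length(fcols))))
  feats <- tibble::as_tibble(setNames(as.data.frame(fm), fcols))

  centres <- t0 + (seq_len(n_win) - 1L + 0.5) * window_s
  ci <- findInterval(centres + 1e-9, gt$time)
  out <- tibble::tibble(win_start = t0 + (seq_len(n_win) - 1L) * window_s)
  for (col in c("subject", "group", "arm", "task", "movement_type")) {
    if (col %in% names(recording)) out[[col]] <- recording[[col]][ci]
  }
  dplyr::bind_cols(out, feats, tibble::tibble(label = gt$label[ci]))
}

# ---- model fitting -------------------------------------------------------

scale_by <- function(x, centre, spread) {
  spread[spread == 0 | !is.finite(spread)] <- 1
  sweep(sweep(x, 2, centre, "-"), 2, spread, "/")
}

fit_predict <- function(model, x_train, y_train, x_test, params) {
  y_f <- factor(y_train, levels = c(0, 1))
  if (model == "rf") {
    fit <- ranger::ranger(
      x = x_train, y = y_f, num.trees = params$num_trees,
      seed = params$fit_seed, num.threads = 1
    )
    as.integer(as.character(predict(fit, data = x_test,
                                    num.threads = 1)$predictions))
  } else if (model == "svm") {
    mu <- colMeans(x_train); sdev <- apply(x_train, 2, sd)
    xs <- scale_by(x_train, mu, sdev)
    tab <- table(y_f)
    wts <- as.numeric(sum(tab) / (2 * tab)); names(wts) <- names(tab)
    fit <- e1071::svm(x = xs, y = y_f, kernel = "radial",
                      cost = params$cost, gamma = params$gamma,
                      class.weights = wts, scale = FALSE)
    as.integer(as.character(predict(fit, scale_by(x_test, mu, sdev))))
  } else if (model == "mlp") {
    mu <- colMeans(x_train); sdev <- apply(x_train, 2, sd)
    xs <- scale_by(x_train, mu, sdev)
    set.seed(params$fit_seed)
    fit <- nnet::nnet(x = xs, y = as.numeric(y_train), size = params$size,
                      decay = params$decay, maxit = params$maxit,
                      trace = FALSE, linout = FALSE)
    as.integer(predict(fit, scale_by(x_test, mu, sdev)) > 0.5)
  } else {
    abort(paste0("unknown model: ", model))
  }
}

model_grid <- function(model, grids) {
  if (model == "rf") {
    lapply(grids$rf_trees, function(nt) list(num_trees = nt))
  } else if (model == "svm") {
    g <- expand.grid(cost = grids$svm_cost, gamma = grids$svm_gamma)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
  } else {
    list(list(size = grids$mlp_size, decay = grids$mlp_decay,
              maxit = grids$mlp_maxit))
  }
}

#' Default hyper-parameter grids
#'
#' @return list with the random-forest tree grid, the SVM cost/gamma grid
#'   and the fixed MLP architecture.
#' @export
ml_grids <- function() {
  list(rf_trees = c(10, 50, 100, 200),
       svm_cost = c(0.1, 1, 10, 100),
       svm_gamma = c(0.001, 0.01, 0.1, 1),
       mlp_size = 16, mlp_decay = 1e-3, mlp_maxit = 200)
}

confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

metrics_row <- function(cc) {
  sens <- if ((cc["tp"] + cc["fn"]) > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else NA_real_
  spec <- if ((cc["tn"] + cc["fp"]) > 0) cc["tn"] / (cc["tn"] + cc["fp"]) else NA_real_
  tibble::tibble(tp = unname(cc["tp"]), fp = unname(cc["fp"]),
                 tn = unname(cc["tn"]), fn = unname(cc["fn"]),
                 sensitivity = unname(sens), specificity = unname(spec),
                 youden = unname(sens + spec - 1))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# Nested grid search: every outer-training fold serves as the validation
# fold once; returns the grid entry with the best mean Youden.
select_params <- function(model, x, y, fold_id, train_folds, grids) {
  grid <- model_grid(model, grids)
  if (length(grid) == 1L) return(grid[[1L]])
  scores <- vapply(grid, function(params) {
    params$fit_seed <- sample.int(1e9, 1)
    ys <- vapply(train_folds, function(v) {
      tr <- which(fold_id %in% setdiff(train_folds, v))
      va <- which(fold_id == v)
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      pred <- fit_predict(model, x[tr, , drop = FALSE], y[tr],
                          x[va, , drop = FALSE], params)
      cc <- confusion_counts(pred, y[va])
      unname(metrics_row(cc)$youden)
    }, numeric(1))
    mean(ys, na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(scores)]]
}

#' Intra-subject nested cross-validation
#'
#' Repeated stratified k-fold evaluation of one subject-arm's window table.
#' Within each outer training set, hyper-parameters are selected by using
#' every training fold as the validation fold once (nested grid search);
#' the chosen model is refit on the full outer training set and evaluated
#' on the held-out fold.  All reported metrics come from outer-test
#' predictions only.
#'
#' @param table window table from [build_window_table()] (one subject and
#'   arm, both classes present).
#' @param model `"rf"`, `"svm"` or `"mlp"`.
#' @param folds number of outer folds (default 5).
#' @param iterations number of repetitions with fresh fold splits
#'   (default 10).
#' @param seed integer seed controlling folds and model fits.
#' @param feature_cols feature subset to use (default: all 11).
#' @param grids hyper-parameter grids, see [ml_grids()].
#' @return an object of class `limbuse_cv` with one result row per
#'   iteration x fold; see [tidy.limbuse_cv()].
#' @export
train_eval_intra <- function(table, model = c("rf", "svm", "mlp"),
                             folds = 5, iterations = 10, seed = 1,
                             feature_cols = NULL, grids = ml_grids()) {
  model <- match.arg(model)
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names, names(table))
  x <- as.matrix(table[, feature_cols])
  y <- table$label
  if (length(unique(y)) < 2L) {
    abort("window table contains a single class; both functional and non-functional windows are required")
  }
  set.seed(seed)
  rows <- list(); book <- list()
  for (it in seq_len(iterations)) {
    fold_id <- stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      test_idx <- which(fold_id == k)
      train_idx <- which(fold_id != k)
      params <- select_params(model, x, y, fold_id,
                              setdiff(seq_len(folds), k), grids)
      params$fit_seed <- sample.int(1e9, 1)
      pred <- fit_predict(model, x[train_idx, , drop = FALSE], y[train_idx],
                          x[test_idx, , drop = FALSE], params)
      cc <- confusion_counts(pred, y[test_idx])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(iteration = it, fold = k,
                       params = paste(names(params)[names(params) != "fit_seed"],
                                      unlist(params[names(params) != "fit_seed"]),
                                      sep = "=", collapse = ",")),
        metrics_row(cc)
      )
      book[[length(book) + 1L]] <- list(iteration = it, fold = k,
                                        outer_test = test_idx,
                                        selection = train_idx)
    }
  }
  structure(list(results = dplyr::bind_rows(rows), model = model,
                 scheme = "intra", folds = folds, iterations = iterations,
                 seed = seed, feature_cols = feature_cols,
                 bookkeeping = book),
            class = "limbuse_cv")
}

#' Inter-subject (leave-one-subject-out) cross-validation
#'
#' For each subject, trains on all other subjects (hyper-parameters chosen
#' with each training subject serving as the validation set once) and
#' evaluates on the held-out subject.
#'
#' @param table combined window table with a `subject` column (at least 3
#'   subjects).
#' @inheritParams train_eval_intra
#' @return an object of class `limbuse_cv` with one result row per subject.
#' @export
train_eval_inter <- function(table, model = c("rf", "svm", "mlp"),
                             seed = 1, feature_cols = NULL,
                             grids = ml_grids()) {
  model <- match.arg(model)
  if (!"subject" %in% names(table)) abort("table must have a subject column")
  subjects <- unique(table$subject)
  if (length(subjects) < 3L) abort("inter-subject evaluation needs at least 3 subjects")
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names, names(table))
  x <- as.matrix(table[, feature_cols])
  y <- table$label
  set.seed(seed)
  rows <- list(); book <- list()
  for (s in subjects) {
    test_idx <- which(table$subject == s)
    train_idx <- which(table$subject != s)
    train_subj <- table$subject[train_idx]
    fold_id <- match(table$subject, unique(train_subj))  # NA for held-out
    params <- select_params(model, x, y, fold_id,
                            seq_along(unique(train_subj)), grids)
    params$fit_seed <- sample.int(1e9, 1)
    pred <- fit_predict(model, x[train_idx, , drop = FALSE], y[train_idx],
                        x[test_idx, , drop = FALSE], params)
    cc <- confusion_counts(pred, y[test_idx])
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(subject = s,
                     params = paste(names(params)[names(params) != "fit_seed"],
                                    unlist(params[names(params) != "fit_seed"]),
                                    sep = "=", collapse = ",")),
      metrics_row(cc)
    )
    book[[length(book) + 1L]] <- list(subject = s, outer_test = test_idx,
                                      selection = train_idx)
  }
  structure(list(results = dplyr::bind_rows(rows), model = model,
                 scheme = "inter", seed = seed, feature_cols = feature_cols,
                 bookkeeping = book),
            class = "limbuse_cv")
}

#' Fit a random forest on a window table
#'
#' @param table window table with features and `label`.
#' @param feature_cols feature subset (default: all 11).
#' @param num_trees number of trees.
#' @param seed integer seed.
#' @return a `ranger` fit with impurity (Gini) importance.
#' @export
fit_rf <- function(table, feature_cols = NULL, num_trees = 100, seed = 1) {
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names, names(table))
  ranger::ranger(
    x = as.matrix(table[, feature_cols]),
    y = factor(table$label, levels = c(0, 1)),
    num.trees = num_trees, importance = "impurity",
    seed = seed, num.threads = 1
  )
}

#' Normalised Gini importances of a fitted random forest
#'
#' @param fit a `ranger` fit trained with impurity importance, e.g. from
#'   [fit_rf()].
#' @return tibble `feature`, `importance` (summing to 1), in descending
#'   order of importance.
#' @export
gini_importances <- function(fit) {
  if (!inherits(fit, "ranger") || is.null(fit$variable.importance)) {
    abort("need a fitted ranger forest with impurity importance (see fit_rf())")
  }
  imp <- fit$variable.importance
  tibble::tibble(feature = names(imp),
                 importance = as.numeric(imp) / sum(imp)) %>%
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Evaluate reduced feature-subset models
#'
#' Reruns the cross-validation protocol restricted to each feature subset
#' (by default the 1-, 3-, 6- and 11-feature sets of [feature_sets()]),
#' with identical seeds so the full subset reproduces the unrestricted run.
#'
#' @param table window table (intra scheme: one subject-arm; inter scheme:
#'   combined with `subject` column).
#' @param subsets named list of feature-name vectors or names of
#'   [feature_sets()] entries.
#' @param model,scheme model and evaluation scheme.
#' @inheritParams train_eval_intra
#' @return a named list of `limbuse_cv` objects, one per subset.
#' @export
reduced_model_eval <- function(table, subsets = feature_sets(),
                               model = "rf", scheme = c("intra", "inter"),
                               folds = 5, iterations = 10, seed = 1,
                               grids = ml_grids()) {
  scheme <- match.arg(scheme)
  if (is.character(subsets)) {
    known <- feature_sets()
    bad <- setdiff(subsets, names(known))
    if (length(bad) > 0L) abort(paste0("unknown feature subset(s): ",
                                       paste(bad, collapse = ", ")))
    subsets <- known[subsets]
  }
  lapply(subsets, function(fc) {
    if (scheme == "intra") {
      train_eval_intra(table, model = model, folds = folds,
                       iterations = iterations, seed = seed,
                       feature_cols = fc, grids = grids)
    } else {
      train_eval_inter(table, model = model, seed = seed,
                       feature_cols = fc, grids = grids)
    }
  })
}
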