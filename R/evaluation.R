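# Ground-truth comparison and measure-family statistics: confusion counts
# on a common 50 Hz grid, the Youden index, ANOVA across measure families,
# feature-correlate interpretation, and the two data-factor experiments.

#' Confusion counts of a binary use signal against ground truth
#'
#' The (lower-rate) use signal is aligned to the ground-truth grid by
#' zero-order hold and compared sample-wise over the overlapping span.
#'
#' @param use tibble `time`, `use` (binary, any rate).
#' @param gt tibble `time`, `label` (binary, evaluation grid, typically
#'   50 Hz).
#' @return a one-row tibble with `tp, fp, tn, fn`, `sensitivity`,
#'   `specificity` and `youden`.
#' @export
confusion <- function(use, gt) {
  lo <- max(min(use$time) - 1, min(gt$time))
  hi <- min(max(use$time), max(gt$time))
  sel <- gt$time >= lo & gt$time <= hi
  if (!any(sel)) abort("use signal and ground truth do not overlap in time")
  g <- gt[sel, ]
  idx <- findInterval(g$time, use$time)
  first <- idx >= 1L
  # before the first use sample, hold the first value backwards over the
  # window it summarises
  idx[!first] <- 1L
  u <- use$use[idx]
  metrics_row(confusion_counts(u, g$label))
}

#' Youden's J statistic
#'
#' `sensitivity + specificity - 1`: 1 for a perfect classifier, 0 for a
#' chance-level one, -1 for an always-wrong one.
#'
#' @param sensitivity,specificity values in \[0, 1\] (vectorised).
#' @return numeric vector of Youden indices in \[-1, 1\].
#' @export
youden <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 |
            specificity < 0 | specificity > 1, na.rm = TRUE)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Compare Youden indices across measure families
#'
#' One-way ANOVA across the groups followed by all pairwise Welch t-tests
#' with Bonferroni correction.
#'
#' @param data data frame with one observation per row.
#' @param value name of the numeric column (default `"youden"`).
#' @param group name of the grouping column (default `"family"`).
#' @return list with `anova` (one-row tibble: `F`, `p`) and `pairwise`
#'   (tibble: `group1`, `group2`, `t`, `p`, `p_bonferroni`).
#' @export
compare_measure_groups <- function(data, value = "youden", group = "family") {
  y <- data[[value]]
  g <- factor(data[[group]])
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort("every group needs at least 2 values for the ANOVA")
  }
  fit <- aov(y ~ g)
  s <- summary(fit)[[1]]
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- dplyr::bind_rows(lapply(pairs, function(p) {
    tt <- stats::t.test(y[g == p[1]], y[g == p[2]])
    tibble::tibble(group1 = p[1], group2 = p[2],
                   t = unname(tt$statistic), p = tt$p.value,
                   p_bonferroni = min(1, m * tt$p.value))
  }))
  list(
    anova = tibble::tibble(F = s$`F value`[1], p = s$`Pr(>F)`[1]),
    pairwise = pw
  )
}

#' Spearman correlations between window features and measure variables
#'
#' Correlates each feature column with each interpretable variable (window
#' mean pitch, yaw range, activity counts, ...).  Constant columns yield an
#' undefined (NA) correlation with a warning.
#'
#' @param features data frame of window features (rows = windows).
#' @param variables data frame of window variables on the same rows.
#' @return a tibble in long form: `feature`, `variable`, `rho`.
#' @export
feature_correlates <- function(features, variables) {
  if (nrow(features) != nrow(variables)) {
    abort("features and variables must describe the same windows")
  }
  out <- tidyr::expand_grid(feature = names(features),
                            variable = names(variables))
  out$rho <- purrr::map2_dbl(out$feature, out$variable, function(f, v) {
    x <- features[[f]]; y <- variables[[v]]
    ok <- is.finite(x) & is.finite(y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(paste0("constant column in pair (", f, ", ", v,
                  "); correlation undefined"))
      return(NA_real_)
    }
    cor(x[ok], y[ok], method = "spearman")
  })
  out
}

#' Per-window variables used by the traditional measures
#'
#' For each window of a feature table, computes the mean forearm pitch, the
#' yaw range, and the activity counts (zero-order-held from the 1 Hz counts
#' signal), for correlating against the window features.
#'
#' @param table window table from [build_window_table()].
#' @param orientation orientation tibble ([estimate_orientation()]).
#' @param counts tibble `time`, `counts` at 1 Hz.
#' @param window_s window length in seconds.
#' @return tibble with `mean_pitch`, `yaw_range`, `counts`, one row per
#'   window of `table`.
#' @export
window_variables <- function(table, orientation, counts, window_s = 0.25) {
  yaw <- unwrap_deg(orientation$yaw)
  res <- lapply(table$win_start, function(t0) {
    sel <- orientation$time >= t0 - 1e-9 & orientation$time < t0 + window_s - 1e-9
    c(mean_pitch = mean(orientation$pitch[sel]),
      yaw_range = diff(range(yaw[sel])))
  })
  ci <- findInterval(table$win_start + window_s / 2, counts$time)
  cnt <- ifelse(ci >= 1, counts$counts[pmax(1L, ci)], NA_real_)
  tibble::tibble(
    mean_pitch = vapply(res, `[[`, numeric(1), "mean_pitch"),
    yaw_range = vapply(res, `[[`, numeric(1), "yaw_range"),
    counts = cnt
  )
}

#' Regress classifier performance on the proportion of functional data
#'
#' Ordinary least-squares fits of per-subject sensitivity and specificity
#' against the percentage of functional data, with t-tests on the slopes.
#'
#' @param data data frame with columns `pct_functional`, `sensitivity`,
#'   `specificity` (one row per subject or arm; at least 3 rows).
#' @return tibble `response`, `intercept`, `slope`, `p_value`.
#' @export
proportion_regression <- function(data) {
  if (nrow(data) < 3L) abort("need at least 3 subjects for the regression")
  fit_one <- function(resp) {
    fit <- lm(data[[resp]] ~ data$pct_functional)
    cf <- summary(fit)$coefficients
    tibble::tibble(response = resp, intercept = cf[1, 1], slope = cf[2, 1],
                   p_value = cf[2, 4])
  }
  dplyr::bind_rows(fit_one("sensitivity"), fit_one("specificity"))
}

#' Task presence/absence ablation
#'
#' Evaluates a random-forest classifier under the four compositions of a
#' task's presence in the training and testing data: present in both
#' (`tr.te`), absent from training only (`tr_.te`), absent from testing
#' only (`tr.te_`), absent from both (`tr_.te_`).  Windows labelled with an
#' unknown task are excluded.  The same stratified fold split is reused
#' across conditions; metrics are pooled over the outer folds.
#'
#' @param table window table with a `task` column.
#' @param task the task label to ablate.
#' @param folds number of folds.
#' @param num_trees random-forest size.
#' @param seed integer seed.
#' @param feature_cols feature subset (default: all 11).
#' @return tibble `task`, `condition`, `sensitivity`, `specificity` with
#'   exactly four rows.
#' @export
task_ablation <- function(table, task, folds = 5, num_trees = 100,
                          seed = 1, feature_cols = NULL) {
  if (!"task" %in% names(table)) abort("window table must have a task column")
  table <- table[table$task != "unknown", ]
  if (!any(table$task == task)) {
    abort(paste0("task '", task, "' is not present in the data"))
  }
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names, names(table))
  x <- as.matrix(table[, feature_cols])
  y <- table$label
  is_task <- table$task == task
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  conditions <- c("tr.te", "tr_.te", "tr.te_", "tr_.te_")
  rows <- lapply(conditions, function(cond) {
    drop_train <- cond %in% c("tr_.te", "tr_.te_")
    drop_test <- cond %in% c("tr.te_", "tr_.te_")
    cc <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (k in seq_len(folds)) {
      tr <- which(fold_id != k & !(drop_train & is_task))
      te <- which(fold_id == k & !(drop_test & is_task))
      if (length(te) == 0L || length(unique(y[tr])) < 2L) next
      pred <- fit_predict("rf", x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE],
                          list(num_trees = num_trees,
                               fit_seed = sample.int(1e9, 1)))
      cc <- cc + confusion_counts(pred, y[te])
    }
    m <- metrics_row(cc)
    tibble::tibble(task = task, condition = cond,
                   sensitivity = m$sensitivity, specificity = m$specificity)
  })
  dplyr::bind_rows(rows)
}
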