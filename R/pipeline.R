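# End-to-end pipelines chaining the modules: preprocessing, per-arm use
# signals for every measure, cohort-level evaluation, and the
# machine-learning window tables.

#' Preprocess a raw arm recording
#'
#' Applies the standard preparation steps: rest-period detection,
#' gyroscope offset correction, and median filtering of the accelerometer.
#'
#' @param recording arm recording tibble.
#' @param rest_min_duration,rest_variance_threshold rest-detection
#'   parameters, see [detect_rest_periods()].
#' @return the corrected recording tibble.
#' @export
preprocess_recording <- function(recording, rest_min_duration = 10,
                                 rest_variance_threshold = 0.15) {
  rest <- detect_rest_periods(recording, rest_min_duration,
                              rest_variance_threshold)
  recording %>%
    correct_gyro_offset(rest) %>%
    median_filter_accel()
}

#' Compute every measure's use signal for one arm
#'
#' @param recording preprocessed arm recording.
#' @param measures subset of `c("vm", "gm", "gmac", "ac")`; the
#'   activity-count (`ac`) use signal additionally needs the other arm and
#'   is computed by [evaluate_measures()] at the subject level, so here
#'   `ac` yields the counts signal only.
#' @param config parameter list, see [limbuse_config()].
#' @return a list with the orientation series, the counts signals and the
#'   binary use signals that can be computed from one arm.
#' @export
arm_measures <- function(recording, measures = c("vm", "gm", "gmac", "ac"),
                         config = limbuse_config()) {
  p <- config$measures
  out <- list()
  orient <- estimate_orientation(recording, algorithm = "madgwick",
                                 use_mag = FALSE,
                                 beta = config$orientation$beta)
  out$orientation <- orient
  if (any(c("vm", "gmac") %in% measures)) {
    out$vm_counts <- vector_magnitude_counts(
      recording, deadband_threshold = p$deadband,
      beta = config$orientation$beta)
    if ("vm" %in% measures) out$vm <- vm_use(out$vm_counts)
    if ("gmac" %in% measures) {
      out$gmac <- gmac_use(out$vm_counts, orient[, c("time", "pitch")],
                           pitch_limit = p$pitch_limit)
    }
  }
  if ("gm" %in% measures) {
    out$gm <- gm_use(orient, angle_threshold = p$angle_threshold,
                     pitch_limit = p$pitch_limit)
  }
  if ("ac" %in% measures) {
    out$ac_counts <- activity_counts(recording, step = p$quantize_step,
                                     kp = config$orientation$kp,
                                     ki = config$orientation$ki)
  }
  out
}

dominant_arm <- function(arms) {
  if ("right" %in% arms) "right" else if ("unaffected" %in% arms) "unaffected"
  else arms[1]
}

#' Evaluate the traditional measures over a cohort dataset
#'
#' For every subject and arm: preprocesses the recording, computes the
#' requested use signals, derives the consensus ground truth from the four
#' annotation tracks, and reports confusion counts, sensitivity,
#' specificity and Youden index.  The activity-count measure is resolved at
#' the subject level through the laterality index of the two arms' counts.
#'
#' @param dataset dataset tibble (see [read_imu_dataset()]).
#' @param measures subset of `c("vm", "gm", "gmac", "ac")`.
#' @param config parameter list, see [limbuse_config()].
#' @return a tibble of class `limbuse_eval`: one row per subject, arm and
#'   measure.
#' @export
evaluate_measures <- function(dataset, measures = c("vm", "gm", "gmac", "ac"),
                              config = limbuse_config()) {
  arms <- dataset_arms(dataset)
  rows <- list()
  for (s in unique(arms$subject)) {
    sub <- arms[arms$subject == s, ]
    per_arm <- list()
    for (j in seq_len(nrow(sub))) {
      rec <- preprocess_recording(
        sub$recording[[j]],
        rest_min_duration = config$orientation$rest_min_duration,
        rest_variance_threshold = config$orientation$rest_variance_threshold)
      per_arm[[sub$arm[j]]] <- list(
        measures = arm_measures(rec, measures, config),
        gt = consensus_ground_truth(sub$recording[[j]]),
        group = sub$group[j])
    }
    if ("ac" %in% measures && length(per_arm) == 2L) {
      dom <- dominant_arm(names(per_arm))
      non <- setdiff(names(per_arm), dom)
      lat <- laterality_use(per_arm[[dom]]$measures$ac_counts,
                            per_arm[[non]]$measures$ac_counts,
                            threshold = config$measures$laterality_threshold)
      per_arm[[dom]]$measures$ac <-
        tibble::tibble(time = lat$time, use = lat$use_dominant)
      per_arm[[non]]$measures$ac <-
        tibble::tibble(time = lat$time, use = lat$use_nondominant)
    }
    for (arm in names(per_arm)) {
      pa <- per_arm[[arm]]
      for (m in measures) {
        if (is.null(pa$measures[[m]])) next
        cm <- confusion(pa$measures[[m]], pa$gt)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(subject = s, group = pa$group, arm = arm,
                         measure = m),
          cm)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("limbuse_eval", class(out))
  out
}

#' Build machine-learning window tables for a whole dataset
#'
#' Preprocesses each arm, derives the consensus ground truth, and extracts
#' the per-window feature table, keeping subject/arm/task metadata.
#'
#' @param dataset dataset tibble.
#' @param window_s feature window length in seconds.
#' @param gyro_features include gyroscope mean/variance features.
#' @return one combined window table (tibble).
#' @export
ml_window_tables <- function(dataset, window_s = 0.25,
                             gyro_features = FALSE) {
  arms <- dataset_arms(dataset)
  tabs <- lapply(seq_len(nrow(arms)), function(j) {
    rec <- arms$recording[[j]]
    gt <- consensus_ground_truth(rec)
    rec2 <- preprocess_recording(rec)
    rec2$subject <- arms$subject[j]
    rec2$group <- arms$group[j]
    rec2$arm <- arms$arm[j]
    rec2$task <- rec$task
    rec2$movement_type <- rec$movement_type
    build_window_table(rec2, gt, window_s = window_s,
                       gyro_features = gyro_features)
  })
  dplyr::bind_rows(tabs)
}

#' Intra-subject machine-learning evaluation over a cohort
#'
#' Runs [train_eval_intra()] per subject and arm and returns one summary
#' row per subject-arm (mean over iterations and folds).
#'
#' @param tables combined window table from [ml_window_tables()].
#' @inheritParams train_eval_intra
#' @return tibble `subject`, `arm`, `sensitivity`, `specificity`, `youden`
#'   (means over outer-test folds).
#' @export
evaluate_ml_intra <- function(tables, model = "rf", folds = 5,
                              iterations = 10, seed = 1,
                              feature_cols = NULL, grids = ml_grids()) {
  keys <- dplyr::distinct(tables, .data$subject, .data$arm)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    tab <- tables[tables$subject == keys$subject[i] &
                    tables$arm == keys$arm[i], ]
    cv <- train_eval_intra(tab, model = model, folds = folds,
                           iterations = iterations,
                           seed = seed + i, feature_cols = feature_cols,
                           grids = grids)
    g <- glance(cv)
    tibble::tibble(subject = keys$subject[i], arm = keys$arm[i],
                   sensitivity = g$mean_sensitivity,
                   specificity = g$mean_specificity,
                   youden = g$mean_youden)
  })
  dplyr::bind_rows(rows)
}
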