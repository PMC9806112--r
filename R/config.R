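# YAML-backed run configuration.  The defaults reproduce the measures'
# published parameters: 0.017 g quantization, 0.068 g dead-band, 30 deg
# angle threshold and functional pitch band, +/-0.95 laterality threshold,
# 0.25 s feature windows, 5 outer folds, 10 iterations.

config_defaults <- function() {
  list(
    seed = 1,
    orientation = list(
      beta = 0.1, kp = 1, ki = 0.3,
      rest_min_duration = 10, rest_variance_threshold = 0.15
    ),
    measures = list(
      deadband = 0.068, quantize_step = 0.017,
      angle_threshold = 30, pitch_limit = 30,
      laterality_threshold = 0.95
    ),
    ml = list(
      window_s = 0.25, folds = 5, iterations = 10,
      model = "rf", scheme = "intra",
      rf_trees = c(10, 50, 100, 200),
      svm_cost = c(0.1, 1, 10, 100),
      svm_gamma = c(0.001, 0.01, 0.1, 1),
      mlp_size = 16, mlp_decay = 1e-3, mlp_maxit = 200,
      gyro_features = FALSE
    ),
    simulate = list(
      n_subjects = 15, duration = 180, annotator_flip = 0.02,
      pitch_only = FALSE
    )
  )
}

merge_config <- function(defaults, overrides, path = character()) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown configuration key(s): ",
                 paste(paste(c(path, unknown[1]), collapse = "."),
                       collapse = ", ")))
  }
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    c(path, k))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Load the run configuration
#'
#' Returns the default parameter set, optionally overridden by a YAML file
#' with the same nested structure (sections `orientation`, `measures`,
#' `ml`, `simulate`, plus a top-level `seed`).  Unknown keys are rejected.
#'
#' @param path optional path to a YAML configuration file.
#' @return a nested configuration list.
#' @export
limbuse_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    overrides <- yaml::read_yaml(path)
    if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  }
  cfg
}

config_grids <- function(config) {
  list(rf_trees = config$ml$rf_trees,
       svm_cost = config$ml$svm_cost,
       svm_gamma = config$ml$svm_gamma,
       mlp_size = config$ml$mlp_size,
       mlp_decay = config$ml$mlp_decay,
       mlp_maxit = config$ml$mlp_maxit)
}

#' Run a pipeline command
#'
#' Thin programmatic equivalent of the command-line interface: `simulate`
#' writes a synthetic cohort CSV; `measures` computes every measure's use
#' signal for each subject and arm; `evaluate` scores the measures against
#' the consensus ground truth and writes JSON; `ml` runs the intra- or
#' inter-subject machine-learning protocol and writes JSON.
#'
#' @param command one of `"simulate"`, `"measures"`, `"evaluate"`, `"ml"`.
#' @param config configuration list from [limbuse_config()].
#' @param input input CSV path (ignored for `simulate`).
#' @param output output path (CSV for `simulate`/`measures`, JSON
#'   otherwise).
#' @param seed overrides the configuration seed.
#' @return the computed object, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "measures", "evaluate", "ml"),
                         config = limbuse_config(), input = NULL,
                         output = NULL, seed = NULL) {
  command <- match.arg(command)
  if (is.null(seed)) seed <- config$seed
  res <- switch(
    command,
    simulate = {
      data <- simulate_cohort(
        n_subjects = config$simulate$n_subjects,
        duration = config$simulate$duration,
        annotator_flip = config$simulate$annotator_flip,
        pitch_only = config$simulate$pitch_only,
        seed = seed)
      if (!is.null(output)) write_imu_dataset(data, output)
      data
    },
    measures = {
      data <- read_imu_dataset(input)
      arms <- dataset_arms(data)
      use <- dplyr::bind_rows(lapply(seq_len(nrow(arms)), function(j) {
        rec <- preprocess_recording(arms$recording[[j]])
        m <- arm_measures(rec, measures = c("vm", "gm", "gmac"),
                          config = config)
        dplyr::bind_rows(
          dplyr::mutate(m$vm, measure = "vm"),
          dplyr::mutate(m$gm, measure = "gm"),
          dplyr::mutate(m$gmac, measure = "gmac")
        ) %>%
          dplyr::mutate(subject = arms$subject[j], arm = arms$arm[j])
      }))
      if (!is.null(output)) readr::write_csv(use, output, progress = FALSE)
      use
    },
    evaluate = {
      data <- read_imu_dataset(input)
      ev <- evaluate_measures(data, config = config)
      if (!is.null(output)) {
        jsonlite::write_json(ev, output, digits = NA)
      }
      ev
    },
    ml = {
      data <- read_imu_dataset(input)
      tables <- ml_window_tables(data, window_s = config$ml$window_s,
                                 gyro_features = config$ml$gyro_features)
      res <- if (config$ml$scheme == "intra") {
        evaluate_ml_intra(tables, model = config$ml$model,
                          folds = config$ml$folds,
                          iterations = config$ml$iterations,
                          seed = seed, grids = config_grids(config))
      } else {
        tidy(train_eval_inter(tables, model = config$ml$model, seed = seed,
                              grids = config_grids(config)))
      }
      if (!is.null(output)) jsonlite::write_json(res, output, digits = NA)
      res
    }
  )
  invisible(res)
}
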