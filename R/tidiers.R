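# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
print.limbuse_cv <- function(x, ...) {
  cat("<limbuse_cv> ", x$model, " (", x$scheme, "-subject)\n", sep = "")
  if (x$scheme == "intra") {
    cat("  ", x$iterations, " iteration(s) x ", x$folds, " fold(s)\n", sep = "")
  } else {
    cat("  ", nrow(x$results), " held-out subject(s)\n", sep = "")
  }
  g <- glance(x)
  cat(sprintf("  mean sensitivity %.3f, specificity %.3f, Youden %.3f\n",
              g$mean_sensitivity, g$mean_specificity, g$mean_youden))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x a `limbuse_cv` object.
#' @param ... unused.
#' @return the per-fold (intra) or per-subject (inter) metrics tibble.
#' @export
tidy.limbuse_cv <- function(x, ...) {
  x$results
}

#' One-row summary of a cross-validation result
#'
#' @param x a `limbuse_cv` object.
#' @param ... unused.
#' @return tibble with the model, scheme, number of outer evaluations and
#'   mean sensitivity/specificity/Youden over outer-test folds.
#' @export
glance.limbuse_cv <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    model = x$model, scheme = x$scheme, n_evaluations = nrow(r),
    mean_sensitivity = mean(r$sensitivity, na.rm = TRUE),
    mean_specificity = mean(r$specificity, na.rm = TRUE),
    mean_youden = mean(r$youden, na.rm = TRUE)
  )
}

#' Plot cross-validated Youden indices
#'
#' @param object a `limbuse_cv` object.
#' @param ... unused.
#' @return a ggplot: Youden index per outer evaluation.
#' @export
autoplot.limbuse_cv <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = factor(1), y = .data$youden)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Youden index",
                  title = paste0(object$model, " (", object$scheme,
                                 "-subject)")) +
    ggplot2::theme_minimal()
}

#' Tidy a measure evaluation table
#'
#' @param x a `limbuse_eval` tibble from [evaluate_measures()].
#' @param ... unused.
#' @return the underlying tibble.
#' @export
tidy.limbuse_eval <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a measure evaluation by measure
#'
#' @param x a `limbuse_eval` tibble.
#' @param ... unused.
#' @return one row per measure with mean sensitivity, specificity and
#'   Youden index over subject-arms.
#' @export
glance.limbuse_eval <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::group_by(.data$measure) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      mean_youden = mean(.data$youden, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Sensitivity versus 1-specificity plot of measure performance
#'
#' Each point is one subject-arm under one measure; the dashed diagonal is
#' chance-level performance.
#'
#' @param object a `limbuse_eval` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.limbuse_eval <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity,
                                  colour = .data$measure)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Measure") +
    ggplot2::theme_minimal()
}

#' Boxplot of Youden indices by measure
#'
#' @param eval a `limbuse_eval` tibble.
#' @return a ggplot object.
#' @export
plot_youden <- function(eval) {
  d <- tibble::as_tibble(eval)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure, y = .data$youden)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = "Measure", y = "Youden index") +
    ggplot2::theme_minimal()
}
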