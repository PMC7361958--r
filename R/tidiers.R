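#' Tidy a cross-validation result
#'
#' One row per fold with its held-out accuracy.
#'
#' @param x An `eeg_cv` from [kfold_cross_validate()].
#' @param ... Unused.
#' @return A tibble with columns `fold`, `accuracy`, `n_test`.
#' @export
tidy.eeg_cv <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k),
                 accuracy = x$fold_accuracies,
                 n_test = as.integer(tabulate(x$folds, nbins = x$k)))
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.eeg_cv
#' @return A tibble with the classifier kind, fold count, mean and
#'   across-fold standard deviation of accuracy (percent), total rows and
#'   total correct held-out predictions.
#' @export
glance.eeg_cv <- function(x, ...) {
  tibble::tibble(classifier = x$spec$kind, k = x$k,
                 mean_accuracy = x$mean_accuracy,
                 std_accuracy = x$std_accuracy,
                 n = x$n,
                 n_correct = sum(diag(x$confusion)))
}

#' Tidy a grid of cross-validation results
#'
#' @param x An `eeg_grid` from [run_grid()].
#' @param ... Unused.
#' @return The grid without its `cv` list-column.
#' @export
tidy.eeg_grid <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$cv <- NULL
  out
}

#' Confusion matrix of a cross-validation result as a tibble
#'
#' @param x An `eeg_cv`.
#' @return Long tibble with columns `truth`, `predicted`, `n`.
#' @export
cv_confusion <- function(x) {
  stopifnot(inherits(x, "eeg_cv"))
  out <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(out) <- c("truth", "predicted", "n")
  tibble::as_tibble(out)
}

#' Plot per-fold accuracies
#'
#' @param object An `eeg_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "fold", y = "held-out accuracy (%)",
                  title = sprintf("%s, %d-fold CV: %.1f%% ± %.1f%%",
                                  object$spec$kind, object$k,
                                  object$mean_accuracy, object$std_accuracy)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a statistic-by-classifier accuracy grid
#'
#' @param object An `eeg_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_grid <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$classifier, y = .data$statistic,
                                  fill = .data$mean_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f±%.1f", .data$mean_accuracy, .data$std_accuracy)
    ), color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "accuracy (%)") +
    ggplot2::labs(x = "classifier", y = "sub-band statistic") +
    ggplot2::theme_minimal()
}

#' Plot two feature dimensions by class
#'
#' Scatter of two columns of a feature table, colored by class label; the
#' conventional way to eyeball how separable the extracted statistics are.
#'
#' @param features Feature tibble from [extract_features()].
#' @param x,y Feature column names; defaults to the first two feature
#'   columns.
#' @return A ggplot object.
#' @export
plot_features <- function(features, x = NULL, y = NULL) {
  fc <- feature_cols(features)
  x <- x %||% fc[1]
  y <- y %||% fc[2]
  ggplot2::ggplot(features, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                         color = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(color = "class") +
    ggplot2::theme_minimal()
}
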