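#' Specify a classifier
#'
#' The four classifiers of the workflow: linear discriminant analysis
#' (`"lda"`), linear support-vector machine with one-vs-all fusion for more
#' than two classes (`"svm_linear_ova"`), k-nearest neighbors (`"knn"`,
#' k = 5 by convention) and a single-hidden-layer neural network (`"ann"`,
#' 5 hidden nodes, early stopping on a held-out slice of the training fold).
#'
#' Feature standardization (train-fold z-score) defaults to on for the
#' distance- and margin-based methods (svm/knn/ann) and off for lda, which
#' is scale-equivariant.
#'
#' @param kind One of `"lda"`, `"svm_linear_ova"`, `"knn"`, `"ann"`.
#' @param k_neighbors Neighborhood size for knn (default 5).
#' @param hidden_nodes Hidden-layer width for ann (default 5).
#' @param max_epochs Training-epoch budget for ann.
#' @param max_iter Iteration bound for iterative backends. The libsvm solver
#'   behind the linear SVM exposes a convergence tolerance rather than an
#'   iteration cap; `svm_tolerance` is derived from this field.
#' @param cost Soft-margin cost for the linear SVM.
#' @param standardize `TRUE`/`FALSE`, or `NULL` for the per-kind default.
#' @param seed Integer seed for any stochastic initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "svm_linear_ova", "knn", "ann"),
                            k_neighbors = 5L, hidden_nodes = 5L,
                            max_epochs = 300L, max_iter = 10000L, cost = 1,
                            standardize = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (k_neighbors < 1) abort("`k_neighbors` must be >= 1.",
                             class = "eegdx_parameter_error")
  if (hidden_nodes < 1) abort("`hidden_nodes` must be >= 1.",
                              class = "eegdx_parameter_error")
  if (is.null(standardize)) standardize <- kind != "lda"
  structure(list(kind = kind, k_neighbors = as.integer(k_neighbors),
                 hidden_nodes = as.integer(hidden_nodes),
                 max_epochs = as.integer(max_epochs),
                 max_iter = as.integer(max_iter), cost = cost,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "classifier_spec")
}

as_classifier_spec <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

# fixed class order: known diagnostic labels first, anything else sorted
class_factor <- function(labels, levels = NULL) {
  if (is.null(levels)) {
    u <- unique(as.character(labels))
    levels <- c(intersect(CLASS_LABELS, u), sort(setdiff(u, CLASS_LABELS)))
  }
  factor(as.character(labels), levels = levels)
}

split_features <- function(features, labels = NULL) {
  if (is.data.frame(features)) {
    fc <- feature_cols(features)
    X <- as.matrix(features[fc])
    y <- labels %||% features$class_label
  } else {
    X <- as.matrix(features)
    y <- labels
  }
  if (is.null(y)) abort("labels are required for training.",
                        class = "eegdx_contract_error")
  list(X = X, y = class_factor(y))
}

standardizer <- function(X, enabled) {
  if (!enabled) return(list(center = NULL, scale = NULL))
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(center = colMeans(X), scale = s)
}

apply_standardizer <- function(X, std) {
  if (is.null(std$center)) return(X)
  scale(X, center = std$center, scale = std$scale)
}

#' Train a classifier on a feature table
#'
#' @param spec A [classifier_spec()] (or a kind name).
#' @param features Feature tibble from [extract_features()] (its
#'   `class_label` column supplies the labels), or a numeric matrix together
#'   with `labels`.
#' @param labels Optional label vector overriding `features$class_label`.
#' @return An object of class `eeg_model` with a [predict()] method.
#' @export
train_classifier <- function(spec, features, labels = NULL) {
  spec <- as_classifier_spec(spec)
  d <- split_features(features, labels)
  X <- d$X; y <- droplevels(d$y)
  if (anyNA(X) || !all(is.finite(X))) {
    abort("validation error: features must be finite.",
          class = "eegdx_validation_error")
  }
  if (nlevels(y) < 2) {
    abort("training error: need at least 2 classes.",
          class = "eegdx_training_error")
  }
  std <- standardizer(X, spec$standardize)
  Xs <- apply_standardizer(X, std)
  fit <- switch(spec$kind,
    lda = MASS::lda(Xs, grouping = y),
    svm_linear_ova = train_svm_ova(Xs, y, spec),
    knn = list(X = Xs, y = y),
    ann = train_ann(Xs, y, spec)
  )
  structure(list(spec = spec, fit = fit, classes = levels(y),
                 std = std, p = ncol(X),
                 feature_names = colnames(X)),
            class = "eeg_model")
}

train_svm_ova <- function(X, y, spec) {
  classes <- levels(y)
  machines <- lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(X, yb, kernel = "linear", scale = FALSE,
                      cost = spec$cost, tolerance = max(1e-3, 1 / spec$max_iter))
    dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
    flip <- mean(dv[y == cl]) < mean(dv[y != cl])   # orient: positive = target
    list(fit = fit, flip = flip)
  })
  names(machines) <- classes
  machines
}

svm_ova_decision <- function(machines, X) {
  vapply(machines, function(m) {
    dv <- attr(predict(m$fit, X, decision.values = TRUE), "decision.values")[, 1]
    if (m$flip) -dv else dv
  }, numeric(nrow(X)))
}

train_ann <- function(X, y, spec) {
  classes <- levels(y)
  Y <- nnet::class.ind(y)
  n <- nrow(X)
  # stratified 10% early-stopping split of the training data
  val <- withr::with_seed(spec$seed, {
    unlist(lapply(split(seq_len(n), y), function(idx) {
      nv <- floor(length(idx) * 0.1)
      if (nv >= 1 && length(idx) - nv >= 1) sample(idx, nv) else integer()
    }), use.names = FALSE)
  })
  use_es <- length(val) >= nlevels(y) && all(table(y[-val]) >= 1)
  tr <- if (use_es) setdiff(seq_len(n), val) else seq_len(n)
  chunk <- 25L
  patience <- 4L
  best <- NULL; best_loss <- Inf; since_best <- 0L
  wts <- NULL
  epochs <- 0L
  withr::with_seed(spec$seed, {
    while (epochs < spec$max_epochs) {
      args <- list(x = X[tr, , drop = FALSE], y = Y[tr, , drop = FALSE],
                   size = spec$hidden_nodes, softmax = TRUE,
                   maxit = min(chunk, spec$max_epochs - epochs),
                   decay = 1e-4, trace = FALSE, MaxNWts = 100000)
      if (!is.null(wts)) args$Wts <- wts
      net <- do.call(nnet::nnet, args)
      wts <- net$wts
      epochs <- epochs + chunk
      if (use_es) {
        p <- predict(net, X[val, , drop = FALSE])
        p <- pmax(p, 1e-12)
        loss <- -mean(log(p[cbind(seq_along(val), as.integer(y[val]))]))
      } else {
        loss <- net$value
      }
      if (loss < best_loss - 1e-8) {
        best_loss <- loss; best <- net; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break   # early stopping
      }
    }
  })
  list(net = best %||% net, classes = classes)
}

# deterministic knn: neighbors tied with the k-th distance all vote; vote
# ties go to the class with the nearer nearest neighbor, then class order
knn_predict <- function(fit, X, k) {
  trX <- fit$X; try_ <- fit$y
  classes <- levels(try_)
  d2 <- outer(rowSums(X^2), rep(1, nrow(trX))) +
    outer(rep(1, nrow(X)), rowSums(trX^2)) - 2 * X %*% t(trX)
  d2[d2 < 0] <- 0
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- d2[i, ]
    ord <- order(d, seq_along(d))
    kth <- d[ord[min(k, length(ord))]]
    nb <- which(d <= kth + 1e-12)
    votes <- table(factor(try_[nb], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      nearest <- vapply(top, function(cl) min(d[nb][try_[nb] == cl]), numeric(1))
      top <- top[nearest == min(nearest)]
    }
    out[i] <- top[1]   # fixed class order resolves any remaining tie
  }
  factor(out, levels = classes)
}

#' Predict class labels from a trained model
#'
#' @param object An `eeg_model` from [train_classifier()].
#' @param newdata Feature tibble (matching feature columns are selected by
#'   name) or a numeric matrix with the training dimensionality.
#' @param ... Unused.
#' @return Factor of predicted labels, levels = training classes.
#' @export
predict.eeg_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (all(object$feature_names %in% names(newdata))) {
      newdata <- as.matrix(newdata[object$feature_names])
    } else {
      newdata <- as.matrix(newdata[feature_cols(newdata)])
    }
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    abort(sprintf("dimension mismatch: model expects %d features, got %d.",
                  object$p, ncol(newdata)),
          class = "eegdx_contract_error")
  }
  X <- apply_standardizer(newdata, object$std)
  spec <- object$spec
  switch(spec$kind,
    lda = predict(object$fit, X)$class,
    svm_linear_ova = {
      dv <- svm_ova_decision(object$fit, X)
      factor(object$classes[max.col(dv, ties.method = "first")],
             levels = object$classes)
    },
    knn = knn_predict(object$fit, X, spec$k_neighbors),
    ann = {
      p <- predict(object$fit$net, X)
      factor(object$fit$classes[max.col(p, ties.method = "first")],
             levels = object$classes)
    }
  )
}

# fold assignment: stratified round-robin after a seeded shuffle; with
# groups, whole subjects are assigned to folds (stratified by subject class)
make_folds <- function(y, k, seed, stratified = TRUE, groups = NULL) {
  n <- length(y)
  if (k < 2) abort("`k` must be >= 2.", class = "eegdx_parameter_error")
  if (is.null(groups)) {
    if (stratified) {
      if (any(table(y) < k)) {
        small <- names(which(table(y) < k))
        abort(sprintf("fold error: class(es) %s have fewer than k = %d members; reduce k, disable stratification, or add data.",
                      paste(small, collapse = ", "), k),
              class = "eegdx_fold_error")
      }
      folds <- integer(n)
      withr::with_seed(seed, {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          folds[idx] <- rep_len(seq_len(k), length(idx))
        }
      })
    } else {
      folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    }
  } else {
    gclass <- vapply(split(as.character(y), groups),
                     function(v) names(sort(table(v), decreasing = TRUE))[1],
                     character(1))
    if (length(gclass) < k) {
      abort(sprintf("fold error: only %d subject group(s) for k = %d folds.",
                    length(gclass), k),
            class = "eegdx_fold_error")
    }
    gfold <- integer(length(gclass))
    names(gfold) <- names(gclass)
    withr::with_seed(seed, {
      counter <- 0L
      for (cl in unique(gclass)) {
        gs <- sample(names(gclass)[gclass == cl])
        gfold[gs] <- (counter + seq_along(gs) - 1L) %% k + 1L
        counter <- counter + length(gs)
      }
    })
    folds <- gfold[as.character(groups)]
  }
  as.integer(folds)
}

#' k-fold cross-validated accuracy
#'
#' Splits the rows into `k` folds (stratified by class by default, or by
#' subject when `group_folds = TRUE`), trains on k-1 folds and scores the
#' held-out fold, so every row is held out exactly once. Per-fold accuracy
#' is `100 * correct / held-out`, and the overall accuracy is the arithmetic
#' mean of the fold accuracies; the reported dispersion is the across-fold
#' standard deviation. Standardization parameters are computed on each
#' training fold only.
#'
#' @param features Feature tibble from [extract_features()].
#' @param spec A [classifier_spec()] or kind name.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold shuffle (and any classifier
#'   randomness).
#' @param stratified Keep per-fold class proportions within one sample of the
#'   global proportions (default `TRUE`).
#' @param group_folds Assign whole subjects to folds so no `subject_id`
#'   appears in both train and test of any fold.
#' @param folds Optional precomputed integer fold assignment (advanced; used
#'   by [run_grid()] to reuse one partition across cells).
#' @return An object of class `eeg_cv`: fold accuracies (percent), their
#'   mean and standard deviation, the pooled confusion matrix, and the
#'   resolved spec/seed/fold assignment. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
kfold_cross_validate <- function(features, spec = "knn", k = 10, seed = 1,
                                 stratified = TRUE, group_folds = FALSE,
                                 folds = NULL) {
  spec <- as_classifier_spec(spec)
  d <- split_features(features)
  y <- droplevels(d$y)
  if (nlevels(y) < 2) {
    abort("training error: need at least 2 classes.",
          class = "eegdx_training_error")
  }
  groups <- if (group_folds && is.data.frame(features)) features$subject_id
  if (is.null(folds)) {
    folds <- make_folds(y, k, seed, stratified = stratified, groups = groups)
  }
  k <- max(folds)
  spec <- utils::modifyList(spec, list(seed = as.integer(seed)))
  class(spec) <- "classifier_spec"
  fold_acc <- numeric(k)
  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(truth = levels(y), predicted = levels(y)))
  for (f in seq_len(k)) {
    te <- folds == f
    model <- train_classifier(spec, d$X[!te, , drop = FALSE], y[!te])
    pred <- predict(model, d$X[te, , drop = FALSE])
    fold_acc[f] <- 100 * mean(pred == y[te])
    confusion <- confusion + unclass(table(y[te], pred))
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 std_accuracy = stats::sd(fold_acc),
                 k = k, confusion = confusion, spec = spec, seed = seed,
                 n = length(y), classes = levels(y), folds = folds,
                 stratified = stratified, group_folds = group_folds),
            class = "eeg_cv")
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv> %s, %d-fold: %.2f%% +/- %.2f%% (n = %d, classes: %s)\n",
              x$spec$kind, x$k, x$mean_accuracy, x$std_accuracy, x$n,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Cross-validate a grid of feature statistics and classifiers
#'
#' Evaluates every (statistic, classifier) cell on the same fold partition,
#' selecting for each cell the feature columns of that statistic. Reusing
#' one partition makes the cells directly comparable.
#'
#' @param features Feature tibble from [extract_features()] containing
#'   columns for every requested statistic.
#' @param statistics Statistics to evaluate (default all five).
#' @param classifiers Classifier kinds or [classifier_spec()] objects.
#' @inheritParams kfold_cross_validate
#' @return A tibble of class `eeg_grid`, one row per cell, with columns
#'   `statistic`, `classifier`, `mean_accuracy`, `std_accuracy`, `k`,
#'   `seed` and a `cv` list-column of [eeg_cv][kfold_cross_validate] objects.
#' @export
run_grid <- function(features, statistics = STATISTICS,
                     classifiers = c("lda", "svm_linear_ova", "knn", "ann"),
                     k = 10, seed = 1, stratified = TRUE, group_folds = FALSE) {
  statistics <- match.arg(statistics, STATISTICS, several.ok = TRUE)
  y <- class_factor(features$class_label)
  y <- droplevels(y)
  groups <- if (group_folds) features$subject_id
  folds <- make_folds(y, k, seed, stratified = stratified, groups = groups)
  cells <- tidyr::expand_grid(statistic = statistics,
                              classifier_id = seq_along(classifiers))
  res <- purrr::pmap(cells, function(statistic, classifier_id) {
    spec <- as_classifier_spec(classifiers[[classifier_id]])
    cols <- cols_for_statistic(features, statistic)
    if (!length(cols)) {
      abort(paste0("config error: no feature columns for statistic ", statistic),
            class = "eegdx_config_error")
    }
    sub <- features[c("class_label", "subject_id", "segment_index", cols)]
    attr(sub, "feature_cols") <- cols
    cv <- kfold_cross_validate(sub, spec, k = k, seed = seed,
                               stratified = stratified,
                               group_folds = group_folds, folds = folds)
    tibble::tibble(statistic = statistic, classifier = spec$kind,
                   mean_accuracy = cv$mean_accuracy,
                   std_accuracy = cv$std_accuracy,
                   k = cv$k, seed = seed, cv = list(cv))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("eeg_grid", class(out))
  out
}
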