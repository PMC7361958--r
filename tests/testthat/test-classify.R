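blob_data <- function(n_per = 50, sep = 10, d = 2, classes = c("neurotypical", "epilepsy"),
                      seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(classes), function(i) {
      matrix(rnorm(n_per * d, mean = (i - 1) * sep), n_per, d)
    }))
    colnames(X) <- paste0("f", seq_len(d))
    cls <- rep(classes, each = n_per)
    tibble::tibble(class_label = cls,
                   subject_id = sprintf("%s_s%02d", cls,
                                        rep_len(rep(1:5, length.out = n_per),
                                                nrow(X))),
                   segment_index = seq_len(nrow(X)) - 1L) |>
      dplyr::bind_cols(tibble::as_tibble(X))
  })
}

test_that("all four classifiers separate well-separated Gaussian blobs", {
  d <- blob_data()
  X <- as.matrix(d[c("f1", "f2")])
  for (kind in c("lda", "svm_linear_ova", "knn", "ann")) {
    m <- train_classifier(kind, d)
    expect_equal(mean(as.character(predict(m, X)) == d$class_label), 1,
                 info = kind)
  }
})

test_that("1-NN resubstitution reproduces every training label", {
  d <- blob_data(sep = 2)
  m <- train_classifier(classifier_spec("knn", k_neighbors = 1), d)
  expect_equal(as.character(predict(m, as.matrix(d[c("f1", "f2")]))),
               d$class_label)
})

test_that("knn ties resolve by nearer neighbor, then fixed class order", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- train_classifier(classifier_spec("knn", k_neighbors = 1, standardize = FALSE),
                        X, labels = c("epilepsy", "autism"))
  # exact midpoint: both neighbors tie at distance 1 -> class order decides
  # (neurotypical < epilepsy < autism is the fixed order; only two present)
  expect_equal(as.character(predict(m, matrix(0, 1, 1))), "epilepsy")
  # off-center: the nearer neighbor wins
  expect_equal(as.character(predict(m, matrix(0.2, 1, 1))), "autism")
  expect_equal(as.character(predict(m, matrix(-0.2, 1, 1))), "epilepsy")
})

test_that("degenerate training inputs raise typed errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_classifier("lda", X, labels = rep("autism", 10)),
               class = "eegdx_training_error")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_classifier("knn", Xb, labels = rep(c("a", "b"), 5)),
               class = "eegdx_validation_error")
  m <- train_classifier("knn", X, labels = rep(c("a", "b"), 5))
  expect_error(predict(m, matrix(0, 1, 3)), class = "eegdx_contract_error")
})

test_that("perfectly separable one-hot features score 100% for every classifier", {
  n_per <- 20
  d <- tibble::tibble(
    class_label = rep(c("neurotypical", "epilepsy", "autism"), each = n_per),
    subject_id = "s", segment_index = 0L,
    f1 = rep(c(1, 0, 0), each = n_per),
    f2 = rep(c(0, 1, 0), each = n_per),
    f3 = rep(c(0, 0, 1), each = n_per))
  for (kind in c("svm_linear_ova", "knn")) {
    cv <- kfold_cross_validate(d, kind, k = 10, seed = 2)
    expect_equal(cv$mean_accuracy, 100, info = kind)
  }
})

test_that("fold partitions are disjoint, exhaustive and stratified", {
  d <- blob_data(n_per = 53, sep = 0)
  cv <- kfold_cross_validate(d, "knn", k = 10, seed = 5)
  expect_length(cv$folds, 106)
  expect_setequal(unique(cv$folds), 1:10)
  per_fold <- table(cv$folds, d$class_label)
  # stratification keeps per-fold class counts within one of each other
  expect_lte(diff(range(per_fold[, 1])), 1)
  expect_lte(diff(range(per_fold[, 2])), 1)
})

test_that("mean accuracy is exactly the arithmetic fold mean and the confusion trace counts correct predictions", {
  d <- blob_data(n_per = 40, sep = 1.2, seed = 9)
  cv <- kfold_cross_validate(d, "lda", k = 10, seed = 3)
  expect_identical(cv$mean_accuracy, mean(cv$fold_accuracies))
  fold_sizes <- tabulate(cv$folds, 10)
  total_correct <- sum(round(cv$fold_accuracies * fold_sizes / 100))
  expect_equal(sum(diag(cv$confusion)), total_correct)
  expect_equal(sum(cv$confusion), nrow(d))
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.vector(table(factor(d$class_label,
                                             levels = cv$classes)))))
})

test_that("leave-one-out produces n singleton folds", {
  d <- blob_data(n_per = 10)
  cv <- kfold_cross_validate(d, "knn", k = 20, seed = 1, stratified = FALSE)
  expect_equal(cv$k, 20)
  expect_equal(unname(tabulate(cv$folds, 20)), rep(1L, 20))
})

test_that("stratification errors when a class has fewer members than folds", {
  d <- blob_data(n_per = 5)
  expect_error(kfold_cross_validate(d, "knn", k = 10, seed = 1),
               class = "eegdx_fold_error")
})

test_that("label-permuted data scores at chance within three standard errors", {
  set.seed(17)
  n <- 200
  d <- blob_data(n_per = n / 2, sep = 8, seed = 4)
  d$class_label <- sample(d$class_label)   # break the feature-label link
  cv <- kfold_cross_validate(d, "knn", k = 10, seed = 6)
  se <- 100 * sqrt(0.25 / n)
  expect_lt(abs(cv$mean_accuracy - 50), 3 * se + 1e-9)
})

test_that("group-aware folding never splits a subject across train and test", {
  d <- blob_data(n_per = 60, sep = 3)
  cv <- kfold_cross_validate(d, "knn", k = 5, seed = 2, group_folds = TRUE)
  split_subjects <- split(d$subject_id, cv$folds)
  for (f in 1:5) {
    expect_length(intersect(split_subjects[[f]],
                            unlist(split_subjects[-f])), 0)
  }
})

test_that("standardization parameters come from the training fold only", {
  # a test-fold outlier must not influence the scaling of the training data:
  # train on rows 1..n-1 (mean 0), predict a huge point; with train-only
  # standardization the model still assigns it to the nearer training class
  set.seed(30)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  m <- train_classifier(classifier_spec("knn"), X, labels = y)
  expect_equal(as.character(predict(m, matrix(c(1e6, 1e6), 1, 2))), "b")
  expect_equal(m$std$center, colMeans(X))
})

test_that("the statistic-by-classifier grid shares folds and is reproducible", {
  spec <- sim_spec(classes = list(spec_neurotypical(), spec_epileptic()),
                   n_segments_per_class = 20, duration_s = 4, seed = 15)
  feats <- extract_features(generate_dataset(spec)$segments)
  g1 <- run_grid(feats, statistics = c("lbp", "entropy"),
                 classifiers = c("lda", "knn"), k = 5, seed = 7)
  expect_equal(nrow(g1), 4)
  expect_setequal(g1$statistic, c("lbp", "entropy"))
  # identical fold partition reused across cells
  folds <- lapply(g1$cv, `[[`, "folds")
  expect_true(all(vapply(folds, identical, logical(1), folds[[1]])))
  g2 <- run_grid(feats, statistics = c("lbp", "entropy"),
                 classifiers = c("lda", "knn"), k = 5, seed = 7)
  expect_identical(tidy(g1), tidy(g2))
  expect_error(run_grid(feats, statistics = "skew"))
})

test_that("tidy, glance and confusion accessors expose the cv result", {
  d <- blob_data(n_per = 25)
  cv <- kfold_cross_validate(d, "lda", k = 5, seed = 1)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_named(td, c("fold", "accuracy", "n_test"))
  gl <- glance(cv)
  expect_equal(gl$mean_accuracy, cv$mean_accuracy)
  expect_equal(gl$n_correct, sum(diag(cv$confusion)))
  cf <- cv_confusion(cv)
  expect_equal(sum(cf$n), nrow(d))
})
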