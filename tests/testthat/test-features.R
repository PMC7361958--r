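test_that("worked examples of the five statistics evaluate exactly", {
  expect_equal(feat_variance(c(1, 2, 3)), 2 / 3)           # population divisor
  expect_equal(feat_variance(rep(4.2, 10)), 0)
  expect_equal(feat_sd(c(1, 2, 3)), sqrt(2 / 3))
  expect_equal(feat_kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(feat_entropy(c(1, 1, 1)), 0)
  expect_equal(feat_entropy(0), 0)                         # 0 * log 0 = 0
  expect_equal(feat_entropy(2), 4 * log(4))
  expect_equal(feat_lbp(rep(1, 7)), 0)
  expect_equal(feat_lbp(c(3, 4)), log(12.5))
})

test_that("statistics match brute-force formula evaluation on random vectors", {
  set.seed(31)
  for (i in 1:50) {
    s <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 10))
    expect_equal(feat_variance(s), oracle_variance(s), tolerance = 1e-13)
    expect_equal(feat_sd(s), oracle_sd(s), tolerance = 1e-13)
    expect_equal(feat_kurtosis(s), oracle_kurtosis(s), tolerance = 1e-13)
    expect_equal(feat_entropy(s), oracle_entropy(s), tolerance = 1e-13)
    expect_equal(feat_lbp(s), oracle_lbp(s), tolerance = 1e-13)
  }
})

test_that("statistic identities and scaling laws hold", {
  set.seed(32)
  s <- rnorm(100)
  expect_equal(feat_variance(s), feat_sd(s)^2)
  expect_equal(feat_sd(-2.5 * s), 2.5 * feat_sd(s))
  expect_equal(feat_lbp(3 * s), feat_lbp(s) + 2 * log(3), tolerance = 1e-12)
  expect_equal(feat_kurtosis(5 * s + 2), feat_kurtosis(s), tolerance = 1e-12)
})

test_that("a large Gaussian sample has kurtosis near 3", {
  x <- withr::with_seed(7, rnorm(1e6))
  expect_equal(feat_kurtosis(x), 3, tolerance = 0.05 / 3)
})

test_that("degenerate inputs raise domain errors or honor the sentinel", {
  expect_error(feat_variance(numeric(0)), class = "eegdx_degenerate_error")
  expect_error(feat_kurtosis(c(5, 5, 5)), class = "eegdx_degenerate_error")
  expect_equal(feat_kurtosis(c(5, 5, 5), degenerate = "zero"), 0)
  expect_error(feat_lbp(rep(0, 4)), class = "eegdx_degenerate_error")
  expect_equal(feat_lbp(rep(0, 4), floor = -50), -50)
})

test_that("log base 10 rescales entropy and band power consistently", {
  s <- c(0.5, 2, -3)
  expect_equal(feat_entropy(s, base = 10), feat_entropy(s) / log(10))
  expect_equal(feat_lbp(s, base = 10), feat_lbp(s) / log(10))
})

test_that("feature vectors are ordered channel-major, then sub-band, then statistic", {
  seg <- eeg_segment(matrix(rnorm(2 * 1024), ncol = 2), fs = 256, duration_s = 4,
                     channel_labels = c("Fp1", "Fp2"))
  sb <- dwt_decompose(seg)
  fv <- build_feature_vector(sb, statistics = c("lbp", "entropy"))
  cols <- setdiff(names(fv), c("class_label", "subject_id", "segment_index"))
  expect_length(cols, 2 * 5 * 2)
  expect_equal(cols[1:4], c("Fp1_D1_lbp", "Fp1_D1_entropy",
                            "Fp1_D2_lbp", "Fp1_D2_entropy"))
  expect_equal(cols[11], "Fp2_D1_lbp")
  # single statistic, single channel: one value per sub-band
  fv1 <- build_feature_vector(dwt_decompose(eeg_segment(rnorm(1024), fs = 256,
                                                        duration_s = 4)),
                              statistics = "lbp")
  expect_length(setdiff(names(fv1), c("class_label", "subject_id", "segment_index")), 5)
})

test_that("a 23-channel segment with one statistic yields 115 features", {
  seg <- eeg_segment(matrix(rnorm(23 * 512), ncol = 23), fs = 256, duration_s = 2)
  fv <- build_feature_vector(dwt_decompose(seg), statistics = "entropy")
  expect_length(setdiff(names(fv), c("class_label", "subject_id", "segment_index")),
                115)
})

test_that("feature extraction propagates metadata and is deterministic", {
  spec <- sim_spec(classes = list(spec_neurotypical()), n_segments_per_class = 3,
                   duration_s = 4, seed = 8)
  segs <- generate_dataset(spec)$segments
  f1 <- extract_features(segs)
  f2 <- extract_features(segs)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 3)
  expect_equal(f1$class_label, rep("neurotypical", 3))
  expect_equal(f1$segment_index, 0:2)
  expect_length(attr(f1, "feature_cols"), 25)
  expect_true(all(is.finite(as.matrix(f1[attr(f1, "feature_cols")]))))
})

test_that("unknown sub-bands and statistics are config errors", {
  sb <- dwt_decompose(eeg_segment(rnorm(1024), fs = 256, duration_s = 4))
  expect_error(build_feature_vector(sb, subbands = c("D1", "D9")),
               class = "eegdx_config_error")
  expect_error(build_feature_vector(sb, statistics = "skew"))
  # zero segment: variance features are all zero, lbp would be degenerate
  zero <- dwt_decompose(eeg_segment(rep(0, 1024), fs = 256, duration_s = 4))
  fv <- build_feature_vector(zero, statistics = "variance")
  expect_true(all(as.matrix(fv[setdiff(names(fv),
    c("class_label", "subject_id", "segment_index"))]) == 0))
  expect_error(build_feature_vector(zero, statistics = "lbp"),
               class = "eegdx_degenerate_error")
})
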