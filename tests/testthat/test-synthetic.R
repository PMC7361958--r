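test_that("an alpha-only profile concentrates its power in 8-13 Hz", {
  sp <- class_spectrum_spec("neurotypical", band_powers = c(alpha = 1),
                            noise_rel_power = 0)
  seg <- generate_segment(sp, fs = 256, duration_s = 10, seed = 7)
  bp <- periodogram_band_powers(seg$samples[, 1], 256,
                                list(alpha = c(8, 13), rest = c(0, 128)))
  expect_gt(bp[["alpha"]] / bp[["rest"]], 0.9)
})

test_that("generation is a pure function of spec and seed", {
  sp <- spec_epileptic()
  s1 <- generate_segment(sp, n_channels = 2, duration_s = 5, seed = 42)
  s2 <- generate_segment(sp, n_channels = 2, duration_s = 5, seed = 42)
  s3 <- generate_segment(sp, n_channels = 2, duration_s = 5, seed = 43)
  expect_identical(s1$samples, s2$samples)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("spike trains raise the kurtosis of the signal", {
  base <- class_spectrum_spec("neurotypical",
                              band_powers = c(delta = 1, theta = 1, alpha = 1,
                                              beta = 1, gamma = 1))
  spiky <- class_spectrum_spec("epilepsy",
                               band_powers = base$band_powers, spike_rate_hz = 2)
  k0 <- feat_kurtosis(generate_segment(base, duration_s = 20, seed = 3)$samples[, 1])
  k1 <- feat_kurtosis(generate_segment(spiky, duration_s = 20, seed = 3)$samples[, 1])
  expect_gt(k1, k0)
})

test_that("realized band-power ratios track the requested profile", {
  sp <- class_spectrum_spec("autism",
                            band_powers = c(delta = 2, theta = 1, alpha = 0.5,
                                            beta = 0.8, gamma = 0.3),
                            noise_rel_power = 0)
  windows <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 60))
  req <- sp$band_powers / sum(sp$band_powers)
  real <- rowMeans(vapply(1:20, function(seed) {
    seg <- generate_segment(sp, fs = 256, duration_s = 8, seed = seed)
    p <- periodogram_band_powers(seg$samples[, 1], 256, windows)
    p / sum(p)
  }, numeric(5)))
  expect_equal(unname(real), unname(req), tolerance = 0.15)
})

test_that("datasets deliver the requested per-class segment counts and labels", {
  spec <- sim_spec(classes = list(spec_neurotypical(), spec_epileptic(),
                                  spec_autistic()),
                   n_segments_per_class = 4, duration_s = 2, seed = 9)
  ds <- generate_dataset(spec)
  expect_length(ds$segments, 12)
  expect_equal(nrow(ds$manifest), 12)
  expect_equal(unname(table(ds$manifest$class_label)[c("neurotypical", "epilepsy", "autism")]),
               rep(4L, 3), ignore_attr = TRUE)
  labs <- vapply(ds$segments, function(s) s$class_label, character(1))
  expect_equal(sort(unique(labs)), sort(c("neurotypical", "epilepsy", "autism")))
  expect_error(sim_spec(classes = list()), class = "eegdx_parameter_error")
})

test_that("blink planting adds an EOG channel carrying the blink train", {
  spec <- sim_spec(classes = list(spec_neurotypical()), n_segments_per_class = 1,
                   n_channels = 3, duration_s = 20, blink_rate_hz = 0.5, seed = 2)
  seg <- generate_dataset(spec)$segments[[1]]
  expect_equal(seg$channel_labels, c("ch1", "ch2", "ch3", "EOG"))
  # scalp channels correlate with the EOG reference through the shared blinks
  cors <- abs(cor(seg$samples[, 1:3], seg$samples[, "EOG"]))
  expect_gt(max(cors), 0.3)
})

test_that("widening the gamma gap between two classes never hurts recovery", {
  accs <- vapply(c(0.4, 1.0, 2.5), function(g) {
    a <- class_spectrum_spec("neurotypical",
                             band_powers = c(delta = 1, theta = 1, alpha = 1,
                                             beta = 1, gamma = 0.3))
    b <- class_spectrum_spec("autism",
                             band_powers = c(delta = 1, theta = 1, alpha = 1,
                                             beta = 1, gamma = g))
    ds <- generate_dataset(sim_spec(classes = list(a, b),
                                    n_segments_per_class = 30,
                                    duration_s = 5, seed = 77))
    feats <- extract_features(ds$segments, statistics = "lbp")
    kfold_cross_validate(feats, "knn", k = 5, seed = 5)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("band centers above Nyquist are rejected", {
  sp <- class_spectrum_spec("neurotypical", band_powers = c(gamma = 1))
  expect_error(generate_segment(sp, fs = 64, duration_s = 2, seed = 1),
               class = "eegdx_parameter_error")
  expect_error(class_spectrum_spec(band_powers = c(alpha = -1)),
               class = "eegdx_parameter_error")
  expect_error(class_spectrum_spec(spike_rate_hz = -2),
               class = "eegdx_parameter_error")
})
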