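test_that("realized elliptic band-pass meets its ripple and attenuation template", {
  spec <- design_elliptic_bandpass(256, 0.1, 60, passband_ripple_db = 0.5,
                                   stopband_atten_db = 40, order = 4)
  gain_db <- function(f) 20 * log10(Mod(filter_response(spec, f)))
  # passband within ripple of unity
  expect_gt(gain_db(30), -0.5 - 1e-6)
  expect_lt(gain_db(30), 1e-6)
  expect_gt(gain_db(10), -0.5 - 1e-6)
  # stopband at least the requested attenuation down
  expect_lt(gain_db(100), -40)
  expect_lt(gain_db(0.02), -40)
  expect_true(all(is.finite(spec$sos)))
})

test_that("high prototype orders remain stable in second-order-section form", {
  spec8 <- design_elliptic_bandpass(256, 0.1, 60, order = 8)
  gain_db <- function(f) 20 * log10(Mod(filter_response(spec8, f)))
  expect_lt(gain_db(80), -40)
  expect_gt(gain_db(20), -0.51)
  # a causal impulse response through the cascade must decay, not blow up
  imp <- eeg_segment(c(1, rep(0, 2559)), fs = 256, duration_s = 10)
  h <- apply_filter(imp, spec8, mode = "causal")$samples[, 1]
  expect_true(all(is.finite(h)))
  expect_lt(max(abs(tail(h, 200))), max(abs(h)))
})

test_that("design rejects invalid band edges and parameters", {
  expect_error(design_elliptic_bandpass(100, 0.1, 60), class = "eegdx_design_error")
  expect_error(design_elliptic_bandpass(256, 60, 0.1), class = "eegdx_parameter_error")
  expect_error(design_elliptic_bandpass(256, 0.1, 60, passband_ripple_db = 0),
               class = "eegdx_parameter_error")
  expect_error(design_elliptic_bandpass(256, 0.1, 60, stopband_atten_db = -3),
               class = "eegdx_parameter_error")
})

test_that("band-pass passes 10 Hz and suppresses 80 Hz tones in the time domain", {
  spec <- design_elliptic_bandpass(256)
  mid <- 640:1920                      # trim edge transients
  s80 <- tone_segment(80)
  s10 <- tone_segment(10)
  r80 <- rms(apply_filter(s80, spec)$samples[mid, 1]) / rms(s80$samples[mid, 1])
  r10 <- rms(apply_filter(s10, spec)$samples[mid, 1]) / rms(s10$samples[mid, 1])
  expect_lt(r80, 0.10)
  # zero-phase filtering applies the magnitude response twice
  expect_gt(r10, 10^(-2 * 0.5 / 20) - 0.01)
  expect_lt(r10, 1.01)
})

test_that("filtering is linear and preserves shape and metadata", {
  spec <- design_elliptic_bandpass(256)
  set.seed(3)
  n <- 1024
  x <- rnorm(n); y <- rnorm(n)
  seg <- function(v) eeg_segment(v, fs = 256, duration_s = n / 256)
  fx <- apply_filter(seg(x), spec)$samples[, 1]
  fy <- apply_filter(seg(y), spec)$samples[, 1]
  fxy <- apply_filter(seg(2 * x - 3 * y), spec)$samples[, 1]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)

  z <- apply_filter(seg(rep(0, n)), spec)
  expect_true(all(z$samples == 0))
  ms <- eeg_segment(matrix(rnorm(2 * n), ncol = 2), fs = 256, duration_s = n / 256,
                    subject_id = "s9", class_label = "autism")
  out <- apply_filter(ms, spec)
  expect_equal(dim(out$samples), dim(ms$samples))
  expect_equal(out$subject_id, "s9")
  expect_equal(out$class_label, "autism")
})

test_that("zero-phase mode introduces no group delay", {
  spec <- design_elliptic_bandpass(256)
  s <- tone_segment(10, duration_s = 8)
  y <- apply_filter(s, spec, mode = "zero_phase")$samples[, 1]
  x <- s$samples[, 1]
  mid <- 512:1536
  lags <- -10:10
  cc <- vapply(lags, function(L) {
    stats::cor(x[mid], y[mid + L])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("sampling-rate mismatch between filter and segment is a contract error", {
  spec <- design_elliptic_bandpass(256)
  s <- tone_segment(10, fs = 128, duration_s = 4)
  expect_error(apply_filter(s, spec), class = "eegdx_contract_error")
})

test_that("notch biquad removes its center frequency and passes neighbors", {
  nt <- design_notch(256, 60, q = 30)
  gain <- function(f) Mod(filter_response(nt, f))
  expect_lt(gain(60), 0.01)
  expect_gt(gain(50), 0.95)
  expect_gt(gain(70), 0.95)
  expect_error(design_notch(100, 60), class = "eegdx_design_error")
})
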