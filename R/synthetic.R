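# Class-conditioned synthetic EEG generator.
#
# Each channel is a sum of band-limited oscillators (one per conventional
# EEG rhythm at its canonical center frequency) with seeded random phases,
# scaled so the relative band powers match the requested profile, plus
# 1/f^a background noise, optional Poisson spike transients (epileptiform
# stand-in) and optional stereotyped eye-blink artifacts mirrored on a
# synthetic EOG channel. Everything is a pure function of (spec, seed).

# canonical rhythm centers (Hz); fixed constants of the generator
BAND_CENTERS <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 40)

# background 1/f noise power relative to total oscillator power
NOISE_REL_POWER <- 0.2

#' Specify the spectral profile of one diagnostic class
#'
#' @param class_label Diagnostic class the profile emulates.
#' @param band_powers Named non-negative relative powers for
#'   `delta, theta, alpha, beta, gamma`; at least one must be positive.
#' @param spike_rate_hz Poisson rate of transient high-amplitude spikes
#'   (models epileptiform activity; 0 disables).
#' @param noise_exponent Spectral slope `a` of the `1/f^a` background noise.
#' @param amplitude_uv Overall signal scale: the standard deviation of the
#'   spike-free signal, in microvolts.
#' @param noise_rel_power Power of the background noise relative to the
#'   total oscillator power (default 0.2; 0 disables the noise floor).
#' @return An object of class `class_spectrum_spec`.
#' @export
class_spectrum_spec <- function(class_label = "unknown",
                                band_powers = c(delta = 1, theta = 1, alpha = 1,
                                                beta = 1, gamma = 1),
                                spike_rate_hz = 0, noise_exponent = 1,
                                amplitude_uv = 20,
                                noise_rel_power = NOISE_REL_POWER) {
  band_powers <- band_powers[names(BAND_CENTERS)]
  names(band_powers) <- names(BAND_CENTERS)
  band_powers[is.na(band_powers)] <- 0
  if (any(band_powers < 0) || all(band_powers == 0)) {
    abort("`band_powers` must be non-negative with at least one positive entry.",
          class = "eegdx_parameter_error")
  }
  if (spike_rate_hz < 0 || amplitude_uv < 0 || noise_rel_power < 0) {
    abort("rates and scale must be non-negative.", class = "eegdx_parameter_error")
  }
  structure(list(class_label = match.arg(class_label, CLASS_LABELS),
                 band_powers = band_powers, spike_rate_hz = spike_rate_hz,
                 noise_exponent = noise_exponent, amplitude_uv = amplitude_uv,
                 noise_rel_power = noise_rel_power),
            class = "class_spectrum_spec")
}

#' Preset class profiles
#'
#' Three ready-made spectral profiles: a neurotypical resting profile
#' dominated by the alpha rhythm; an epileptic profile with frequent
#' high-amplitude spike transients over a broad low-frequency background;
#' and an autism profile with elevated slow (delta/theta) and gamma power
#' and attenuated alpha, the pattern most consistently reported for resting
#' ASD EEG.
#'
#' @return A `class_spectrum_spec`.
#' @export
spec_neurotypical <- function() {
  class_spectrum_spec("neurotypical",
                      band_powers = c(delta = 0.6, theta = 0.8, alpha = 2.0,
                                      beta = 0.6, gamma = 0.2),
                      spike_rate_hz = 0, noise_exponent = 1, amplitude_uv = 20)
}

#' @rdname spec_neurotypical
#' @export
spec_epileptic <- function() {
  class_spectrum_spec("epilepsy",
                      band_powers = c(delta = 1.5, theta = 1.0, alpha = 0.7,
                                      beta = 0.5, gamma = 0.3),
                      spike_rate_hz = 1.5, noise_exponent = 1, amplitude_uv = 30)
}

#' @rdname spec_neurotypical
#' @export
spec_autistic <- function() {
  class_spectrum_spec("autism",
                      band_powers = c(delta = 1.3, theta = 1.6, alpha = 0.8,
                                      beta = 0.6, gamma = 0.9),
                      spike_rate_hz = 0, noise_exponent = 1, amplitude_uv = 22)
}

# 1/f^a noise of unit variance via FFT spectral shaping
pink_noise <- function(n, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))          # avoid dividing by zero at DC
  f <- pmin(f, n - f + 1)            # symmetric about Nyquist
  W <- W / f^(exponent / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

# biphasic ~60 ms spike transient (difference of Gaussians)
spike_template <- function(fs) {
  t <- seq(-0.03, 0.03, by = 1 / fs)
  s <- exp(-(t / 0.006)^2) - 0.6 * exp(-((t - 0.012) / 0.012)^2)
  s / max(abs(s))
}

# 400 ms raised-cosine blink transient
blink_template <- function(fs) {
  n <- round(0.4 * fs)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

add_transients <- function(x, template, times, fs, amplitude) {
  n <- length(x)
  for (t0 in times) {
    i0 <- round(t0 * fs) + 1
    idx <- i0:min(n, i0 + length(template) - 1)
    if (length(idx) < 2) next
    x[idx] <- x[idx] + amplitude * template[seq_along(idx)]
  }
  x
}

generate_channel <- function(spec, fs, duration_s) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  bp <- spec$band_powers / sum(spec$band_powers)
  osc <- numeric(n)
  for (b in names(BAND_CENTERS)) {
    if (bp[b] == 0) next
    f0 <- BAND_CENTERS[b]
    if (f0 >= fs / 2) {
      abort(sprintf("fs = %g Hz cannot represent the %s band center at %g Hz.",
                    fs, b, f0),
            class = "eegdx_parameter_error")
    }
    phase <- runif(1, 0, 2 * pi)
    # sinusoid power is A^2/2; amplitude set so band power ratios hold
    osc <- osc + sqrt(2 * bp[b]) * sin(2 * pi * f0 * t + phase)
  }
  nrp <- spec$noise_rel_power %||% NOISE_REL_POWER
  x <- osc
  if (nrp > 0) x <- x + sqrt(nrp) * pink_noise(n, spec$noise_exponent)
  x <- x / sd(x) * spec$amplitude_uv
  if (spec$spike_rate_hz > 0) {
    n_spikes <- rpois(1, spec$spike_rate_hz * duration_s)
    if (n_spikes > 0) {
      times <- sort(runif(n_spikes, 0, duration_s - 0.06))
      x <- add_transients(x, spike_template(fs), times, fs,
                          amplitude = 8 * spec$amplitude_uv)
    }
  }
  x
}

#' Generate one synthetic EEG segment
#'
#' @param spec A [class_spectrum_spec()].
#' @param n_channels Number of scalp channels (independent realizations of
#'   the same profile).
#' @param fs Sampling rate in Hz.
#' @param duration_s Segment duration in seconds (50 s is the standard
#'   window of this workflow).
#' @param seed Integer seed; generation is a pure function of
#'   `(spec, seed)`.
#' @param segment_index,subject_id Metadata stamped on the segment.
#' @return An [eeg_segment].
#' @export
generate_segment <- function(spec, n_channels = 1, fs = 256, duration_s = 50,
                             seed = 1, segment_index = 0L, subject_id = "sim") {
  stopifnot(inherits(spec, "class_spectrum_spec"))
  samples <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_channels),
           function(ci) generate_channel(spec, fs, duration_s),
           numeric(round(duration_s * fs)))
  })
  eeg_segment(samples, fs = fs, duration_s = duration_s,
              channel_labels = paste0("ch", seq_len(n_channels)),
              subject_id = subject_id, class_label = spec$class_label,
              segment_index = segment_index)
}

#' Specify a synthetic dataset
#'
#' @param classes List of [class_spectrum_spec()] objects, one per class.
#' @param n_segments_per_class Segments generated per class (>= 1).
#' @param n_channels Channels per segment.
#' @param fs Sampling rate in Hz.
#' @param duration_s Segment duration in seconds.
#' @param blink_rate_hz Poisson rate of planted eye blinks; when positive, a
#'   stereotyped low-frequency blink transient is added to every channel and
#'   a synthetic `EOG` reference channel is appended.
#' @param n_subjects_per_class Synthetic subjects each class's segments are
#'   attributed to (round-robin), for group-aware folding.
#' @param seed Master seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(classes = list(spec_neurotypical(), spec_epileptic()),
                     n_segments_per_class = 100, n_channels = 1, fs = 256,
                     duration_s = 50, blink_rate_hz = 0,
                     n_subjects_per_class = 10, seed = 1) {
  if (!length(classes)) {
    abort("`classes` must contain at least one class profile.",
          class = "eegdx_parameter_error")
  }
  stopifnot(n_segments_per_class >= 1, fs > 0, duration_s > 0,
            blink_rate_hz >= 0)
  structure(list(classes = classes,
                 n_segments_per_class = as.integer(n_segments_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, blink_rate_hz = blink_rate_hz,
                 n_subjects_per_class = as.integer(n_subjects_per_class),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_segments_per_class` segments for every class profile in the
#' spec. With `blink_rate_hz > 0` each segment receives planted blink
#' transients on all channels (5x the background standard deviation, 400 ms
#' raised cosine) and an extra `EOG` channel carrying the same blink train,
#' flagged via the segment's recording metadata.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Optional directory; when given, every segment is written
#'   as an EDF file there and the manifest's `path` column points at the
#'   files.
#' @return A list with `segments` (list of [eeg_segment]) and `manifest`
#'   (tibble with columns `path`, `dialect`, `class_label`, `subject_id`).
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  segments <- list()
  rows <- list()
  seg_seed <- spec$seed
  for (ci in seq_along(spec$classes)) {
    cls <- spec$classes[[ci]]
    for (si in seq_len(spec$n_segments_per_class)) {
      seg_seed <- seg_seed + 1L
      subj <- sprintf("%s_s%02d", cls$class_label,
                      (si - 1L) %% spec$n_subjects_per_class + 1L)
      seg <- generate_segment(cls, n_channels = spec$n_channels, fs = spec$fs,
                              duration_s = spec$duration_s, seed = seg_seed,
                              segment_index = si - 1L, subject_id = subj)
      if (spec$blink_rate_hz > 0) {
        seg <- plant_blinks(seg, spec$blink_rate_hz, seed = seg_seed)
      }
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir,
                          sprintf("%s_%03d.edf", cls$class_label, si))
        write_edf(seg, path)
      }
      segments[[length(segments) + 1L]] <- seg
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = path, dialect = "edf", class_label = cls$class_label,
        subject_id = subj)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(segments = segments, manifest = manifest)
}

# add a blink train to all channels and append a synthetic EOG channel
plant_blinks <- function(seg, blink_rate_hz, seed, gain_eog = 2) {
  withr::with_seed(as.integer(seed) + 10000L, {
    fs <- seg$fs
    dur <- n_samples(seg) / fs
    n_blinks <- max(1L, rpois(1, blink_rate_hz * dur))
    times <- sort(runif(n_blinks, 0, dur - 0.45))
    tpl <- blink_template(fs)
    out <- seg$samples
    for (ci in seq_len(ncol(out))) {
      amp <- 5 * sd(out[, ci])
      out[, ci] <- add_transients(out[, ci], tpl, times, fs, amp)
    }
    base_sd <- mean(apply(seg$samples, 2, sd))
    eog <- add_transients(0.2 * base_sd * rnorm(nrow(out)), tpl, times, fs,
                          gain_eog * 5 * base_sd)
    samples <- cbind(out, EOG = eog)
    res <- eeg_segment(samples, fs = fs, duration_s = seg$duration_s,
                       channel_labels = c(seg$channel_labels, "EOG"),
                       subject_id = seg$subject_id,
                       class_label = seg$class_label,
                       segment_index = seg$segment_index,
                       short_tail = seg$short_tail)
    attr(res, "blink_times") <- times
    res
  })
}

#' Convert a segment to a recording
#'
#' Useful for feeding synthetic segments (whose EOG channel is labeled
#' `"EOG"`) into [remove_eye_artifacts()] or [segment_recording()].
#'
#' @param seg An [eeg_segment].
#' @param eog_labels Channel labels to flag as ocular references.
#' @return An [eeg_recording].
#' @export
as_recording <- function(seg, eog_labels = intersect("EOG", seg$channel_labels)) {
  eeg_recording(seg$samples, fs = seg$fs, channel_labels = seg$channel_labels,
                eog_labels = eog_labels, subject_id = seg$subject_id,
                class_label = seg$class_label)
}

#' Write segments as EDF fixture files
#'
#' All segments must share one sampling rate and channel layout. Each
#' segment becomes one EDF file readable by [read_edf()] (round trip exact
#' to within 16-bit quantization of each channel's physical range).
#'
#' @param segments List of [eeg_segment] objects.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_fixture_edf <- function(segments, dir) {
  if (!length(segments)) {
    abort("empty segment list.", class = "eegdx_parameter_error")
  }
  fs <- unique(vapply(segments, function(s) s$fs, numeric(1)))
  ncs <- unique(vapply(segments, n_channels, integer(1)))
  if (length(fs) != 1 || length(ncs) != 1) {
    abort("segments must share one fs and channel layout.",
          class = "eegdx_parameter_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(segments), function(i) {
    p <- file.path(dir, sprintf("segment_%04d.edf", i))
    write_edf(segments[[i]], p)
    p
  }, character(1))
  invisible(paths)
}
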