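#' Construct a raw EEG recording
#'
#' A recording is the unit of input/output: a samples-by-channels matrix of
#' voltages (nominally microvolts) with a sampling rate, unique channel
#' labels, an optional subset of channels flagged as ocular (EOG) references,
#' a subject identifier and a diagnostic class label.
#'
#' @param samples Numeric matrix, one column per channel, or a numeric vector
#'   for a single-channel recording.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique labels, one per channel.
#' @param eog_labels Subset of `channel_labels` flagged as ocular reference
#'   channels (possibly empty).
#' @param subject_id Opaque subject identifier.
#' @param class_label One of `"neurotypical"`, `"epilepsy"`, `"autism"`,
#'   `"unknown"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = NULL,
                          eog_labels = character(), subject_id = "anon",
                          class_label = "unknown") {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "eegdx_parameter_error")
  }
  if (length(channel_labels) != ncol(samples)) {
    abort("`channel_labels` must have one entry per channel.",
          class = "eegdx_contract_error")
  }
  if (anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique.", class = "eegdx_contract_error")
  }
  if (!all(eog_labels %in% channel_labels)) {
    abort("`eog_labels` must be a subset of `channel_labels`.",
          class = "eegdx_contract_error")
  }
  class_label <- match.arg(class_label, CLASS_LABELS)
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         eog_labels = as.character(eog_labels), subject_id = subject_id,
         class_label = class_label),
    class = "eeg_recording"
  )
}

#' Construct an EEG segment
#'
#' A segment is one fixed-duration window of a recording and the unit of
#' feature extraction. `short_tail` flags a segment whose sample count is
#' below `round(duration_s * fs)` because the source recording was shorter
#' than the requested window.
#'
#' @inheritParams eeg_recording
#' @param duration_s Segment duration in seconds.
#' @param segment_index 0-based ordinal of the window within its source
#'   recording.
#' @param short_tail Logical flag for windows truncated by the end of the
#'   recording.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, duration_s = NULL, channel_labels = NULL,
                        subject_id = "anon", class_label = "unknown",
                        segment_index = 0L, short_tail = FALSE) {
  rec <- eeg_recording(samples, fs, channel_labels,
                       subject_id = subject_id, class_label = class_label)
  n <- nrow(rec$samples)
  if (is.null(duration_s)) duration_s <- n / fs
  if (!short_tail && n != round(duration_s * fs)) {
    abort("sample count does not match round(duration_s * fs) for a non-short-tail segment.",
          class = "eegdx_contract_error")
  }
  structure(
    list(samples = rec$samples, fs = fs, duration_s = duration_s,
         channel_labels = rec$channel_labels, subject_id = subject_id,
         class_label = rec$class_label, segment_index = as.integer(segment_index),
         short_tail = isTRUE(short_tail)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %.2f Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  subject: %s  class: %s\n", x$subject_id, x$class_label))
  if (length(x$eog_labels)) {
    cat("  EOG reference channels:", paste(x$eog_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment #%d> %d channel(s) x %d samples @ %.2f Hz (%.1f s)%s\n",
              x$segment_index, ncol(x$samples), nrow(x$samples), x$fs,
              x$duration_s, if (x$short_tail) " [short tail]" else ""))
  cat(sprintf("  subject: %s  class: %s\n", x$subject_id, x$class_label))
  invisible(x)
}

n_channels <- function(x) ncol(x$samples)
n_samples <- function(x) nrow(x$samples)
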