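#' Read a single-channel ASCII EEG signal
#'
#' Reads the plain-text dialect used by the Bonn University epilepsy sets
#' (A-E): one sample value per line, no header. Blank lines are ignored;
#' values must use a decimal point.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz (the Bonn sets use 173.61 Hz).
#' @param class_label Diagnostic class of the recording.
#' @param subject_id Subject identifier (defaults to the file name).
#' @return An [eeg_recording] with one channel.
#' @export
read_ascii_single_channel <- function(path, fs = 173.61,
                                      class_label = "unknown",
                                      subject_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "eegdx_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    abort(paste0("empty input: no sample lines in ", path),
          class = "eegdx_empty_input_error")
  }
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    abort(sprintf("format error in %s at line %d: cannot parse %s as a number",
                  path, keep[bad[1]], dQuote(trimws(lines[keep[bad[1]]]))),
          class = "eegdx_format_error")
  }
  eeg_recording(vals, fs = fs, channel_labels = "ch1",
                subject_id = subject_id %||% basename(path),
                class_label = class_label)
}

#' Cut a recording into fixed-length segments
#'
#' Windows are consecutive and non-overlapping; each segment inherits the
#' recording's class label and subject id and carries a 0-based
#' `segment_index`.
#'
#' The trailing partial window is handled by `policy`:
#' \describe{
#'   \item{`"drop"`}{discard any samples beyond the last full window;}
#'   \item{`"keep-short"`}{emit the partial tail as an extra short segment;}
#'   \item{`"whole-if-shorter"`}{(default) like `"drop"`, except a recording
#'     shorter than one window yields a single short-tail segment covering
#'     the whole recording. This is the only way a 23.6 s single-channel
#'     signal can be used with the standard 50 s window.}
#' }
#'
#' @param rec An [eeg_recording].
#' @param window_s Window length in seconds (> 0); 50 s is the conventional
#'   default for this workflow.
#' @param policy Tail policy, see Details.
#' @return A list of [eeg_segment] objects.
#' @export
segment_recording <- function(rec, window_s = 50,
                              policy = c("whole-if-shorter", "drop", "keep-short")) {
  stopifnot(inherits(rec, "eeg_recording"))
  policy <- match.arg(policy)
  if (!is.numeric(window_s) || length(window_s) != 1 || window_s <= 0) {
    abort("`window_s` must be a single positive number.",
          class = "eegdx_parameter_error")
  }
  n <- n_samples(rec)
  win <- round(window_s * rec$fs)
  n_full <- n %/% win
  segs <- list()
  make_seg <- function(i0, i1, idx, short) {
    eeg_segment(rec$samples[i0:i1, , drop = FALSE], fs = rec$fs,
                duration_s = if (short) (i1 - i0 + 1) / rec$fs else window_s,
                channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, class_label = rec$class_label,
                segment_index = idx, short_tail = short)
  }
  for (i in seq_len(n_full)) {
    segs[[i]] <- make_seg((i - 1) * win + 1, i * win, i - 1L, FALSE)
  }
  rem <- n - n_full * win
  if (rem > 0) {
    emit_tail <- switch(policy,
      "drop" = FALSE,
      "keep-short" = TRUE,
      "whole-if-shorter" = n_full == 0
    )
    if (emit_tail) {
      segs[[n_full + 1]] <- make_seg(n_full * win + 1, n, n_full, TRUE)
    }
  }
  segs
}

#' Read a dataset manifest CSV
#'
#' A manifest enumerates recordings as rows with columns
#' `path,dialect,class_label,subject_id`, where `dialect` is
#' `"ascii_single"` or `"edf"`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "eegdx_io_error")
  }
  m <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("path", "dialect", "class_label", "subject_id")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")),
          class = "eegdx_format_error")
  }
  if (anyDuplicated(m$path)) {
    abort("manifest paths must be unique.", class = "eegdx_format_error")
  }
  if (!all(m$dialect %in% c("ascii_single", "edf"))) {
    abort("manifest dialect must be 'ascii_single' or 'edf'.",
          class = "eegdx_format_error")
  }
  m[need]
}

#' Load every recording listed in a manifest
#'
#' @param manifest Tibble from [read_manifest()] (or a compatible data frame).
#' @param fs_ascii Sampling rate assumed for `ascii_single` entries.
#' @param eog_labels Channel labels flagged as ocular references in EDF
#'   entries.
#' @param base_dir Directory that relative manifest paths are resolved
#'   against.
#' @return A list of [eeg_recording] objects.
#' @export
load_manifest <- function(manifest, fs_ascii = 173.61, eog_labels = character(),
                          base_dir = ".") {
  purrr::pmap(manifest, function(path, dialect, class_label, subject_id, ...) {
    full <- if (file.exists(path)) path else file.path(base_dir, path)
    if (dialect == "ascii_single") {
      read_ascii_single_channel(full, fs = fs_ascii, class_label = class_label,
                                subject_id = subject_id)
    } else {
      rec <- read_edf(full, eog_labels = eog_labels)
      rec$class_label <- match.arg(class_label, CLASS_LABELS)
      rec$subject_id <- subject_id
      rec
    }
  })
}
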