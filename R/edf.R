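# Minimal EDF (European Data Format) reader / writer.
#
# EDF stores fixed-width ASCII headers followed by data records of 16-bit
# little-endian integers, one block per signal per record, with per-signal
# physical/digital calibration ranges. Only continuous uniform-rate layouts
# are supported; EDF+ annotation channels are skipped on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Read an EDF/EDF+ recording
#'
#' Channels are returned in file order with the sampling rate taken from the
#' header. All selected channels must share one sampling rate; EDF+
#' annotation channels are skipped.
#'
#' @param path Path to the EDF file.
#' @param eog_labels Channel labels to flag as ocular (EOG) reference
#'   channels on the returned recording.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, eog_labels = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "eegdx_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  rdn <- function(w) as.numeric(trimws(rd(w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)            # version, ids, date, time
  header_bytes <- rdn(8)
  rd(44)
  n_records <- rdn(8)
  record_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels    <- field(16)
  field(80)                                      # transducer
  field(8)                                       # physical dimension
  phys_min  <- as.numeric(field(8))
  phys_max  <- as.numeric(field(8))
  dig_min   <- as.numeric(field(8))
  dig_max   <- as.numeric(field(8))
  field(80)                                      # prefiltering
  spr       <- as.integer(field(8))
  field(32)                                      # reserved
  stopifnot(header_bytes == 256 * (ns + 1))
  if (n_records < 0) {
    n_records <- (file.size(path) - header_bytes) / (2 * sum(spr))
  }
  n_records <- as.integer(n_records)
  keep <- which(labels != "EDF Annotations")
  if (!length(keep)) {
    abort("no signal channels in EDF file.", class = "eegdx_format_error")
  }
  if (length(unique(spr[keep])) != 1) {
    abort("unsupported layout: selected channels have mixed sampling rates.",
          class = "eegdx_unsupported_layout_error")
  }
  out <- matrix(0, nrow = n_records * spr[keep[1]], ncol = length(keep))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      j <- match(s, keep)
      if (!is.na(j)) {
        rows <- ((r - 1) * spr[s] + 1):(r * spr[s])
        out[rows, j] <- phys_min[s] + (dig - dig_min[s]) * gain[s]
      }
    }
  }
  fs <- spr[keep[1]] / record_dur
  eeg_recording(out, fs = fs, channel_labels = labels[keep],
                eog_labels = intersect(eog_labels, labels[keep]))
}

#' Write a recording to an EDF file
#'
#' Each channel is calibrated to its own physical range and quantized to
#' 16-bit integers, so a round trip reproduces samples within one
#' quantization step of `(max - min) / 65535` per channel.
#'
#' @param rec An [eeg_recording] or [eeg_segment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  n <- nrow(x); nc <- ncol(x); fs <- rec$fs
  # prefer 1 s records when fs is integral and divides n; else one big record
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- round(fs); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1; rec_dur <- n / fs
  }
  dig_min <- -32768; dig_max <- 32767
  phys_min <- apply(x, 2, min); phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id %||% "X", 80))
  wr(edf_pad("eegdx", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (nc + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_num(rec_dur, 8))
  wr(edf_pad(nc, 4))
  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(nc)) wr(edf_pad("", 80))
  for (i in seq_len(nc)) wr(edf_pad("uV", 8))
  for (v in phys_min) wr(edf_num(v, 8))
  for (v in phys_max) wr(edf_num(v, 8))
  for (i in seq_len(nc)) wr(edf_pad(dig_min, 8))
  for (i in seq_len(nc)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(nc)) wr(edf_pad("", 80))
  for (i in seq_len(nc)) wr(edf_pad(spr, 8))
  for (i in seq_len(nc)) wr(edf_pad("", 32))
  # headers round physical ranges to 8 ASCII chars; use the stored values
  pmin_h <- as.numeric(trimws(vapply(phys_min, edf_num, character(1))))
  pmax_h <- as.numeric(trimws(vapply(phys_max, edf_num, character(1))))
  gain <- (pmax_h - pmin_h) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(nc)) {
      dig <- round((x[rows, s] - pmin_h[s]) / gain[s] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
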