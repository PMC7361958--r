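# Periodized orthonormal discrete wavelet transform.
#
# The analysis step correlates the signal with even shifts of the scaling
# (low-pass) filter h and the quadrature mirror (high-pass) filter
# g[m] = (-1)^m h[L-1-m], wrapping indices modulo the signal length. For even
# lengths the step is an orthogonal map, so coefficient energy equals signal
# energy and the synthesis step (the transpose) reconstructs exactly.

# orthonormal scaling filters, sum h = sqrt(2); "dbN" has N vanishing moments
WAVELET_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
           0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333)
)

wavelet_filter <- function(name) {
  h <- WAVELET_FILTERS[[name]]
  if (is.null(h)) {
    abort(paste0("unknown wavelet: ", name, " (available: ",
                 paste(names(WAVELET_FILTERS), collapse = ", "), ")"),
          class = "eegdx_parameter_error")
  }
  L <- length(h)
  list(h = h, g = (-1)^(0:(L - 1)) * rev(h), support = L)
}

# one analysis step; odd-length inputs are padded by repeating the last sample
dwt_step <- function(x, h, g) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  half <- n / 2
  L <- length(h)
  k2 <- 2 * (0:(half - 1))
  cA <- numeric(half); cD <- numeric(half)
  for (m in 0:(L - 1)) {
    idx <- (k2 + m) %% n + 1
    cA <- cA + h[m + 1] * x[idx]
    cD <- cD + g[m + 1] * x[idx]
  }
  list(cA = cA, cD = cD)
}

# one synthesis step (transpose of the analysis map)
idwt_step <- function(cA, cD, h, g) {
  half <- length(cA)
  n <- 2 * half
  L <- length(h)
  k2 <- 2 * (0:(half - 1))
  y <- numeric(n)
  for (m in 0:(L - 1)) {
    idx <- (k2 + m) %% n + 1
    y[idx] <- y[idx] + h[m + 1] * cA + g[m + 1] * cD
  }
  y
}

#' Nominal sub-band frequency ranges of the DWT tree
#'
#' Successive halving of the Nyquist interval: D1 covers `(fs/4, fs/2]`, each
#' deeper detail halves the band, and the final approximation covers
#' `(0, fs/2^(level+1)]`. At fs = 256 Hz and level 4 the five bands line up
#' with the conventional gamma/beta/alpha/theta/delta rhythm labels.
#'
#' @param fs Sampling rate in Hz.
#' @param level Decomposition level.
#' @return Named list of `c(low, high)` pairs in Hz, finest band first.
#' @export
nominal_bands <- function(fs, level = 4) {
  out <- list()
  hi <- fs / 2
  for (j in seq_len(level)) {
    out[[paste0("D", j)]] <- c(hi / 2, hi)
    hi <- hi / 2
  }
  out[[paste0("A", level)]] <- c(0, hi)
  out
}

#' Decompose a segment into DWT sub-bands
#'
#' Runs a `level`-deep discrete wavelet transform on every channel and
#' returns the detail coefficients of each level plus the final
#' approximation (for level 4: D1-D4 and A4). The default db4 mother wavelet
#' with periodized orthonormal extension conserves energy exactly on
#' even-length inputs.
#'
#' @param seg An [eeg_segment] (or [eeg_recording]).
#' @param wavelet Mother wavelet name (one of
#'   `r paste(names(WAVELET_FILTERS), collapse = ", ")`).
#' @param level Decomposition depth (the standard tree uses 4).
#' @return An object of class `subband_set`: per channel a named list of
#'   coefficient vectors (`D1`..`Dlevel`, `Alevel`), plus `nominal_bands`,
#'   `wavelet`, `level`, `fs` and the segment's metadata.
#' @export
dwt_decompose <- function(seg, wavelet = "db4", level = 4) {
  flt <- wavelet_filter(wavelet)
  n <- n_samples(seg)
  min_n <- 2^level * flt$support
  if (n < min_n) {
    abort(sprintf("segment too short for a level-%d %s decomposition: %d samples, need >= %d.",
                  level, wavelet, n, min_n),
          class = "eegdx_length_error")
  }
  det_names <- paste0("D", seq_len(level))
  app_name <- paste0("A", level)
  channels <- lapply(seq_len(n_channels(seg)), function(ci) {
    x <- seg$samples[, ci]
    bands <- list()
    for (j in seq_len(level)) {
      st <- dwt_step(x, flt$h, flt$g)
      bands[[det_names[j]]] <- st$cD
      x <- st$cA
    }
    bands[[app_name]] <- x
    bands
  })
  names(channels) <- seg$channel_labels
  structure(
    list(channels = channels, wavelet = wavelet, level = level, fs = seg$fs,
         nominal_bands = nominal_bands(seg$fs, level),
         class_label = seg$class_label %||% "unknown",
         subject_id = seg$subject_id %||% "anon",
         segment_index = seg$segment_index %||% 0L),
    class = "subband_set"
  )
}

#' Reconstruct a signal from its DWT sub-bands
#'
#' Inverse of [dwt_decompose()] for a single channel; with the periodized
#' orthonormal filters and even lengths at every level the reconstruction is
#' exact to floating precision.
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @param channel Channel label or index.
#' @return Numeric vector of reconstructed samples.
#' @export
dwt_reconstruct <- function(sb, channel = 1) {
  flt <- wavelet_filter(sb$wavelet)
  bands <- sb$channels[[channel]]
  x <- bands[[paste0("A", sb$level)]]
  for (j in rev(seq_len(sb$level))) {
    x <- idwt_step(x, bands[[paste0("D", j)]], flt$h, flt$g)
  }
  x
}

#' @export
print.subband_set <- function(x, ...) {
  lens <- vapply(x$channels[[1]], length, integer(1))
  cat(sprintf("<subband_set> %s level %d, %d channel(s)\n",
              x$wavelet, x$level, length(x$channels)))
  for (b in names(lens)) {
    rng <- x$nominal_bands[[b]]
    alias <- SUBBAND_ALIASES[b]
    cat(sprintf("  %s%s: %d coefficients, nominal (%.3g, %.3g] Hz\n", b,
                if (!is.na(alias)) paste0(" (", alias, ")") else "",
                lens[b], rng[1], rng[2]))
  }
  invisible(x)
}
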