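# The five sub-band statistics. Each operates on the raw DWT coefficients of
# one sub-band and deliberately uses population (divisor-N) moments.

#' Population variance of a coefficient sequence
#'
#' `(1/N) * sum((s - mean(s))^2)` — the divisor-N variance, not the sample
#' (divisor N-1) variance returned by [stats::var()].
#'
#' @param coeffs Non-empty numeric vector.
#' @return A single number.
#' @export
feat_variance <- function(coeffs) {
  check_coeffs(coeffs)
  mean((coeffs - mean(coeffs))^2)
}

#' Population standard deviation of a coefficient sequence
#'
#' Square root of [feat_variance()].
#'
#' @inheritParams feat_variance
#' @return A single number.
#' @export
feat_sd <- function(coeffs) {
  sqrt(feat_variance(coeffs))
}

#' Kurtosis of a coefficient sequence
#'
#' Fourth standardized moment `E[((s - mu)/sigma)^4]` in the non-excess
#' convention (a Gaussian signal gives 3). A constant sequence has no
#' defined kurtosis; by default this raises a degenerate-signal error, or
#' returns `0` when `degenerate = "zero"` (useful for batch runs).
#'
#' @inheritParams feat_variance
#' @param degenerate Either `"error"` (default) or `"zero"`.
#' @return A single number.
#' @export
feat_kurtosis <- function(coeffs, degenerate = c("error", "zero")) {
  check_coeffs(coeffs)
  degenerate <- match.arg(degenerate)
  mu <- mean(coeffs)
  v <- mean((coeffs - mu)^2)
  if (v == 0) {
    if (degenerate == "zero") return(0)
    abort("degenerate signal: kurtosis undefined for a constant sequence (sigma = 0).",
          class = "eegdx_degenerate_error")
  }
  mean((coeffs - mu)^4) / v^2
}

#' Non-normalized Shannon entropy of a coefficient sequence
#'
#' `sum(s^2 * log(s^2))` with the convention `0 * log(0) = 0`. The natural
#' logarithm is the default; the base only rescales the statistic.
#'
#' @inheritParams feat_variance
#' @param base Logarithm base (`exp(1)` or `10`).
#' @return A single number.
#' @export
feat_entropy <- function(coeffs, base = exp(1)) {
  check_coeffs(coeffs)
  s2 <- coeffs^2
  nz <- s2 > 0
  sum(s2[nz] * log(s2[nz], base = base))
}

#' Logarithmic band power of a coefficient sequence
#'
#' `log(mean(s^2))` — the log of the mean squared amplitude. Natural
#' logarithm by default. An all-zero sequence has no finite log power and
#' raises a domain error unless a finite `floor` is supplied.
#'
#' @inheritParams feat_entropy
#' @param floor Optional finite value returned for all-zero input instead of
#'   an error.
#' @return A single number.
#' @export
feat_lbp <- function(coeffs, base = exp(1), floor = NULL) {
  check_coeffs(coeffs)
  ms <- mean(coeffs^2)
  if (ms == 0) {
    if (!is.null(floor)) return(floor)
    abort("domain error: logarithmic band power of an all-zero sequence is -Inf.",
          class = "eegdx_degenerate_error")
  }
  log(ms, base = base)
}

check_coeffs <- function(coeffs) {
  if (length(coeffs) == 0) {
    abort("domain error: empty coefficient sequence.",
          class = "eegdx_degenerate_error")
  }
  invisible(coeffs)
}

feature_fun <- function(statistic, kurtosis_degenerate = "error",
                        log_base = exp(1)) {
  switch(statistic,
    lbp      = function(s) feat_lbp(s, base = log_base),
    sd       = feat_sd,
    variance = feat_variance,
    kurtosis = function(s) feat_kurtosis(s, degenerate = kurtosis_degenerate),
    entropy  = function(s) feat_entropy(s, base = log_base),
    abort(paste0("unknown statistic: ", statistic), class = "eegdx_config_error")
  )
}

#' Assemble a feature vector from a sub-band decomposition
#'
#' Values are ordered channel-major, then sub-band in the fixed order
#' D1, D2, ..., A-level, then statistic, so the layout is part of the
#' contract and stable across segments.
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @param statistics Character vector drawn from
#'   `c("lbp", "sd", "variance", "kurtosis", "entropy")`.
#' @param subbands Ordered subset of the decomposition's sub-band names
#'   (default: all of them).
#' @param kurtosis_degenerate Passed to [feat_kurtosis()].
#' @param log_base Logarithm base for `lbp` and `entropy`.
#' @return A one-row tibble with columns `class_label`, `subject_id`,
#'   `segment_index`, then one numeric column per
#'   `<channel>_<subband>_<statistic>` triple.
#' @export
build_feature_vector <- function(sb, statistics = STATISTICS, subbands = NULL,
                                 kurtosis_degenerate = "error",
                                 log_base = exp(1)) {
  stopifnot(inherits(sb, "subband_set"))
  statistics <- match.arg(statistics, STATISTICS, several.ok = TRUE)
  all_bands <- names(sb$channels[[1]])
  subbands <- subbands %||% all_bands
  missing <- setdiff(subbands, all_bands)
  if (length(missing)) {
    abort(paste0("requested sub-bands not present: ", paste(missing, collapse = ", ")),
          class = "eegdx_config_error")
  }
  vals <- list()
  for (ch in names(sb$channels)) {
    for (b in subbands) {
      for (st in statistics) {
        v <- feature_fun(st, kurtosis_degenerate, log_base)(sb$channels[[ch]][[b]])
        if (!is.finite(v)) {
          abort(sprintf("non-finite %s for channel %s sub-band %s.", st, ch, b),
                class = "eegdx_degenerate_error")
        }
        vals[[paste(ch, b, st, sep = "_")]] <- v
      }
    }
  }
  tibble::as_tibble(c(
    list(class_label = sb$class_label, subject_id = sb$subject_id,
         segment_index = sb$segment_index),
    vals
  ))
}

#' Extract a feature table from a list of segments
#'
#' Runs [dwt_decompose()] and [build_feature_vector()] on every segment and
#' binds the rows: one row per segment, one numeric column per
#' `<channel>_<subband>_<statistic>` triple, plus `class_label`,
#' `subject_id` and `segment_index` metadata columns. This wide tibble is
#' the classifier-ready feature table used by [kfold_cross_validate()] and
#' [run_grid()].
#'
#' @param segments List of [eeg_segment] objects (one [eeg_segment] is also
#'   accepted).
#' @inheritParams dwt_decompose
#' @inheritParams build_feature_vector
#' @return A tibble of features; the feature column names are stored in
#'   `attr(., "feature_cols")`.
#' @export
extract_features <- function(segments, statistics = STATISTICS,
                             wavelet = "db4", level = 4, subbands = NULL,
                             kurtosis_degenerate = "error",
                             log_base = exp(1)) {
  if (inherits(segments, "eeg_segment")) segments <- list(segments)
  rows <- purrr::map(segments, function(seg) {
    sb <- dwt_decompose(seg, wavelet = wavelet, level = level)
    build_feature_vector(sb, statistics = statistics, subbands = subbands,
                         kurtosis_degenerate = kurtosis_degenerate,
                         log_base = log_base)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "feature_cols") <- setdiff(names(out),
                                       c("class_label", "subject_id", "segment_index"))
  out
}

feature_cols <- function(features) {
  attr(features, "feature_cols") %||%
    setdiff(names(features), c("class_label", "subject_id", "segment_index"))
}

# feature columns belonging to one statistic, e.g. "..._D3_lbp"
cols_for_statistic <- function(features, statistic) {
  fc <- feature_cols(features)
  fc[endsWith(fc, paste0("_", statistic))]
}
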