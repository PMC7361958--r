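#' Default pipeline configuration
#'
#' Returns the full configuration list with the workflow's standard
#' parameters; supplied values override defaults field-by-field. The same
#' structure is accepted as YAML by [run_pipeline()] and the command-line
#' driver.
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    io = list(manifest = NULL, fs_ascii = 173.61, eog_labels = list()),
    preprocess = list(ica = TRUE, ica_threshold = 0.7,
                      window_s = 50, tail_policy = "whole-if-shorter",
                      band = c(0.1, 60), order = 8,
                      passband_ripple_db = 0.5, stopband_atten_db = 40,
                      zero_phase = TRUE, notch = FALSE, notch_hz = 60),
    features = list(statistics = STATISTICS, wavelet = "db4", level = 4),
    classify = list(classifiers = c("lda", "svm_linear_ova", "knn", "ann"),
                    k = 10, stratified = TRUE, group_folds = FALSE),
    seed = 1,
    output = list(dir = NULL)
  )
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]) &&
                     !is.null(names(b[[nm]]))) {
        merge_rec(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  cfg <- merge_rec(base, list(...))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config not found: ", path), class = "eegdx_io_error")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full diagnostic pipeline
#'
#' Executes the standard stage order: read recordings from the manifest,
#' remove ocular artifacts (multi-channel recordings with EOG references
#' only), cut into fixed windows, band-pass filter, extract DWT sub-band
#' features, and cross-validate the classifier grid. When
#' `config$output$dir` is set, writes `features.csv`, `results.csv`,
#' `results.json` (fold-level detail and confusion matrices) and
#' `run_log.yaml` recording every parameter, the seed, and a hash of the
#' resolved configuration.
#'
#' @param config A [pipeline_config()] list or the path of a YAML file.
#' @return A list with `features` (tibble) and `results` (an
#'   [`eeg_grid`][run_grid] tibble), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "eegdx_pipeline_error", parent = e)
    })
  }
  if (is.null(config$io$manifest)) {
    abort("config$io$manifest is required.", class = "eegdx_config_error")
  }
  manifest <- stage("read-manifest", read_manifest(config$io$manifest))
  recs <- stage("read-recordings",
    load_manifest(manifest, fs_ascii = config$io$fs_ascii,
                  eog_labels = unlist(config$io$eog_labels),
                  base_dir = dirname(config$io$manifest)))
  pp <- config$preprocess
  if (isTRUE(pp$ica)) {
    recs <- stage("artifact-removal", lapply(recs, function(r) {
      remove_eye_artifacts(r, corr_threshold = pp$ica_threshold,
                           seed = config$seed)$recording
    }))
  }
  segments <- stage("segment", unlist(lapply(recs, function(r) {
    segment_recording(r, window_s = pp$window_s, policy = pp$tail_policy)
  }), recursive = FALSE))
  segments <- stage("filter", {
    specs <- list()
    lapply(segments, function(s) {
      key <- as.character(s$fs)
      if (is.null(specs[[key]])) {
        specs[[key]] <<- design_elliptic_bandpass(
          s$fs, pp$band[1], pp$band[2], pp$passband_ripple_db,
          pp$stopband_atten_db, pp$order)
      }
      out <- apply_filter(s, specs[[key]],
                          mode = if (isTRUE(pp$zero_phase)) "zero_phase" else "causal")
      if (isTRUE(pp$notch) && pp$notch_hz < s$fs / 2) {
        out <- apply_filter(out, design_notch(s$fs, pp$notch_hz),
                            mode = if (isTRUE(pp$zero_phase)) "zero_phase" else "causal")
      }
      out
    })
  })
  features <- stage("features",
    extract_features(segments, statistics = unlist(config$features$statistics),
                     wavelet = config$features$wavelet,
                     level = config$features$level))
  results <- stage("cross-validate",
    run_grid(features, statistics = unlist(config$features$statistics),
             classifiers = unlist(config$classify$classifiers),
             k = config$classify$k, seed = config$seed,
             stratified = isTRUE(config$classify$stratified),
             group_folds = isTRUE(config$classify$group_folds)))
  if (!is.null(config$output$dir)) {
    stage("write-outputs", write_pipeline_outputs(config, features, results))
  }
  invisible(list(features = features, results = results))
}

write_pipeline_outputs <- function(config, features, results) {
  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  analysis_cfg <- unclass(config)[setdiff(names(config), "output")]
  cfg_hash <- rlang::hash(analysis_cfg)
  out <- function(f) file.path(config$output$dir, f)
  write.csv(features, out("features.csv"), row.names = FALSE)
  res_flat <- tidy(results)
  res_flat$config_hash <- cfg_hash
  write.csv(res_flat, out("results.csv"), row.names = FALSE)
  detail <- purrr::map2(results$cv, seq_len(nrow(results)), function(cv, i) {
    list(statistic = results$statistic[i], classifier = results$classifier[i],
         fold_accuracies = cv$fold_accuracies,
         mean_accuracy = cv$mean_accuracy, std_accuracy = cv$std_accuracy,
         k = cv$k, confusion = as.data.frame(cv_confusion(cv)))
  })
  jsonlite::write_json(list(config_hash = cfg_hash, seed = config$seed,
                            cells = detail),
                       out("results.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(c(unclass(config), list(config_hash = cfg_hash)),
                   out("run_log.yaml"))
  invisible(config$output$dir)
}
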