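# Symmetric FastICA with a tanh contrast, deterministic given a seed.
# Used for reference-channel ocular artifact removal: independent components
# of the scalp channels that correlate strongly with an EOG reference are
# zeroed before reconstruction.

fastica_decompose <- function(X, seed = 1, max_iter = 200, tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  K <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))       # whitening matrix
  Z <- Xc %*% K                                      # n x m, identity covariance
  m <- ncol(Z)
  run <- function(seed_i) {
    W <- withr::with_seed(seed_i, matrix(rnorm(m * m), m, m))
    sym_decorrelate <- function(W) {
      sv <- svd(W)
      sv$u %*% t(sv$v)
    }
    W <- sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      WX <- Z %*% t(W)                               # n x m sources
      gwx <- tanh(WX)
      gp <- colMeans(1 - gwx^2)
      W1 <- crossprod(gwx, Z) / n - diag(gp, m) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
    }
    list(W = W, converged = FALSE, iter = max_iter)
  }
  fit <- run(seed)
  if (!fit$converged) fit <- run(seed + 1L)
  if (!fit$converged) {
    abort("ICA failed to converge after a retry with a new seed.",
          class = "eegdx_convergence_error")
  }
  unmix <- K %*% t(fit$W)                            # X_c %*% unmix = S
  mix <- MASS::ginv(unmix)                           # S %*% mix ~= X_c
  list(S = Xc %*% unmix, mixing = mix, unmixing = unmix, center = mu,
       iterations = fit$iter)
}

#' Remove ocular artifacts with reference-channel ICA
#'
#' Decomposes the non-EOG channels with FastICA, zeroes every independent
#' component whose absolute Pearson correlation with any EOG reference
#' channel exceeds `corr_threshold`, reconstructs the scalp channels, and
#' drops the EOG channels from the output. Recordings without EOG channels,
#' or with fewer than two scalp channels (where ICA is undefined), pass
#' through unchanged with an empty report.
#'
#' @param rec An [eeg_recording] whose `eog_labels` mark the reference
#'   channels.
#' @param corr_threshold Rejection threshold on `|cor|`, in `[0, 1]`
#'   (default 0.7).
#' @param seed Integer seed controlling the ICA initialization.
#' @return A list with elements `recording` (cleaned, EOG channels dropped)
#'   and `report` (fields `n_components_removed`,
#'   `removed_component_indices`, `max_abs_correlation_with_eog`).
#' @export
remove_eye_artifacts <- function(rec, corr_threshold = 0.7, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (corr_threshold < 0 || corr_threshold > 1) {
    abort("`corr_threshold` must lie in [0, 1].", class = "eegdx_parameter_error")
  }
  empty_report <- list(n_components_removed = 0L,
                       removed_component_indices = integer(),
                       max_abs_correlation_with_eog = numeric())
  is_eog <- rec$channel_labels %in% rec$eog_labels
  if (!any(is_eog) || sum(!is_eog) < 2) {
    return(list(recording = rec, report = empty_report))
  }
  X <- rec$samples[, !is_eog, drop = FALSE]
  E <- rec$samples[, is_eog, drop = FALSE]
  dec <- fastica_decompose(X, seed = seed)
  m <- ncol(dec$S)
  max_cor <- vapply(seq_len(m), function(i) {
    max(abs(cor(dec$S[, i], E)))
  }, numeric(1))
  removed <- which(max_cor > corr_threshold)
  S <- dec$S
  if (length(removed)) S[, removed] <- 0
  Xc <- S %*% dec$mixing
  Xr <- sweep(Xc, 2, dec$center, `+`)
  out <- eeg_recording(Xr, fs = rec$fs,
                       channel_labels = rec$channel_labels[!is_eog],
                       eog_labels = character(),
                       subject_id = rec$subject_id,
                       class_label = rec$class_label)
  list(recording = out,
       report = list(n_components_removed = length(removed),
                     removed_component_indices = removed,
                     max_abs_correlation_with_eog = max_cor[removed]))
}
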