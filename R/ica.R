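# Symmetric fixed-point ICA (cube/kurtosis contrast, suited to spiky
# super-Gaussian artifact sources such as blinks and bursts) on whitened
# data. The
# initialisation is the identity in whitened space, so the decomposition is
# deterministic. Returns unmixing (components x channels) and mixing
# (channels x components) matrices satisfying mixing %*% unmixing == I on
# the span of the data.
fast_ica <- function(X, n_comp = nrow(X), tol = 1e-6, max_iter = 400L) {
  nc <- nrow(X); ns <- ncol(X)
  if (ns < 2L * nc) stop("ICA needs at least 2x more samples than channels")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (ns - 1)
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(pos))
  E <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  Dh <- sqrt(eg$values[seq_len(n_comp)])
  K <- sweep(t(E), 1L, Dh, "/")          # whitening: n_comp x channels
  Z <- K %*% Xc

  W <- diag(n_comp)
  sym_decorrelate <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), n_comp) %*% t(s$vectors) %*% W
  }
  # Fixed-point update with annealed step size: when the update oscillates
  # (typical for directions with little non-Gaussian structure, which have
  # no stable fixed point) the step is damped, so strongly non-Gaussian
  # components converge first and the remainder freezes smoothly.
  iter <- 0L; delta <- Inf; alpha <- 1
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    WZ <- W %*% Z
    G <- WZ^3
    gd <- 3 * rowMeans(WZ^2)
    Wfp <- tcrossprod(G, Z) / ns - diag(gd, n_comp) %*% W
    W1 <- sym_decorrelate((1 - alpha) * W + alpha * sym_decorrelate(Wfp))
    d_new <- max(abs(1 - abs(rowSums(W1 * W))))
    if (d_new > 0.9 * delta) alpha <- alpha * 0.7
    delta <- d_new
    W <- W1
  }
  if (delta > tol)
    stop(sprintf("ICA did not converge: %d iterations, last delta %.3g (tol %.3g)",
                 iter, delta, tol))
  unmixing <- W %*% K                     # components x channels
  mixing <- E %*% diag(Dh, n_comp) %*% t(W)  # channels x components
  list(unmixing = unmixing, mixing = mixing, center = mu,
       n_comp = n_comp, iterations = iter)
}

#' ICA-based ocular artifact removal
#'
#' Decomposes the recording into independent components (fitted on a 1-Hz
#' high-passed, subsampled copy of the data, applied to the analysis data),
#' flags eye-related components, zeroes them, and projects the remaining
#' components back. A component is flagged when the absolute correlation of
#' its time course with the EOG reference exceeds \code{corr_threshold}, or
#' when the fraction of its (absolute) scalp weights carried by frontal
#' channels reaches \code{frontal_fraction}. With no flagged components the
#' reconstruction equals the input to numerical precision.
#'
#' @param recording An \code{eeg_recording}.
#' @param eog_reference Numeric vector (sample-aligned EOG or frontal
#'   trace), or NULL to rely on the frontal-concentration criterion alone.
#' @param corr_threshold Absolute correlation flag threshold (default 0.7).
#' @param frontal_fraction Frontal scalp-weight concentration threshold
#'   (default 0.6).
#' @param frontal_labels Channels counted as frontal; default: montage
#'   positions with y >= 0.5 (FP/AF/F rows).
#' @param fit_highpass_hz High-pass corner for the ICA fitting copy.
#' @param max_fit_samples Upper bound on samples used to estimate the
#'   unmixing matrix (regular subsampling).
#' @return List with \code{recording} (cleaned) and \code{decomposition}
#'   (unmixing/mixing matrices, per-component flags and flag scores).
#' @export
remove_ocular_components <- function(recording, eog_reference = NULL,
                                     corr_threshold = 0.7,
                                     frontal_fraction = 0.6,
                                     frontal_labels = NULL,
                                     fit_highpass_hz = 1,
                                     max_fit_samples = 100000L) {
  X <- recording$data
  if (ncol(X) < 2L * nrow(X)) stop("ICA needs at least 2x more samples than channels")
  fit_rec <- apply_filter(recording,
                          filter_spec("highpass", 4, fit_highpass_hz))
  Xf <- fit_rec$data
  if (ncol(Xf) > max_fit_samples) {
    stride <- ceiling(ncol(Xf) / max_fit_samples)
    Xf <- Xf[, seq(1L, ncol(Xf), by = stride), drop = FALSE]
  }
  dec <- fast_ica(Xf)

  mu <- rowMeans(X)
  S <- dec$unmixing %*% (X - mu)          # component time courses

  if (is.null(frontal_labels))
    frontal_labels <- frontal_channels(recording$channel_labels)
  fr <- canonical_labels(recording$channel_labels) %in%
    canonical_labels(frontal_labels)

  k <- dec$n_comp
  corr_score <- rep(0, k)
  if (!is.null(eog_reference)) {
    if (length(eog_reference) != ncol(X))
      stop("EOG reference is not sample-aligned with the recording")
    corr_score <- abs(as.vector(stats::cor(t(S), eog_reference)))
  }
  absA <- abs(dec$mixing)
  frontal_score <- colSums(absA[fr, , drop = FALSE]) / colSums(absA)
  flags <- corr_score >= corr_threshold | frontal_score >= frontal_fraction

  keep <- which(!flags)
  cleaned <- dec$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  out <- recording
  out$data <- cleaned
  dimnames(out$data) <- dimnames(recording$data)
  out <- log_provenance(out, "ica_eog_removal", removed = sum(flags))
  decomposition <- list(unmixing = dec$unmixing, mixing = dec$mixing,
                        flags = flags, corr_score = corr_score,
                        frontal_score = frontal_score,
                        iterations = dec$iterations)
  list(recording = out, decomposition = decomposition)
}
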