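#' Sliding-window scheme for single-trial decoding
#'
#' Windows of \code{window_len_s} slide in \code{step_s} steps over the
#' time region of interest (tROI). Each window is labeled by its END time;
#' end labels run over the half-open interval (troi_lo, troi_hi] so the
#' default tROI [-1, 2.5] s with 50-ms steps yields exactly 70 models
#' (ends -0.95, -0.90, ..., 2.50), each window seeing only the 500 ms
#' preceding its label. Within a window, \code{n_amplitudes} equally
#' spaced potential amplitudes per channel are taken on the 50-ms grid
#' covering the half-open window [end - window_len, end).
#'
#' @param troi_s Length-2 numeric, time region of interest (s).
#' @param window_len_s Window length (s), default 0.5.
#' @param step_s Slide step (s), default 0.05.
#' @param n_amplitudes Amplitudes per channel per window, default 10.
#' @return Object of class \code{window_scheme} with the vector of window
#'   end times.
#' @export
window_scheme <- function(troi_s = c(-1.0, 2.5), window_len_s = 0.5,
                          step_s = 0.05, n_amplitudes = 10L) {
  stopifnot(troi_s[2] > troi_s[1], window_len_s > 0, step_s > 0)
  n_win <- round((troi_s[2] - troi_s[1]) / step_s)
  ends <- troi_s[1] + step_s * seq_len(n_win)
  structure(list(troi_s = troi_s, window_len_s = window_len_s,
                 step_s = step_s, n_amplitudes = as.integer(n_amplitudes),
                 window_ends_s = ends),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("Sliding-window scheme: %d windows of %g ms over (%g, %g] s, step %g ms, %d amplitudes/channel\n",
              length(x$window_ends_s), 1000 * x$window_len_s,
              x$troi_s[1], x$troi_s[2], 1000 * x$step_s, x$n_amplitudes))
  invisible(x)
}

#' Window amplitude features
#'
#' For each channel, the \code{n_amplitudes} EEG potential amplitudes on
#' the 50-ms grid covering the half-open 500-ms window ending at
#' \code{window_end_s}; channels are concatenated in montage order, so 33
#' channels give d = 330 features per trial.
#'
#' @param epochs An \code{epoch_set} at the analysis rate (100 Hz).
#' @param window_end_s Window end time (s, relative to onset).
#' @param scheme A \code{window_scheme}.
#' @return Numeric matrix trials x (channels * n_amplitudes).
#' @export
extract_window_features <- function(epochs, window_end_s,
                                    scheme = window_scheme()) {
  fs <- epochs$sampling_rate_hz
  na <- scheme$n_amplitudes
  stepf <- scheme$window_len_s / na
  offs <- -scheme$window_len_s + stepf * (0:(na - 1L))
  tt <- window_end_s + offs
  t0 <- epochs$time_axis[1]
  idx <- round((tt - t0) * fs) + 1L
  ntime <- dim(epochs$data)[3]
  if (any(idx < 1L | idx > ntime))
    stop(sprintf("window ending at %.2f s lies outside the epoch", window_end_s))
  d <- dim(epochs$data)
  # trials x channels x amplitudes, channels-major concatenation
  sub <- epochs$data[, , idx, drop = FALSE]
  # flatten to channel-major columns: ch1 amp1..ampK, ch2 amp1..ampK, ...
  out <- matrix(aperm(sub, c(1, 3, 2)), nrow = d[1])
  colnames(out) <- paste(rep(epochs$channel_labels, each = na),
                         rep(seq_len(na), d[2]), sep = "_")
  out
}

# stratified fold assignment, deterministic under the supplied seed
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds)
      stop("class ", cl, " has fewer trials (", length(idx),
           ") than folds (", folds, ")")
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Cross-validated sliding-window accuracy curve
#'
#' For every window of the scheme: extract features, run repeated
#' stratified k-fold cross-validation (repetition r reshuffles folds with
#' seed + r), refit the classifier per fold (binary \code{slda} for two
#' classes, one-vs-one ensemble otherwise), and record held-out accuracy.
#' The curve reports the mean and SD over the folds x repetitions
#' accuracies per window. Identical seeds reproduce the curve bit-exactly.
#'
#' @param epochs An \code{epoch_set} (only kept trials are used).
#' @param conditions Conditions to decode; default: all kept labels.
#' @param scheme A \code{window_scheme}.
#' @param folds Number of CV folds, default 5.
#' @param repetitions Number of CV repetitions, default 10.
#' @param seed Base RNG seed.
#' @param lambda Optional fixed shrinkage intensity.
#' @return Object of class \code{accuracy_curve}: data.frame with columns
#'   \code{window_time_s}, \code{accuracy}, \code{sd}; attributes carry
#'   the CV settings.
#' @export
cross_validated_curve <- function(epochs, conditions = NULL,
                                  scheme = window_scheme(),
                                  folds = 5L, repetitions = 10L, seed = 1L,
                                  lambda = NULL) {
  ep <- kept_epochs(epochs, conditions)
  y <- as.character(ep$labels)
  if (length(unique(y)) < 2L) stop("need at least two conditions")
  if (min(table(y)) < folds)
    stop("a class has fewer trials than folds")
  ends <- scheme$window_ends_s
  feats <- lapply(ends, function(e) extract_window_features(ep, e, scheme))
  fold_sets <- lapply(seq_len(repetitions),
                      function(r) stratified_folds(y, folds, seed + r))
  acc <- sd_ <- numeric(length(ends))
  for (wi in seq_along(ends)) {
    X <- feats[[wi]]
    a <- numeric(0)
    for (r in seq_len(repetitions)) {
      fa <- fold_sets[[r]]
      for (f in seq_len(folds)) {
        tr <- fa != f; te <- !tr
        pred <- fit_predict(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE], lambda)
        a <- c(a, mean(pred == y[te]))
      }
    }
    acc[wi] <- mean(a); sd_[wi] <- stats::sd(a)
  }
  curve <- data.frame(window_time_s = ends, accuracy = acc, sd = sd_)
  structure(curve,
            class = c("accuracy_curve", "data.frame"),
            subject = ep$subject_id, conditions = unique(y),
            folds = folds, repetitions = repetitions, seed = seed,
            n_trials = length(y))
}

fit_predict <- function(Xtr, ytr, Xte, lambda = NULL) {
  if (length(unique(ytr)) == 2L) {
    m <- fit_slda(Xtr, ytr, lambda = lambda)
    predict(m, Xte)
  } else {
    m <- fit_slda_ovo(Xtr, ytr, lambda = lambda)
    predict(m, Xte)
  }
}

#' @export
print.accuracy_curve <- function(x, ...) {
  pk <- peak_performance(x)
  cat(sprintf("Accuracy curve: %d windows [%g, %g] s; peak %.1f%% at %g s (n = %d trials)\n",
              nrow(x), x$window_time_s[1], x$window_time_s[nrow(x)],
              100 * pk$accuracy, pk$time_s, attr(x, "n_trials")))
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, chance = NULL, ...) {
  graphics::plot(x$window_time_s, x$accuracy, type = "l", lwd = 2,
                 xlab = "window end time relative to onset (s)",
                 ylab = "cross-validated accuracy", ylim = c(0, 1), ...)
  graphics::polygon(c(x$window_time_s, rev(x$window_time_s)),
                    c(x$accuracy - x$sd, rev(x$accuracy + x$sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$window_time_s, x$accuracy, lwd = 2)
  graphics::abline(v = 0, lty = 3)
  if (!is.null(chance)) graphics::abline(h = chance, lty = 2, col = "red")
  invisible(x)
}

#' Peak of an accuracy curve
#'
#' @param curve An \code{accuracy_curve} (or data.frame with
#'   \code{window_time_s} and \code{accuracy}).
#' @return List with \code{accuracy} and \code{time_s}; ties resolve to
#'   the earliest window.
#' @export
peak_performance <- function(curve) {
  if (!nrow(curve)) stop("empty accuracy curve")
  i <- which(curve$accuracy == max(curve$accuracy))[1]
  list(accuracy = curve$accuracy[i], time_s = curve$window_time_s[i])
}

#' Grand-average accuracy curve over subjects
#'
#' Pointwise mean of per-subject curves (the grand peak is therefore at
#' most the mean of the subject-specific peaks).
#'
#' @param curves List of \code{accuracy_curve}s on identical window grids.
#' @return An \code{accuracy_curve} with SD = between-subject SD.
#' @export
grand_average_curve <- function(curves) {
  tt <- curves[[1]]$window_time_s
  for (cu in curves) stopifnot(isTRUE(all.equal(cu$window_time_s, tt)))
  A <- sapply(curves, function(cu) cu$accuracy)
  out <- data.frame(window_time_s = tt, accuracy = rowMeans(A),
                    sd = apply(A, 1, stats::sd))
  structure(out, class = c("accuracy_curve", "data.frame"),
            subject = "grand", n_trials = sum(sapply(curves, attr, "n_trials")))
}

#' Cross-validated confusion matrix at one window
#'
#' Pools held-out predictions over folds and repetitions at a single
#' window and tabulates them against the true conditions.
#'
#' @inheritParams cross_validated_curve
#' @param window_time_s Window end time (s).
#' @return Object of class \code{confusion_matrix}: \code{counts} (k x k,
#'   rows = true), \code{normalized} (row-stochastic), \code{tpr}
#'   (diagonal of the normalized form).
#' @export
confusion_at <- function(epochs, window_time_s, conditions = NULL,
                         scheme = window_scheme(), folds = 5L,
                         repetitions = 10L, seed = 1L, lambda = NULL) {
  ep <- kept_epochs(epochs, conditions)
  y <- as.character(ep$labels)
  cls <- sort(unique(y))
  X <- extract_window_features(ep, window_time_s, scheme)
  counts <- matrix(0L, length(cls), length(cls),
                   dimnames = list(true = cls, predicted = cls))
  for (r in seq_len(repetitions)) {
    fa <- stratified_folds(y, folds, seed + r)
    for (f in seq_len(folds)) {
      tr <- fa != f; te <- !tr
      te_idx <- which(te)
      pred <- fit_predict(X[tr, , drop = FALSE], y[tr],
                          X[te_idx, , drop = FALSE], lambda)
      for (j in seq_along(te_idx))
        counts[y[te_idx[j]], pred[j]] <- counts[y[te_idx[j]], pred[j]] + 1L
    }
  }
  rs <- rowSums(counts)
  normalized <- sweep(counts, 1L, pmax(rs, 1L), "/")
  structure(list(counts = counts, normalized = normalized,
                 tpr = diag(normalized), window_time_s = window_time_s),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Confusion matrix at %g s (row-normalized):\n", x$window_time_s))
  print(round(x$normalized, digits))
  cat("TPR:", paste(sprintf("%s=%.1f%%", names(x$tpr), 100 * x$tpr),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted-Wald upper chance bound
#'
#' Upper confidence bound on the accuracy attainable by guessing among k
#' classes, from the pseudo-count-adjusted (adjusted-Wald) binomial
#' interval: with p0 = 1/k, x = n p0 and z the one-sided normal quantile
#' at 1 - alpha,
#'
#'   p_tilde = (x + z^2/2) / (n + z^2),
#'   bound = p_tilde + z sqrt(p_tilde (1 - p_tilde) / (n + z^2)).
#'
#' Accuracies above the bound are deemed better than chance at level
#' alpha.
#'
#' @param n_trials Number of trials the accuracy is computed from.
#' @param n_classes Number of classes k.
#' @param alpha One-sided level, default 0.05.
#' @return Object of class \code{chance_bound} with element \code{bound}.
#' @export
chance_upper_bound <- function(n_trials, n_classes, alpha = 0.05) {
  if (n_trials < 1L || n_classes < 2L) stop("need n >= 1 and k >= 2")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  p0 <- 1 / n_classes
  z <- stats::qnorm(1 - alpha)
  x <- n_trials * p0
  pt <- (x + z^2 / 2) / (n_trials + z^2)
  bound <- pt + z * sqrt(pt * (1 - pt) / (n_trials + z^2))
  structure(list(n_trials = n_trials, n_classes = n_classes,
                 alpha = alpha, bound = bound),
            class = "chance_bound")
}

#' @export
print.chance_bound <- function(x, ...) {
  cat(sprintf("Adjusted-Wald chance bound: %.1f%% (n = %d, k = %d, alpha = %g)\n",
              100 * x$bound, x$n_trials, x$n_classes, x$alpha))
  invisible(x)
}
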