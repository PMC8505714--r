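#' Grand-average MRCP with confidence bands
#'
#' Pointwise mean waveform per condition and channel over kept trials
#' (pooled across subjects by default, matching the "mean over all trials
#' of all subjects" convention), with a t-based 95 percent confidence
#' interval: mean +- t(0.975, n-1) * SE. With \code{by = "subject"} the
#' averaging (and CI) is over subject means instead.
#'
#' @param epochs An \code{epoch_set} (or list of epoch sets, pooled).
#' @param conditions Conditions to include; default all present.
#' @param alpha CI level is 1 - alpha (default 0.05).
#' @param by \code{"trial"} (default) or \code{"subject"}.
#' @return Object of class \code{grand_average}: arrays \code{mean},
#'   \code{lower}, \code{upper} of dim conditions x channels x time,
#'   \code{n_trials} per condition, \code{time_axis},
#'   \code{channel_labels}.
#' @export
grand_average <- function(epochs, conditions = NULL, alpha = 0.05,
                          by = c("trial", "subject")) {
  by <- match.arg(by)
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  time_axis <- epochs[[1]]$time_axis
  labels <- epochs[[1]]$channel_labels
  all_conds <- unique(unlist(lapply(epochs, function(e) e$labels[e$kept])))
  if (is.null(conditions)) conditions <- all_conds
  nc <- length(labels); nt <- length(time_axis); nk <- length(conditions)
  mean_a <- lo_a <- hi_a <- array(NA_real_, c(nk, nc, nt),
                                  dimnames = list(conditions, labels, NULL))
  n_used <- setNames(integer(nk), conditions)
  for (ci in seq_len(nk)) {
    unit_mats <- list()
    for (e in epochs) {
      sel <- e$kept & e$labels == conditions[ci]
      if (!any(sel)) next
      if (by == "trial") {
        for (i in which(sel)) unit_mats <- c(unit_mats, list(e$data[i, , ]))
      } else {
        unit_mats <- c(unit_mats,
                       list(apply(e$data[which(sel), , , drop = FALSE],
                                  c(2, 3), mean)))
      }
    }
    n <- length(unit_mats)
    if (n < 2L) stop("need at least 2 units (trials/subjects) for condition ",
                     conditions[ci])
    arr <- array(unlist(unit_mats), c(nc, nt, n))
    m <- apply(arr, c(1, 2), mean)
    se <- apply(arr, c(1, 2), stats::sd) / sqrt(n)
    tq <- stats::qt(1 - alpha / 2, n - 1)
    mean_a[ci, , ] <- m
    lo_a[ci, , ] <- m - tq * se
    hi_a[ci, , ] <- m + tq * se
    n_used[ci] <- n
  }
  structure(list(mean = mean_a, lower = lo_a, upper = hi_a,
                 n_trials = n_used, time_axis = time_axis,
                 channel_labels = labels, alpha = alpha, by = by),
            class = "grand_average")
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("Grand-average MRCP (%s mode): %d conditions x %d channels x %d samples\n",
              x$by, dim(x$mean)[1], dim(x$mean)[2], dim(x$mean)[3]))
  cat("  n per condition:",
      paste(sprintf("%s=%d", names(x$n_trials), x$n_trials),
            collapse = ", "), "\n")
  invisible(x)
}

# exact two-sided Mann-Whitney p-value by enumeration of the U
# distribution (no ties), via the standard counting recurrence
exact_ranksum_p <- function(u, n1, n2) {
  # number of ways to obtain each U value among choose(n1+n2, n1) splits
  counts <- vapply(0:(n1 * n2), function(k) mw_count(k, n1, n2), numeric(1))
  total <- sum(counts)
  p_le <- sum(counts[seq_len(u + 1)]) / total
  p_ge <- sum(counts[(u + 1):(n1 * n2 + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

mw_count_env <- new.env(parent = emptyenv())
mw_count <- function(u, n1, n2) {
  key <- paste(n1, n2, sep = "_")
  tab <- mw_count_env[[key]]
  if (is.null(tab)) {
    # dynamic programme over the generating function of U
    poly <- 1
    for (i in seq_len(n1)) {
      # multiply by (1 - x^(n2+i)) / (1 - x^i), done as polynomial ops
      poly <- polydiv_cum(polymul_gap(poly, n2 + i), i)
    }
    tab <- poly
    mw_count_env[[key]] <- tab
  }
  if (u + 1 > length(tab)) 0 else tab[u + 1]
}
polymul_gap <- function(p, g) {      # p(x) * (1 - x^g)
  q <- c(p, numeric(g)) - c(numeric(g), p)
  q
}
polydiv_cum <- function(p, g) {      # p(x) / (1 - x^g), power series
  q <- p
  for (i in seq_len(length(q) - g)) q[i + g] <- q[i + g] + q[i]
  q
}

#' Sample-wise Wilcoxon rank-sum track
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test at every time sample of
#' one channel, comparing two sets of trials. For n_A + n_B > 20 (or in
#' the presence of ties) the tie-corrected normal approximation is used;
#' otherwise the exact null distribution is enumerated. Samples where all
#' values are tied get p = 1. No multiple-comparison correction is applied
#' (an FDR option is available).
#'
#' @param epochs_a,epochs_b Matrices trials x samples (one channel), or
#'   \code{epoch_set}s with \code{channel} given.
#' @param channel Channel label used when epoch sets are passed.
#' @param alpha Significance level for the mask (default 0.05).
#' @param correct \code{"none"} (default) or \code{"fdr"}.
#' @return Object of class \code{significance_track}: \code{p} per sample,
#'   logical \code{significant} mask (p < alpha).
#' @export
samplewise_ranksum <- function(epochs_a, epochs_b, channel = NULL,
                               alpha = 0.05, correct = c("none", "fdr")) {
  correct <- match.arg(correct)
  pick <- function(e) {
    if (inherits(e, "epoch_set")) {
      if (is.null(channel)) stop("channel must be given with epoch sets")
      ci <- match(channel, e$channel_labels)
      if (is.na(ci)) stop("channel ", channel, " not in epoch set")
      e$data[e$kept, ci, , drop = TRUE]
    } else as.matrix(e)
  }
  A <- pick(epochs_a); B <- pick(epochs_b)
  if (ncol(A) != ncol(B)) stop("time axes differ between groups")
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 5L || n2 < 5L) stop("need at least 5 trials per group")
  ns <- ncol(A)
  p <- numeric(ns)
  for (s in seq_len(ns)) {
    x <- A[, s]; y <- B[, s]
    ties <- anyDuplicated(c(x, y)) > 0L
    if (length(unique(c(x, y))) == 1L) { p[s] <- 1; next }
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (!ties && (n1 + n2) <= 20L) {
      p[s] <- exact_ranksum_p(as.integer(round(u)), n1, n2)
    } else {
      mu <- n1 * n2 / 2
      tie_tab <- table(c(x, y))
      sig2 <- n1 * n2 / 12 *
        ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
           ((n1 + n2) * (n1 + n2 - 1)))
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p[s] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  if (correct == "fdr") p <- stats::p.adjust(p, "fdr")
  structure(list(p = p, significant = p < alpha, alpha = alpha,
                 n = c(n1, n2)),
            class = "significance_track")
}

#' @export
print.significance_track <- function(x, ...) {
  cat(sprintf("Sample-wise rank-sum track: %d samples, %.1f%% significant at alpha = %g (n = %d vs %d)\n",
              length(x$p), 100 * mean(x$significant), x$alpha, x$n[1], x$n[2]))
  invisible(x)
}

#' Topographic frame: per-channel mean amplitude over a time window
#'
#' @param ga A \code{grand_average}.
#' @param time_window Length-2 numeric (s), inclusive, within the epoch.
#' @param condition Condition name (default: first).
#' @return Data.frame \code{label}, \code{x}, \code{y},
#'   \code{amplitude_uv}.
#' @export
topographic_frame <- function(ga, time_window, condition = NULL) {
  if (is.null(condition)) condition <- dimnames(ga$mean)[[1]][1]
  sel <- ga$time_axis >= time_window[1] & ga$time_axis <= time_window[2]
  if (!any(sel)) stop("empty time window")
  amp <- apply(ga$mean[condition, , sel, drop = FALSE], 2, mean)
  co <- montage_coordinates(ga$channel_labels)
  co$amplitude_uv <- as.vector(amp)
  co
}
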