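#' Per-trial rejection report
#'
#' @param trial_id Integer trial identifiers.
#' @param reasons List of character vectors (empty = kept).
#' @return Object of class \code{rejection_report}: data.frame with columns
#'   \code{trial_id}, \code{kept}, \code{reasons} (';'-joined), plus a
#'   summary attribute.
#' @export
rejection_report <- function(trial_id, reasons) {
  stopifnot(length(trial_id) == length(reasons))
  kept <- lengths(reasons) == 0L
  df <- data.frame(trial_id = trial_id, kept = kept,
                   reasons = vapply(reasons, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  attr(df, "summary") <- list(total = length(kept), kept = sum(kept),
                              rejected = sum(!kept),
                              fraction_rejected = mean(!kept))
  class(df) <- c("rejection_report", "data.frame")
  df
}

#' @export
print.rejection_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Rejection report: %d/%d trials rejected (%.1f%%)\n",
              s$rejected, s$total, 100 * s$fraction_rejected))
  tab <- table(unlist(strsplit(x$reasons[!x$kept], ";")))
  if (length(tab))
    cat("  reasons:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Merge rejection reports trial-wise
#'
#' @param ... \code{rejection_report}s over the same trials.
#' @return The combined \code{rejection_report} (union of reasons).
#' @export
merge_reports <- function(...) {
  reps <- list(...)
  ids <- reps[[1]]$trial_id
  reasons <- lapply(seq_along(ids), function(i) {
    r <- unlist(lapply(reps, function(rp) {
      stopifnot(identical(rp$trial_id, ids))
      v <- rp$reasons[i]
      if (nzchar(v)) strsplit(v, ";")[[1]] else character(0)
    }))
    unique(r)
  })
  rejection_report(ids, reasons)
}

#' Reaction-time screening
#'
#' Discards trials whose reaction time exceeds the threshold; the
#' inequality is strict, so RT exactly at the threshold is kept.
#' No-movement trials (RT = NA) pass vacuously. Negative RTs indicate a
#' data/marker fault and are flagged as \code{channel_noise}.
#'
#' @param rt_s Numeric vector of per-trial reaction times in seconds (NA
#'   for no-movement trials).
#' @param threshold_s Rejection threshold (s), default 2.
#' @param trial_id Optional trial identifiers.
#' @return A \code{rejection_report}.
#' @export
reject_high_rt <- function(rt_s, threshold_s = 2.0,
                           trial_id = seq_along(rt_s)) {
  reasons <- lapply(rt_s, function(r) {
    if (is.na(r)) character(0)
    else if (r < 0) "channel_noise"
    else if (r > threshold_s) "rt_gt_2s"
    else character(0)
  })
  rejection_report(trial_id, reasons)
}

#' Amplitude-threshold rejection
#'
#' A trial is rejected iff any retained channel/sample exceeds the limit in
#' absolute value; the boundary itself is kept ("exceeds" is strict).
#'
#' @param epochs An \code{epoch_set} in microvolts.
#' @param limit_uv Threshold, default 200.
#' @return A \code{rejection_report}.
#' @export
reject_by_amplitude <- function(epochs, limit_uv = 200) {
  nt <- dim(epochs$data)[1]
  reasons <- vector("list", nt)
  for (i in seq_len(nt)) {
    m <- max(abs(epochs$data[i, , ]), na.rm = TRUE)
    reasons[[i]] <- if (is.finite(m) && m > limit_uv) "amplitude"
    else character(0)
  }
  rejection_report(seq_len(nt), reasons)
}

# per-trial, per-channel outlier statistics:
#  - joint probability: mean negative log of the empirical density of the
#    trial's samples, under a 50-bin histogram pooled over all trials of
#    that channel (EEGLAB-style)
#  - sample kurtosis m4/m2^2 of the trial's samples
trial_statistics <- function(epochs, n_bins = 50L) {
  d <- dim(epochs$data)
  nt <- d[1]; nc <- d[2]
  jp <- kt <- matrix(NA_real_, nt, nc)
  for (c in seq_len(nc)) {
    ch <- epochs$data[, c, , drop = FALSE]
    pooled <- as.vector(ch)
    br <- seq(min(pooled), max(pooled), length.out = n_bins + 1L)
    if (br[1] == br[n_bins + 1L]) br <- br[1] + seq(-1, 1, length.out = n_bins + 1L)
    h <- tabulate(findInterval(pooled, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
    p <- h / sum(h)
    for (i in seq_len(nt)) {
      x <- epochs$data[i, c, ]
      bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
      jp[i, c] <- mean(-log(pmax(p[bin], .Machine$double.xmin)))
      m2 <- mean((x - mean(x))^2)
      kt[i, c] <- if (m2 > 0) mean((x - mean(x))^4) / m2^2 else 0
    }
  }
  list(joint_probability = jp, kurtosis = kt)
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd == 0] <- Inf
  sweep(sweep(m, 2L, mu), 2L, sd, "/")
}

#' Joint-probability / kurtosis outlier rejection
#'
#' Computes two statistics per trial and channel — the improbability of
#' the trial's amplitudes under the channel's pooled empirical
#' distribution (50-bin histogram), and the sample kurtosis — z-scores
#' each statistic across trials, and rejects trials beyond
#' \code{z_limit} standard deviations.
#'
#' Aggregation across channels: \code{"global"} (default) averages each
#' statistic over channels before z-scoring, giving one pair of scores per
#' trial (this keeps the false-rejection rate of clean Gaussian data near
#' the nominal 3-SD level); \code{"channel"} rejects when any single
#' channel's score exceeds the limit (conservative; sensitive to focal
#' channel noise, but with many channels it rejects a substantial fraction
#' of clean trials by multiplicity).
#'
#' @param epochs An \code{epoch_set}.
#' @param z_limit Rejection threshold in SD units, default 3.
#' @param aggregate \code{"global"} or \code{"channel"}.
#' @param min_trials Below this trial count a warning is issued and no
#'   trial is rejected (the pooled histogram is unstable).
#' @return A \code{rejection_report} with the trial x channel statistics
#'   attached as attribute \code{"statistics"}.
#' @export
reject_statistical_outliers <- function(epochs, z_limit = 3.0,
                                        aggregate = c("global", "channel"),
                                        min_trials = 10L) {
  aggregate <- match.arg(aggregate)
  nt <- dim(epochs$data)[1]
  if (nt < min_trials) {
    warning("fewer than ", min_trials,
            " trials: statistical rejection skipped")
    rep <- rejection_report(seq_len(nt), rep(list(character(0)), nt))
    return(rep)
  }
  st <- trial_statistics(epochs)
  if (aggregate == "global") {
    zjp <- as.vector(scale(rowMeans(st$joint_probability)))
    zkt <- as.vector(scale(rowMeans(st$kurtosis)))
    jp_bad <- abs(zjp) > z_limit
    kt_bad <- abs(zkt) > z_limit
  } else {
    zjp_m <- zscore_cols(st$joint_probability)
    zkt_m <- zscore_cols(st$kurtosis)
    jp_bad <- apply(abs(zjp_m) > z_limit, 1L, any)
    kt_bad <- apply(abs(zkt_m) > z_limit, 1L, any)
  }
  jp_bad[is.na(jp_bad)] <- FALSE
  kt_bad[is.na(kt_bad)] <- FALSE
  reasons <- lapply(seq_len(nt), function(i)
    c(if (jp_bad[i]) "joint_probability", if (kt_bad[i]) "kurtosis"))
  rep <- rejection_report(seq_len(nt), reasons)
  attr(rep, "statistics") <- st
  rep
}
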