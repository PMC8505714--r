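#' Per-trial reaction times from the event table
#'
#' The reaction time is the interval between the "Go" cue and the first
#' button release that follows it within the same trial. No-movement
#' trials have no button release and get \code{NA}; grasp trials whose
#' release is missing (or precedes the Go cue) are flagged.
#'
#' @param events An \code{event_table}.
#' @param sampling_rate_hz Sampling rate the event samples refer to.
#' @return Data.frame with one row per trial: \code{trial}, \code{code},
#'   \code{go_sample}, \code{release_sample}, \code{rt_s}, \code{flagged}.
#' @export
compute_rt <- function(events, sampling_rate_hz) {
  starts <- events$sample[events$kind == "trial_start"]
  if (!length(starts)) stop("event table has no trial_start events")
  bounds <- c(starts, Inf)
  n <- length(starts)
  out <- data.frame(trial = seq_len(n), code = NA_integer_,
                    go_sample = NA_integer_, release_sample = NA_integer_,
                    rt_s = NA_real_, flagged = FALSE)
  for (i in seq_len(n)) {
    inside <- events$sample >= bounds[i] & events$sample < bounds[i + 1]
    tev <- events[inside, , drop = FALSE]
    code <- tev$code[tev$kind == "condition_marker"]
    out$code[i] <- if (length(code)) code[1] else NA_integer_
    go <- tev$sample[tev$kind == "go"]
    rel <- tev$sample[tev$kind == "button_release"]
    if (!length(go)) { out$flagged[i] <- TRUE; next }
    out$go_sample[i] <- go[1]
    is_grasp <- is.na(out$code[i]) || out$code[i] != 6L
    rel_after <- rel[rel >= go[1]]
    if (length(rel_after)) {
      out$release_sample[i] <- rel_after[1]
      out$rt_s[i] <- (rel_after[1] - go[1]) / sampling_rate_hz
    } else if (is_grasp && length(rel)) {
      out$flagged[i] <- TRUE        # release exists but precedes Go
    } else if (is_grasp) {
      out$flagged[i] <- TRUE        # missing release on a grasp trial
    }
  }
  out
}

#' Virtual movement onsets
#'
#' One subject-level mean reaction time is computed over all retained
#' grasp trials (RT defined, not flagged, RT <= \code{rt_threshold_s} —
#' the RT screening precedes this mean), pooled across conditions. Every
#' trial's virtual onset is its Go sample plus the rounded mean RT in
#' samples; no-movement trials share the Go event and receive an onset
#' too.
#'
#' @param rt_table Output of [compute_rt()].
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param rt_threshold_s RTs above this are excluded from the mean
#'   (strictly greater), default 2 s.
#' @return List with \code{mean_rt_s}, \code{sd_rt_s} and integer
#'   \code{onsets} (0-based samples, one per trial).
#' @export
compute_virtual_onsets <- function(rt_table, sampling_rate_hz,
                                   rt_threshold_s = 2.0) {
  ok <- !is.na(rt_table$rt_s) & !rt_table$flagged &
    rt_table$rt_s <= rt_threshold_s & rt_table$rt_s >= 0
  if (!any(ok)) stop("no retained reaction times for this subject")
  mean_rt <- mean(rt_table$rt_s[ok])
  onsets <- rt_table$go_sample + as.integer(round(mean_rt * sampling_rate_hz))
  list(mean_rt_s = mean_rt, sd_rt_s = stats::sd(rt_table$rt_s[ok]),
       onsets = onsets)
}

#' Grasp interval from a force trace
#'
#' Thresholds the per-trial force trace at a fraction of its maximum:
#' grasp start is the first upward crossing after the movement onset,
#' release the last downward crossing, duration their difference.
#'
#' @param force Numeric force trace for one trial window (values >= 0),
#'   starting at the movement onset.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param threshold Fraction of the trace maximum (default 0.1).
#' @return List with \code{grasp_start_s}, \code{release_s},
#'   \code{duration_s}, \code{flagged}.
#' @export
detect_grasp_interval <- function(force, sampling_rate_hz, threshold = 0.1) {
  if (any(force < 0)) stop("force trace must be non-negative")
  mx <- max(force)
  flagged <- list(grasp_start_s = NA_real_, release_s = NA_real_,
                  duration_s = NA_real_, flagged = TRUE)
  if (mx <= 0) return(flagged)
  above <- force > threshold * mx
  if (!any(above)) return(flagged)
  first <- which(above)[1]
  last <- which(above)[sum(above)]
  list(grasp_start_s = (first - 1) / sampling_rate_hz,
       release_s = (last - 1) / sampling_rate_hz,
       duration_s = (last - first) / sampling_rate_hz,
       flagged = FALSE)
}

#' Behavioral summary for one subject
#'
#' Combines reaction times, virtual onsets and force-derived grasp timing
#' into one per-trial table plus per-condition duration means.
#'
#' @param sim A \code{synthetic_subject}, or a list with \code{recording}
#'   and \code{events}.
#' @param rt_threshold_s RT screening threshold (s).
#' @param conditions Optional condition names for codes 1..6.
#' @return List with \code{trials} (data.frame), \code{mean_rt_s},
#'   \code{sd_rt_s}, and \code{condition_durations} (named means, grasp
#'   conditions only).
#' @export
behavioral_summary <- function(sim, rt_threshold_s = 2.0,
                               conditions = NULL) {
  fs <- sim$recording$sampling_rate_hz
  rt <- compute_rt(sim$events, fs)
  vo <- compute_virtual_onsets(rt, fs, rt_threshold_s)
  trial_len <- diff(c(sim$events$sample[sim$events$kind == "trial_start"],
                      ncol(sim$recording$data)))
  starts <- sim$events$sample[sim$events$kind == "trial_start"]
  force <- sim$recording$aux$force
  n <- nrow(rt)
  gs <- rel <- dur <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(rt$code[i]) && rt$code[i] == 6L) next
    a <- vo$onsets[i]; b <- starts[i] + trial_len[i]
    if (is.na(a) || a >= b) next
    f <- force[(a + 1):b]
    g <- detect_grasp_interval(f, fs)
    if (!g$flagged) { gs[i] <- g$grasp_start_s; rel[i] <- g$release_s
                      dur[i] <- g$duration_s }
  }
  trials <- cbind(rt, virtual_onset_sample = vo$onsets,
                  grasp_start_s = gs, release_s = rel, duration_s = dur)
  cond_names <- if (!is.null(conditions)) conditions
                else as.character(1:6)
  grasp <- !is.na(trials$code) & trials$code != 6L & !is.na(dur)
  cd <- tapply(dur[grasp], cond_names[trials$code[grasp]], mean)
  list(trials = trials, mean_rt_s = vo$mean_rt_s, sd_rt_s = vo$sd_rt_s,
       condition_durations = cd)
}

#' One-way repeated-measures ANOVA with Mauchly's sphericity test
#'
#' Classical within-subject one-way ANOVA on an n-subject x k-condition
#' table of means: F = MS_condition / MS_(condition x subject) with
#' df = (k-1, (k-1)(n-1)). Mauchly's W is computed from the covariance of
#' the within-subject data projected on orthonormal contrasts, with its
#' chi-square approximation. When Mauchly's test rejects sphericity
#' (p < 0.05) the Greenhouse-Geisser corrected p-value is reported
#' alongside.
#'
#' @param durations n x k numeric matrix (rows subjects, columns
#'   conditions), complete.
#' @return Object of class \code{rm_anova}: list with \code{F}, \code{df},
#'   \code{p}, \code{mauchly_w}, \code{mauchly_p}, \code{gg_epsilon},
#'   \code{p_gg} (NA unless sphericity is rejected).
#' @export
duration_anova <- function(durations) {
  Y <- as.matrix(durations)
  if (any(is.na(Y))) stop("missing cells in the subject x condition table")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3L || k < 2L) stop("need at least 3 subjects and 2 conditions")
  grand <- mean(Y)
  subj_m <- rowMeans(Y); cond_m <- colMeans(Y)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  Fv <- if (ss_cond <= .Machine$double.eps * abs(ss_tot)) 0
        else (ss_cond / df1) / (ss_err / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  # Mauchly's W on orthonormal contrasts of the condition covariance
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                       # k x (k-1), orthonormal
  S <- crossprod(C, stats::cov(Y)) %*% C
  W <- if (sum(diag(S)) <= 0) 1 else det(S) / (sum(diag(S)) / df1)^df1
  dcorr <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
  chi <- -(n - 1) * dcorr * log(max(W, .Machine$double.xmin))
  df_m <- k * df1 / 2 - 1
  mauchly_p <- if (df_m > 0) stats::pchisq(chi, df_m, lower.tail = FALSE) else NA_real_
  eps <- sum(diag(S))^2 / (df1 * sum(S^2))
  p_gg <- NA_real_
  if (!is.na(mauchly_p) && mauchly_p < 0.05)
    p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)

  structure(list(F = Fv, df = c(df1, df2), p = p,
                 mauchly_w = W, mauchly_p = mauchly_p,
                 gg_epsilon = eps, p_gg = p_gg,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  Mauchly's W = %.4f, p = %.4g%s\n", x$mauchly_w, x$mauchly_p,
              if (!is.na(x$p_gg))
                sprintf("; Greenhouse-Geisser eps = %.3f, corrected p = %.4g",
                        x$gg_epsilon, x$p_gg) else ""))
  invisible(x)
}
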