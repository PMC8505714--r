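#' Continuous multichannel EEG recording
#'
#' Container for a channels x samples matrix in microvolts with channel
#' labels, sampling rate and sample-aligned auxiliary channels (pressure
#' button, force transducer). Time is sample-indexed and 0-based: sample
#' index i corresponds to time i / sampling_rate_hz seconds.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector, one label per row of \code{data}.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param reference_label Label of the recording reference.
#' @param aux Named list of numeric vectors (e.g. \code{button},
#'   \code{force}), each of length \code{ncol(data)}.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate_hz,
                          reference_label = "M1", aux = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop("channel label count (", length(channel_labels),
         ") does not match data row count (", nrow(data), ")")
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive")
  for (nm in names(aux))
    if (length(aux[[nm]]) != ncol(data))
      stop("aux channel '", nm, "' is not sample-aligned with the EEG data")
  rownames(data) <- as.character(channel_labels)
  structure(list(data = data,
                 channel_labels = as.character(channel_labels),
                 sampling_rate_hz = sampling_rate_hz,
                 reference_label = reference_label,
                 aux = aux,
                 provenance = list()),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %.5g Hz (%.6g s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  if (length(x$aux)) cat("  aux channels:", paste(names(x$aux), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  processing:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

log_provenance <- function(rec, op, ...) {
  rec$provenance <- c(rec$provenance, list(c(list(op = op), list(...))))
  rec
}

#' Typed, sample-indexed event table
#'
#' @param sample Integer vector of 0-based sample indices.
#' @param kind Character vector: one of \code{trial_start}, \code{cue},
#'   \code{go}, \code{button_release}, \code{condition_marker}, or
#'   \code{other}.
#' @param code Integer condition code (1..6) for condition markers, NA
#'   otherwise.
#' @return A data.frame of class \code{event_table}, sorted by sample.
#' @export
event_table <- function(sample, kind, code = NA_integer_) {
  kinds <- c("trial_start", "cue", "go", "button_release",
             "condition_marker", "other")
  kind <- as.character(kind)
  if (!all(kind %in% kinds))
    stop("unknown event kind(s): ",
         paste(unique(setdiff(kind, kinds)), collapse = ", "))
  df <- data.frame(sample = as.integer(sample), kind = kind,
                   code = rep_len(as.integer(code), length(sample)),
                   stringsAsFactors = FALSE)
  bad <- df$kind == "condition_marker" & !(df$code %in% 1:6)
  if (any(bad)) stop("condition marker codes must lie in 1..6")
  df <- df[order(df$sample), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write / read events as CSV (sample, kind, code)
#' @param events An \code{event_table}.
#' @param path Output CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(df$sample, df$kind, df$code)
}

#' Epoch a continuous recording around per-trial onsets
#'
#' Cuts trials x channels x samples windows time-locked to the given onset
#' samples. Windows are half-open in sample space:
#' \code{[onset + round(w_lo * fs), onset + round(w_hi * fs))}, so the
#' default (-1.5, 2.5) s window at 100 Hz yields exactly 400 samples and the
#' t = 0 sample is included. Onsets whose window would leave the recording
#' are flagged (kept = FALSE, reason "edge"), not dropped.
#'
#' @param recording An \code{eeg_recording}.
#' @param onsets Integer vector of 0-based onset sample indices.
#' @param window Length-2 numeric, window in seconds relative to onset.
#' @param labels Optional per-trial condition labels.
#' @param subject_id Optional subject identifier.
#' @return An object of class \code{epoch_set}.
#' @export
epoch_recording <- function(recording, onsets, window = c(-1.5, 2.5),
                            labels = NULL, subject_id = NA_character_) {
  fs <- recording$sampling_rate_hz
  lo <- round(window[1] * fs)
  hi <- round(window[2] * fs)
  if (hi <= lo) stop("empty epoch window")
  len <- hi - lo
  nt <- length(onsets)
  nc <- n_channels(recording)
  ns <- n_samples(recording)
  dat <- array(NA_real_, dim = c(nt, nc, len))
  kept <- rep(TRUE, nt)
  reason <- rep("", nt)
  for (i in seq_len(nt)) {
    a <- onsets[i] + lo          # 0-based start
    b <- onsets[i] + hi          # 0-based stop (exclusive)
    if (a < 0 || b > ns) {
      kept[i] <- FALSE
      reason[i] <- "edge"
      next
    }
    dat[i, , ] <- recording$data[, (a + 1):b, drop = FALSE]
  }
  epoch_set(dat, time_axis = (lo:(hi - 1)) / fs,
            sampling_rate_hz = fs,
            channel_labels = recording$channel_labels,
            labels = labels, subject_id = subject_id,
            kept = kept, reject_reason = reason,
            onsets = as.integer(onsets))
}

#' Epoch container
#'
#' @param data trials x channels x samples array (microvolts).
#' @param time_axis Seconds relative to the movement onset (t = 0 at onset).
#' @param sampling_rate_hz Sampling rate of the epoched data.
#' @param channel_labels Channel labels.
#' @param labels Per-trial condition labels (character) or NULL.
#' @param subject_id Subject identifier.
#' @param kept Logical per-trial retention mask.
#' @param reject_reason Character per-trial reason ("" if kept).
#' @param onsets Original onset sample indices (0-based), optional.
#' @return An object of class \code{epoch_set}.
#' @export
epoch_set <- function(data, time_axis, sampling_rate_hz, channel_labels,
                      labels = NULL, subject_id = NA_character_,
                      kept = NULL, reject_reason = NULL, onsets = NULL) {
  stopifnot(length(dim(data)) == 3L)
  nt <- dim(data)[1]
  if (dim(data)[2] != length(channel_labels))
    stop("channel label count does not match epoch data")
  if (dim(data)[3] != length(time_axis))
    stop("time axis length does not match epoch data")
  if (!is.null(labels) && length(labels) != nt)
    stop("labels length must equal trial count")
  if (is.null(kept)) kept <- rep(TRUE, nt)
  if (is.null(reject_reason)) reject_reason <- rep("", nt)
  structure(list(data = data, time_axis = time_axis,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = as.character(channel_labels),
                 labels = labels, subject_id = subject_id,
                 kept = kept, reject_reason = reject_reason,
                 onsets = onsets),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %.5g Hz\n",
              d[1], d[2], d[3], x$sampling_rate_hz))
  cat(sprintf("  time axis [%.3g, %.3g] s; %d trials kept\n",
              x$time_axis[1], x$time_axis[length(x$time_axis)], sum(x$kept)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels[x$kept])
    cat("  kept per condition:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an epoch set to kept trials (optionally by condition)
#'
#' @param epochs An \code{epoch_set}.
#' @param conditions Optional condition labels to retain.
#' @return An \code{epoch_set} containing only the selected kept trials.
#' @export
kept_epochs <- function(epochs, conditions = NULL) {
  sel <- epochs$kept
  if (!is.null(conditions) && !is.null(epochs$labels))
    sel <- sel & (epochs$labels %in% conditions)
  idx <- which(sel)
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$time_axis,
            epochs$sampling_rate_hz, epochs$channel_labels,
            labels = if (!is.null(epochs$labels)) epochs$labels[idx],
            subject_id = epochs$subject_id,
            kept = rep(TRUE, length(idx)),
            reject_reason = rep("", length(idx)),
            onsets = if (!is.null(epochs$onsets)) epochs$onsets[idx])
}

#' Mark trials of an epoch set as rejected
#'
#' @param epochs An \code{epoch_set}.
#' @param reject Logical vector or integer indices of trials to reject.
#' @param reason Reason string recorded for newly rejected trials.
#' @return The updated \code{epoch_set}.
#' @export
mark_rejected <- function(epochs, reject, reason) {
  if (is.logical(reject)) reject <- which(reject)
  newly <- setdiff(reject, which(!epochs$kept))
  epochs$kept[newly] <- FALSE
  epochs$reject_reason[newly] <- ifelse(nzchar(epochs$reject_reason[newly]),
                                        paste(epochs$reject_reason[newly],
                                              reason, sep = ";"),
                                        reason)
  epochs
}

#' Save / load a recording with the package's own container
#'
#' The internal container is a self-describing serialized R object; a
#' write-read round trip is bit-exact.
#'
#' @param x An \code{eeg_recording} (or any package object).
#' @param path File path.
#' @export
save_recording <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) readRDS(path)
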