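#' Filter specification
#'
#' Describes a Butterworth filter stage. Zero-phase filters are applied
#' forward and backward (the effective magnitude order doubles and the
#' group delay cancels), with odd-symmetric edge padding of three times the
#' filter order.
#'
#' @param kind One of \code{"bandpass"}, \code{"lowpass"}, \code{"highpass"},
#'   \code{"notch"}.
#' @param order Filter order (even integer for the analog prototype).
#' @param band_hz One corner (low/high-pass) or two corners (bandpass /
#'   notch) in Hz.
#' @param zero_phase Apply forward-backward?
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass", "highpass", "notch"),
                        order = 4, band_hz, zero_phase = TRUE) {
  kind <- match.arg(kind)
  n_corner <- if (kind %in% c("bandpass", "notch")) 2L else 1L
  if (length(band_hz) != n_corner)
    stop(kind, " filter needs ", n_corner, " corner frequencies")
  if (any(band_hz <= 0)) stop("corner frequencies must be positive")
  if (n_corner == 2L && band_hz[1] >= band_hz[2])
    stop("corner frequencies must be increasing")
  structure(list(kind = kind, order = as.integer(order),
                 band_hz = band_hz, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

butter_coefficients <- function(spec, fs) {
  ny <- fs / 2
  if (any(spec$band_hz >= ny))
    stop("filter corner at or above the Nyquist frequency (", ny, " Hz)")
  W <- spec$band_hz / ny
  type <- switch(spec$kind, bandpass = "pass", lowpass = "low",
                 highpass = "high", notch = "stop")
  signal::butter(spec$order, W, type = type)
}

# forward (causal) IIR pass over a vector
iir_pass <- function(bf, x) as.numeric(signal::filter(bf, x))

# zero-phase filtering with odd-symmetric padding of 3 x order samples
zero_phase_filter <- function(bf, x, order) {
  pad <- min(3L * order, length(x) - 1L)
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_pad <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- iir_pass(bf, xp)
  y <- rev(iir_pass(bf, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' Apply a filter to a recording
#'
#' Filters every EEG channel (auxiliary channels are untouched). With
#' \code{zero_phase = TRUE} the filter runs forward and backward so the
#' output has no group delay.
#'
#' @param recording An \code{eeg_recording}.
#' @param spec A \code{filter_spec}.
#' @return The filtered \code{eeg_recording}.
#' @export
apply_filter <- function(recording, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!all(is.finite(recording$data))) stop("non-finite values in recording")
  bf <- butter_coefficients(spec, recording$sampling_rate_hz)
  out <- recording
  for (i in seq_len(n_channels(recording))) {
    out$data[i, ] <- if (spec$zero_phase)
      zero_phase_filter(bf, recording$data[i, ], spec$order)
    else iir_pass(bf, recording$data[i, ])
  }
  log_provenance(out, "filter", kind = spec$kind, order = spec$order,
                 band_hz = spec$band_hz, zero_phase = spec$zero_phase)
}

#' Drop channels from a recording
#'
#' Removes the given labels, preserving the order of the remaining
#' channels. With the default exclusion list, the 40-channel montage is
#' reduced to the 33 analysis channels (the fronto-ocular FP1, FP2, AF3,
#' AF4, AF5, F5, F6 are dropped). \code{AF7} is accepted as an alias of
#' \code{AF5}.
#'
#' @param recording An \code{eeg_recording}.
#' @param exclude Channel labels to drop.
#' @param strict Error if an excluded label is absent from the montage?
#' @return The reduced \code{eeg_recording}.
#' @export
select_channels <- function(recording, exclude = default_excluded_channels(),
                            strict = TRUE) {
  have <- canonical_labels(recording$channel_labels)
  want_out <- canonical_labels(exclude)
  missing <- setdiff(want_out, have)
  if (length(missing) && strict)
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  keep <- !(have %in% want_out)
  if (!any(keep)) stop("channel selection would remove every channel")
  out <- recording
  out$data <- recording$data[keep, , drop = FALSE]
  out$channel_labels <- recording$channel_labels[keep]
  log_provenance(out, "select_channels", excluded = exclude)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across all retained EEG channels from
#' every channel; auxiliary channels are untouched. After re-referencing
#' the cross-channel mean is zero at every sample.
#'
#' @param recording An \code{eeg_recording} with at least two channels.
#' @return The re-referenced \code{eeg_recording}.
#' @export
common_average_reference <- function(recording) {
  if (n_channels(recording) < 2L)
    stop("common average reference needs at least two channels")
  out <- recording
  out$data <- sweep(recording$data, 2L, colMeans(recording$data))
  out$reference_label <- "CAR"
  log_provenance(out, "car")
}

#' Downsample by an integer factor
#'
#' Decimates by keeping every factor-th sample (the preceding 40-Hz
#' low-pass and 0.3-3 Hz band-pass act as the anti-alias stages of the
#' standard pipeline). Event sample indices rescale by integer division.
#'
#' @param recording An \code{eeg_recording}.
#' @param target_hz Target rate; the current rate must be an integer
#'   multiple.
#' @param events Optional \code{event_table} to rescale alongside.
#' @return The decimated \code{eeg_recording}, or (when \code{events} is
#'   given) a list with elements \code{recording} and \code{events}.
#' @export
downsample <- function(recording, target_hz, events = NULL) {
  fs <- recording$sampling_rate_hz
  factor <- fs / target_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop("sampling rate ", fs, " is not an integer multiple of ", target_hz)
  factor <- as.integer(round(factor))
  idx <- seq(1L, n_samples(recording), by = factor)
  out <- recording
  out$data <- recording$data[, idx, drop = FALSE]
  out$aux <- lapply(recording$aux, function(a) a[idx])
  out$sampling_rate_hz <- target_hz
  out <- log_provenance(out, "downsample", factor = factor,
                        target_hz = target_hz)
  if (is.null(events)) return(out)
  ev <- events
  ev$sample <- ev$sample %/% factor
  list(recording = out, events = ev)
}
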