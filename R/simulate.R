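#' Simulate one subject's reach-and-grasp recording
#'
#' Generates a continuous multichannel EEG recording (sessions concatenated)
#' with known ground truth: condition-specific MRCP templates inserted
#' time-locked to each trial's true movement onset (Go cue + drawn reaction
#' time), 1/f background and white noise, power-line interference, frontal
#' blink artifacts, occasional high-amplitude bursts, and sample-aligned
#' button and force auxiliary channels. The event table carries trial
#' start, cue, Go, condition markers (codes 1..6) and button releases
#' (grasp trials only). Identical \code{(config, seed)} reproduce the
#' output bit-exactly.
#'
#' @param config A \code{grasp_config}.
#' @param templates An \code{mrcp_template_set} (see [mrcp_templates()]).
#' @param behavior A \code{behavior_model}.
#' @param noise A \code{noise_artifact_model}.
#' @param seed Integer RNG seed.
#' @return An object of class \code{synthetic_subject} with elements
#'   \code{recording} (an \code{eeg_recording} with \code{button} and
#'   \code{force} aux channels), \code{events} (an \code{event_table}) and
#'   \code{ground_truth} (a data.frame, one row per trial).
#' @export
simulate_subject <- function(config,
                             templates = mrcp_templates(config),
                             behavior = behavior_model(),
                             noise = noise_artifact_model(),
                             seed = config$rng_seed) {
  fs <- config$sampling_rate_hz
  if (abs(templates$sampling_rate_hz - fs) > 1e-9)
    stop("template sampling rate does not match the configuration")
  tmpl_idx <- round(templates$time * fs)
  need_lo <- round(-1.5 * fs); need_hi <- round(2.5 * fs)
  if (tmpl_idx[1] > need_lo || tmpl_idx[length(tmpl_idx)] < need_hi)
    stop("template time axis is shorter than the epoch window needs")

  set.seed(seed)
  nc <- length(config$montage)
  trial_len <- round(config$trial_duration_s * fs)
  tps <- config$trials_per_session
  n_sess <- config$n_sessions
  N <- n_sess * tps * trial_len

  data <- matrix(0, nrow = nc, ncol = N)
  button <- numeric(N)
  force <- numeric(N)
  ev_sample <- integer(0); ev_kind <- character(0); ev_code <- integer(0)
  gt <- vector("list", n_sess * tps)

  blink_wf <- blink_waveform(fs)
  blink_w <- blink_profile(config$montage)
  spatial <- templates$spatial
  cue_off <- round(config$cue_time_s * fs)
  go_off <- round(config$go_time_s * fs)

  for (s in seq_len(n_sess)) {
    s0 <- (s - 1L) * tps * trial_len            # 0-based session start
    ns <- tps * trial_len
    X <- synth_background(ns, nc, fs, noise)    # channels x samples

    # power-line interference, common source with per-channel gain
    if (noise$line_amp_uv > 0) {
      tt <- (s0 + seq_len(ns) - 1) / fs
      src <- sin(2 * pi * noise$line_freq_hz * tt + stats::runif(1, 0, 2 * pi))
      gain <- stats::runif(nc, 0.5, 1.5)
      X <- X + noise$line_amp_uv * outer(gain, src)
    }

    # blinks: Poisson times, biphasic waveform through the frontal profile
    if (noise$blink_rate_per_min > 0 && noise$blink_amp_uv > 0) {
      n_bl <- stats::rpois(1, noise$blink_rate_per_min * ns / fs / 60)
      if (n_bl > 0) {
        at <- sort(sample.int(ns - length(blink_wf), n_bl))
        for (b in seq_len(n_bl)) {
          amp <- noise$blink_amp_uv * stats::runif(1, 0.7, 1.3)
          idx <- at[b] + seq_along(blink_wf) - 1L
          X[, idx] <- X[, idx] + amp * outer(blink_w, blink_wf)
        }
      }
    }

    cond_order <- sample(rep(1:6, each = config$trials_per_condition_per_session))

    for (j in seq_len(tps)) {
      t0 <- s0 + (j - 1L) * trial_len           # 0-based trial start
      t0s <- t0 - s0                            # within session, 0-based
      trial_no <- (s - 1L) * tps + j
      code <- cond_order[j]
      is_grasp <- code != 6L

      d <- draw_rt(1, behavior)
      rt <- d$rt
      onset <- t0 + go_off + round(rt * fs)     # true movement onset

      ev_sample <- c(ev_sample, t0, t0 + cue_off, t0 + cue_off, t0 + go_off)
      ev_kind <- c(ev_kind, "trial_start", "condition_marker", "cue", "go")
      ev_code <- c(ev_code, NA_integer_, code, NA_integer_, NA_integer_)

      # MRCP template, time-locked to the true onset
      ins <- onset + tmpl_idx
      ok <- ins >= s0 & ins < s0 + ns
      if (any(ok))
        X[, ins[ok] - s0 + 1L] <- X[, ins[ok] - s0 + 1L] +
          outer(spatial, templates$waveforms[code, ok])

      grasp_start <- NA_real_; duration <- NA_real_
      if (is_grasp) {
        ev_sample <- c(ev_sample, onset)
        ev_kind <- c(ev_kind, "button_release")
        ev_code <- c(ev_code, NA_integer_)

        grasp_start <- rtruncnorm(1, behavior$grasp_start_mean_s,
                                  behavior$grasp_start_sd_s, lower = 0.2)
        duration <- rtruncnorm(1, behavior$duration_mean_s,
                               behavior$duration_sd_s, lower = 0.3)
        # button pressed until hand lift, re-pressed after the hand returns
        rel <- onset - t0                        # within trial
        back <- min(round(rel + (grasp_start + duration + 0.8) * fs), trial_len)
        bt <- rep(1, trial_len)
        if (rel < trial_len) bt[(rel + 1):back] <- 0
        button[(t0 + 1):(t0 + trial_len)] <- bt
        # trapezoidal force trace between grasp start and release
        f0 <- onset - t0 + round(grasp_start * fs)
        f1 <- f0 + round(duration * fs)
        rise <- round(behavior$force_rise_s * fs)
        ft <- numeric(trial_len)
        ramp_idx <- function(a, b) pmax(1L, pmin(trial_len, a:b))
        if (f0 + rise <= trial_len) {
          up <- seq(0, 1, length.out = rise + 1)
          ft[ramp_idx(f0, f0 + rise)] <- up
          ft[ramp_idx(f0 + rise, min(f1, trial_len))] <- 1
          if (f1 + rise <= trial_len)
            ft[ramp_idx(f1, f1 + rise)] <- rev(up)
        }
        force[(t0 + 1):(t0 + trial_len)] <- ft
      } else {
        button[(t0 + 1):(t0 + trial_len)] <- 1
      }

      # occasional high-amplitude burst inside the peri-onset window
      burst <- stats::runif(1) < noise$burst_prob
      burst_ch <- NA_character_
      if (burst) {
        ch <- sample.int(nc, 1)
        burst_ch <- config$montage[ch]
        bc <- onset + round(stats::runif(1, -1, 1.8) * fs)
        bi <- bc + seq(-round(0.1 * fs), round(0.1 * fs))
        bi <- bi[bi >= s0 & bi < s0 + ns]
        env <- exp(-((bi - bc) / (0.04 * fs))^2 / 2)
        X[ch, bi - s0 + 1L] <- X[ch, bi - s0 + 1L] +
          noise$burst_amp_uv * stats::runif(1, 0.9, 1.3) *
          env * sign(stats::runif(1) - 0.5)
      }

      gt[[trial_no]] <- data.frame(
        trial_id = trial_no, session = s,
        condition = config$condition_codes[code], condition_code = code,
        true_onset_sample = onset, rt_s = rt, slow_trial = d$slow,
        grasp_start_s = grasp_start, duration_s = duration,
        injected_artifact = burst, artifact_channel = burst_ch,
        stringsAsFactors = FALSE)
    }
    data[, (s0 + 1):(s0 + ns)] <- X
  }

  rec <- eeg_recording(data, config$montage, fs,
                       aux = list(button = button, force = force))
  ev <- event_table(ev_sample, ev_kind, ev_code)
  structure(list(recording = rec, events = ev,
                 ground_truth = do.call(rbind, gt),
                 config = config, seed = seed),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject (seed %d): %d trials in %d sessions\n",
              x$seed, nrow(x$ground_truth), x$config$n_sessions))
  print(x$recording)
  invisible(x)
}

# 1/f^a background: sum of ~80 randomly-phased sinusoids with amplitude
# proportional to f^-a, plus white noise; computed in time chunks via one
# matrix product per chunk so memory stays bounded.
synth_background <- function(ns, nc, fs, noise, n_freq = 80L,
                             chunk = 100000L) {
  X <- matrix(0, nrow = nc, ncol = ns)
  if (noise$background_rms_uv > 0) {
    f_hi <- min(45, 0.45 * fs)
    f <- exp(stats::runif(n_freq, log(0.1), log(f_hi)))
    a <- f^(-noise$spectral_exponent)
    a <- a * noise$background_rms_uv / sqrt(sum(a^2))
    Cs <- matrix(stats::rnorm(n_freq * nc), n_freq, nc) * a
    Cc <- matrix(stats::rnorm(n_freq * nc), n_freq, nc) * a
    w <- 2 * pi * f
    done <- 0L
    while (done < ns) {
      m <- min(chunk, ns - done)
      tt <- (done + seq_len(m) - 1) / fs
      arg <- outer(tt, w)
      X[, (done + 1):(done + m)] <- t(sin(arg) %*% Cs + cos(arg) %*% Cc)
      done <- done + m
    }
  }
  if (noise$white_rms_uv > 0)
    X <- X + matrix(stats::rnorm(nc * ns, sd = noise$white_rms_uv), nc, ns)
  X
}

#' Write the generator's ground-truth table as CSV
#'
#' @param subject A \code{synthetic_subject}.
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(subject, path) {
  utils::write.csv(subject$ground_truth, path, row.names = FALSE)
  invisible(path)
}
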