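#' Condition-specific MRCP waveform templates
#'
#' Builds the per-condition movement-related cortical potential templates
#' used by the synthetic generator, on a time axis covering [-1.5, 3.0] s
#' relative to the movement onset. The parametric form is a piecewise
#' linear Bereitschaftspotential ramp plus Gaussian rebound bumps:
#' \itemize{
#'   \item all five grasp conditions share a monotone negative ramp starting
#'     0.5 s before onset and peaking (most negative) exactly at onset;
#'   \item the no-movement condition shows the same pre-onset trend at
#'     reduced amplitude and stays flat (no rebound) afterwards;
#'   \item push and plug carry a large positive rebound near 1.2 s and are
#'     generated with identical post-onset shape (they are intentionally
#'     confusable); the other grasps have a weak rebound in [0.2, 0.5] s.
#' }
#' Condition differences are confined to the post-onset interval, so class
#' information in the synthetic data only exists after the movement starts.
#'
#' \code{effect_scale} multiplies every template: \code{0} silences them
#' entirely (the null generator — no class information and no MRCP at
#' all), \code{1} gives the full morphology.
#'
#' @param config A \code{grasp_config}.
#' @param effect_scale Non-negative scaling of between-condition differences.
#' @param ramp_amp_uv Pre-onset ramp depth of grasp conditions (microvolts).
#' @param rest_frac Fraction of \code{ramp_amp_uv} reached by the
#'   no-movement template.
#' @return An object of class \code{mrcp_template_set} with elements
#'   \code{time} (seconds), \code{waveforms} (6 x time matrix, microvolts),
#'   \code{spatial} (named channel weight vector, maximal near Cz/C1) and
#'   \code{effect_scale}.
#' @export
mrcp_templates <- function(config, effect_scale = 1, ramp_amp_uv = 8,
                           rest_frac = 0.4) {
  if (effect_scale < 0) stop("effect_scale must be non-negative")
  fs <- config$sampling_rate_hz
  t <- seq(round(-1.5 * fs), round(3.0 * fs)) / fs
  conds <- config$condition_codes

  ramp <- function(depth) {
    w <- numeric(length(t))
    pre <- t >= -0.5 & t <= 0
    w[pre] <- -depth * (t[pre] + 0.5) / 0.5
    w
  }
  recover <- function(depth, tau) {
    w <- numeric(length(t))
    post <- t > 0
    w[post] <- -depth * exp(-t[post] / tau)
    w
  }
  bump <- function(amp, center, width) amp * exp(-(t - center)^2 / (2 * width^2))
  post_only <- function(w) { w[t <= 0] <- 0; w }

  # per-condition post-onset recovery time constants and rebound bumps;
  # recovery is fast enough that the rebound rises above baseline inside
  # its stated latency window
  pars <- list(
    palmar = list(tau = 0.15, amp = 1.5, c = 0.30, w = 0.07),
    pinch  = list(tau = 0.10, amp = 3.5, c = 0.35, w = 0.09),
    push   = list(tau = 0.18, amp = 6.0, c = 1.20, w = 0.25),
    twist  = list(tau = 0.22, amp = 4.5, c = 0.45, w = 0.12),
    plug   = list(tau = 0.18, amp = 6.0, c = 1.20, w = 0.25))

  W <- matrix(0, nrow = 6, ncol = length(t), dimnames = list(conds, NULL))
  for (i in 1:5) {
    p <- pars[[i]]
    W[i, ] <- ramp(ramp_amp_uv) + recover(ramp_amp_uv, p$tau) +
      post_only(bump(p$amp, p$c, p$w))
  }
  # no-movement: same pre-onset trend, reduced depth, slow featureless return
  W[6, ] <- ramp(rest_frac * ramp_amp_uv) +
    recover(rest_frac * ramp_amp_uv, 0.8)

  W <- effect_scale * W

  co <- montage_coordinates(config$montage)
  spatial <- exp(-((co$x + 0.09)^2 + (co$y - 0.05)^2) / (2 * 0.33^2))
  names(spatial) <- config$montage

  structure(list(time = t, waveforms = W, spatial = spatial,
                 effect_scale = effect_scale,
                 sampling_rate_hz = fs),
            class = "mrcp_template_set")
}

#' @export
print.mrcp_template_set <- function(x, ...) {
  cat(sprintf("MRCP template set: 6 conditions x %d samples @ %.5g Hz, effect scale %.3g\n",
              ncol(x$waveforms), x$sampling_rate_hz, x$effect_scale))
  cat(sprintf("  time [%.2f, %.2f] s; spatial max at %s\n",
              x$time[1], x$time[length(x$time)],
              names(x$spatial)[which.max(x$spatial)]))
  invisible(x)
}

#' Behavioral timing model for the synthetic generator
#'
#' Reaction times are truncated-normal (> 0.05 s); with probability
#' \code{slow_trial_prob} a trial is drawn from a slow component whose mass
#' lies mostly above the 2-s rejection threshold. Grasp start follows the
#' observed 0.98-1.18 s window after movement onset; per-condition grasp
#' durations share one distribution, so duration carries no condition
#' information by construction.
#'
#' @param rt_mean_s,rt_sd_s Mean / SD of the regular reaction time (s).
#' @param slow_trial_prob Probability of a slow trial (exercises RT > 2 s
#'   rejection).
#' @param slow_rt_mean_s,slow_rt_sd_s Slow-component mean / SD (s).
#' @param grasp_start_mean_s,grasp_start_sd_s Grasp start offset after
#'   movement onset (s); the mean must lie in [0.98, 1.18].
#' @param duration_mean_s,duration_sd_s Grasp duration (s).
#' @param force_rise_s Rise/fall time of the trapezoidal force profile (s).
#' @return An object of class \code{behavior_model}.
#' @export
behavior_model <- function(rt_mean_s = 0.5, rt_sd_s = 0.15,
                           slow_trial_prob = 0.05,
                           slow_rt_mean_s = 2.6, slow_rt_sd_s = 0.4,
                           grasp_start_mean_s = 1.08,
                           grasp_start_sd_s = 0.10,
                           duration_mean_s = 1.5, duration_sd_s = 0.30,
                           force_rise_s = 0.15) {
  if (grasp_start_mean_s < 0.98 || grasp_start_mean_s > 1.18)
    stop("grasp_start_mean_s must lie in [0.98, 1.18]")
  if (duration_mean_s <= 0) stop("durations must be positive")
  structure(list(rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
                 slow_trial_prob = slow_trial_prob,
                 slow_rt_mean_s = slow_rt_mean_s, slow_rt_sd_s = slow_rt_sd_s,
                 grasp_start_mean_s = grasp_start_mean_s,
                 grasp_start_sd_s = grasp_start_sd_s,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s,
                 force_rise_s = force_rise_s),
            class = "behavior_model")
}

# truncated-normal draw (> lower), by rejection; vectorized
rtruncnorm <- function(n, mean, sd, lower = 0.05) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

draw_rt <- function(n, bm) {
  slow <- stats::runif(n) < bm$slow_trial_prob
  rt <- rtruncnorm(n, bm$rt_mean_s, bm$rt_sd_s)
  if (any(slow))
    rt[slow] <- rtruncnorm(sum(slow), bm$slow_rt_mean_s, bm$slow_rt_sd_s)
  list(rt = rt, slow = slow)
}

#' Background noise and artifact model for the synthetic generator
#'
#' Background activity is a sum of randomly-phased sinusoids with 1/f^a
#' amplitude scaling plus white noise; ocular artifacts are stereotyped
#' biphasic blinks projected through a fixed frontal spatial profile with
#' Poisson event times; occasional high-amplitude bursts exercise the
#' +-200 microvolt rejection rule; line noise exercises the notch filter.
#'
#' @param background_rms_uv RMS of the 1/f background (microvolts).
#' @param spectral_exponent Amplitude exponent a in 1/f^a.
#' @param white_rms_uv RMS of the additive white noise (microvolts).
#' @param line_freq_hz,line_amp_uv Power-line frequency and amplitude.
#' @param blink_rate_per_min,blink_amp_uv Blink Poisson rate and amplitude.
#' @param burst_prob Per-trial probability of an injected high-amplitude
#'   burst.
#' @param burst_amp_uv Burst amplitude (microvolts, well above 200).
#' @return An object of class \code{noise_artifact_model}.
#' @export
noise_artifact_model <- function(background_rms_uv = 10,
                                 spectral_exponent = 1,
                                 white_rms_uv = 3,
                                 line_freq_hz = 50, line_amp_uv = 1.5,
                                 blink_rate_per_min = 2, blink_amp_uv = 90,
                                 burst_prob = 0.04, burst_amp_uv = 350) {
  amps <- c(background_rms_uv, white_rms_uv, line_amp_uv, blink_amp_uv,
            burst_amp_uv)
  if (any(amps < 0)) stop("all amplitudes must be non-negative")
  if (blink_rate_per_min < 0) stop("blink rate must be non-negative")
  structure(list(background_rms_uv = background_rms_uv,
                 spectral_exponent = spectral_exponent,
                 white_rms_uv = white_rms_uv,
                 line_freq_hz = line_freq_hz, line_amp_uv = line_amp_uv,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp_uv = blink_amp_uv,
                 burst_prob = burst_prob, burst_amp_uv = burst_amp_uv),
            class = "noise_artifact_model")
}

# frontal blink projection weights for a set of labels: strongest on the
# FP/AF rows, decaying towards posterior sites
blink_profile <- function(labels) {
  co <- montage_coordinates(labels)
  w <- exp(-(0.9 - co$y) * 5)
  names(w) <- labels
  w
}

# biphasic blink waveform (unit peak), duration ~0.45 s
blink_waveform <- function(fs) {
  tt <- seq(0, 0.45, by = 1 / fs)
  w <- exp(-(tt - 0.15)^2 / (2 * 0.04^2)) -
    0.35 * exp(-(tt - 0.28)^2 / (2 * 0.06^2))
  w / max(abs(w))
}
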