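#' Experiment design configuration
#'
#' Describes the reach-and-grasp recording paradigm: per-session trial
#' structure, within-trial cue timing, sampling rate, montage and condition
#' coding. The default is the reference design of eight 60-trial
#' sessions (10 trials per condition, randomized order), 10-s trials with
#' the auditory target cue at 3 s and the "Go" cue at 5 s, 40 channels at
#' 1,000 Hz — 480 trials per subject, 80 per condition.
#'
#' @param n_sessions Number of recording sessions.
#' @param trials_per_condition_per_session Trials of each condition in one
#'   session; a session holds six times this number of trials.
#' @param trial_duration_s Trial length in seconds.
#' @param cue_time_s Auditory target cue time within the trial (s).
#' @param go_time_s "Go" cue time within the trial (s).
#' @param sampling_rate_hz EEG/aux sampling rate (Hz).
#' @param montage Ordered channel labels (10-20 names).
#' @param condition_codes Ordered names of the six conditions; codes 1..6
#'   follow this order and code 6 is the no-movement condition.
#' @param rng_seed Default seed used when none is given to the simulator.
#' @return An object of class \code{grasp_config}.
#' @export
grasp_config <- function(n_sessions = 8,
                         trials_per_condition_per_session = 10,
                         trial_duration_s = 10,
                         cue_time_s = 3,
                         go_time_s = 5,
                         sampling_rate_hz = 1000,
                         montage = default_montage(),
                         condition_codes = c("palmar", "pinch", "push",
                                             "twist", "plug", "no_movement"),
                         rng_seed = 1L) {
  stopifnot(length(condition_codes) == 6L)
  cfg <- structure(list(
    n_sessions = as.integer(n_sessions),
    trials_per_condition_per_session = as.integer(trials_per_condition_per_session),
    trials_per_session = 6L * as.integer(trials_per_condition_per_session),
    trial_duration_s = trial_duration_s,
    cue_time_s = cue_time_s,
    go_time_s = go_time_s,
    sampling_rate_hz = sampling_rate_hz,
    montage = as.character(montage),
    condition_codes = as.character(condition_codes),
    rng_seed = as.integer(rng_seed)
  ), class = "grasp_config")
  validate_grasp_config(cfg)
  cfg
}

validate_grasp_config <- function(cfg) {
  with(cfg, {
    if (n_sessions < 1L || trials_per_condition_per_session < 1L)
      stop("session and trial counts must be positive")
    if (trials_per_session != 6L * trials_per_condition_per_session)
      stop("trials_per_session must equal 6 x trials_per_condition_per_session")
    if (!(go_time_s > cue_time_s && cue_time_s > 0))
      stop("need go_time_s > cue_time_s > 0")
    if (trial_duration_s <= go_time_s)
      stop("trial_duration_s must exceed go_time_s")
    if (sampling_rate_hz <= 0) stop("sampling rate must be positive")
    if (anyDuplicated(montage)) stop("duplicate channel labels in montage")
  })
  invisible(cfg)
}

#' @export
print.grasp_config <- function(x, ...) {
  total <- x$n_sessions * x$trials_per_session
  cat("Reach-and-grasp experiment configuration\n")
  cat(sprintf("  %d sessions x %d trials (%d per condition) = %d trials, %d per condition\n",
              x$n_sessions, x$trials_per_session,
              x$trials_per_condition_per_session, total,
              total / 6L))
  cat(sprintf("  trial %.4g s, cue %.4g s, go %.4g s; %d channels @ %.5g Hz\n",
              x$trial_duration_s, x$cue_time_s, x$go_time_s,
              length(x$montage), x$sampling_rate_hz))
  cat("  conditions:", paste(sprintf("%d=%s", 1:6, x$condition_codes),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Total trial counts implied by a configuration
#'
#' @param cfg A \code{grasp_config}.
#' @return Named list with \code{total} trials per subject and
#'   \code{per_condition}.
#' @export
design_totals <- function(cfg) {
  total <- cfg$n_sessions * cfg$trials_per_session
  list(total = total, per_condition = total %/% 6L)
}
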