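# Shared fixtures. Simulations are desk-scale: 200 Hz (integer-factor
# decimation to the 100-Hz analysis rate preserved), 1-2 sessions.
# Expensive objects are cached across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

desk_config <- function(n_sessions = 2, fs = 200, tpc = 10)
  grasp_config(n_sessions = n_sessions, sampling_rate_hz = fs,
               trials_per_condition_per_session = tpc)

# one preprocessed default-effect subject (2 sessions, no ICA), shared
desk_subject <- function() {
  cache_get("desk_subject", function() {
    cfg <- desk_config()
    sim <- simulate_subject(cfg, mrcp_templates(cfg), seed = 42)
    pp <- preprocess_subject(sim, preprocess_options(ica = FALSE))
    list(cfg = cfg, sim = sim, pp = pp)
  })
}

# a 4-session subject for decoding-power checks, shared
deep_subject <- function() {
  cache_get("deep_subject", function() {
    cfg <- desk_config(n_sessions = 4)
    sim <- simulate_subject(cfg, mrcp_templates(cfg), seed = 5)
    pp <- preprocess_subject(sim, preprocess_options(ica = FALSE))
    list(cfg = cfg, sim = sim, pp = pp)
  })
}

# epochs built directly from a template + iid noise (no pipeline), for
# statistics whose expected values need a known signal model
make_epochs <- function(n_trials, template, sigma, fs = 100,
                        labels = NULL, n_channels = 1, seed = 1,
                        channel_labels = NULL,
                        window = c(-1.5, 2.5)) {
  set.seed(seed)
  ns <- round((window[2] - window[1]) * fs)
  if (is.null(channel_labels))
    channel_labels <- if (n_channels == 1) "Cz"
                      else paste0("C", seq_len(n_channels))
  dat <- array(stats::rnorm(n_trials * n_channels * ns, sd = sigma),
               dim = c(n_trials, n_channels, ns))
  if (!is.null(template))
    for (i in seq_len(n_trials)) for (c in seq_len(n_channels))
      dat[i, c, ] <- dat[i, c, ] + template
  epoch_set(dat, time_axis = (round(window[1] * fs):(round(window[2] * fs) - 1)) / fs,
            sampling_rate_hz = fs, channel_labels = channel_labels,
            labels = labels)
}

# toy recording with a known constant or supplied matrix
make_recording <- function(data, fs = 100, labels = NULL) {
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(data)))
  eeg_recording(data, labels, fs)
}
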