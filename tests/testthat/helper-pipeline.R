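# one cached tiny end-to-end pipeline run shared by the pipeline and
# acceptance tests (2 subjects, 1 session, ICA on, 1 CV repetition)
tiny_pipeline <- function() {
  cache_get("tiny_pipeline", function() {
    out <- file.path(tempdir(), "mrcpgrasp_tiny_run")
    unlink(out, recursive = TRUE)
    cfg <- desk_config(n_sessions = 1)
    manifest <- suppressMessages(
      run_pipeline(out, config = cfg, n_subjects = 2, seed = 31,
                   repetitions = 1))
    list(out = out, cfg = cfg, manifest = manifest)
  })
}
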