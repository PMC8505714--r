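#' Preprocessing options
#'
#' Bundles the signal-conditioning and rejection parameters of the
#' standard pipeline. The stage order is fixed and logged: RT screening,
#' channel selection, 40-Hz low-pass, amplitude and statistical trial
#' rejection, ICA ocular cleanup, common average reference, 0.3-3 Hz
#' zero-phase band-pass, downsampling to 100 Hz, epoching [-1.5, 2.5] s
#' around the virtual movement onset. The acquisition-side 0.05-100 Hz
#' band-pass and 50-Hz notch describe the amplifier and are off by
#' default.
#'
#' @param exclude_channels Labels dropped before analysis (default: the
#'   seven fronto-ocular channels).
#' @param lowpass_hz Early low-pass corner (Hz).
#' @param amplitude_limit_uv Trial rejection threshold (microvolts).
#' @param z_limit Statistical rejection threshold (SD units).
#' @param stat_aggregate \code{"global"} or \code{"channel"} (see
#'   [reject_statistical_outliers()]).
#' @param ica Run ICA-based ocular removal?
#' @param bandpass_hz Low-frequency analysis band (Hz).
#' @param target_hz Analysis sampling rate after downsampling.
#' @param epoch_window_s Epoch window around the virtual onset (s).
#' @param rt_threshold_s RT screening threshold (s).
#' @param notch Apply a 50-Hz notch before the low-pass (amplifier
#'   emulation, off by default)?
#' @return A list of class \code{preprocess_options}.
#' @export
preprocess_options <- function(exclude_channels = default_excluded_channels(),
                               lowpass_hz = 40,
                               amplitude_limit_uv = 200,
                               z_limit = 3,
                               stat_aggregate = "global",
                               ica = TRUE,
                               bandpass_hz = c(0.3, 3),
                               target_hz = 100,
                               epoch_window_s = c(-1.5, 2.5),
                               rt_threshold_s = 2,
                               notch = FALSE) {
  structure(as.list(environment()), class = "preprocess_options")
}

#' Preprocess one subject end-to-end
#'
#' Runs the full conditioning chain on a (synthetic or recorded) subject
#' and returns analysis-ready epochs at the target rate with rejected
#' trials marked, alongside the rejection report, reaction-time table and
#' ICA decomposition.
#'
#' @param sim A \code{synthetic_subject}, or a list with elements
#'   \code{recording}, \code{events} (and optionally \code{ground_truth}).
#' @param options A \code{preprocess_options} list.
#' @param subject_id Identifier stored in the epoch set.
#' @param conditions Condition names for codes 1..6 (default: from the
#'   simulation config or generic labels).
#' @return List with \code{epochs} (\code{epoch_set}), \code{report}
#'   (\code{rejection_report}), \code{rt_table}, \code{mean_rt_s},
#'   \code{ica} (decomposition or NULL), \code{stages} (ordered stage
#'   log).
#' @export
preprocess_subject <- function(sim, options = preprocess_options(),
                               subject_id = "S1", conditions = NULL) {
  rec <- sim$recording
  fs <- rec$sampling_rate_hz
  if (is.null(conditions))
    conditions <- if (!is.null(sim$config)) sim$config$condition_codes
                  else as.character(1:6)
  stages <- character(0)

  # movement timing and RT screening
  rt_table <- compute_rt(sim$events, fs)
  vo <- compute_virtual_onsets(rt_table, fs, options$rt_threshold_s)
  rep_rt <- reject_high_rt(rt_table$rt_s, options$rt_threshold_s,
                           trial_id = rt_table$trial)
  rep_flag <- rejection_report(rt_table$trial,
                               lapply(rt_table$flagged, function(f)
                                 if (f) "channel_noise" else character(0)))
  stages <- c(stages, "rt_screening")

  # EOG reference from the pre-selection frontal channels
  fp <- which(canonical_labels(rec$channel_labels) %in% c("FP1", "FP2"))
  eog_ref <- if (length(fp)) colMeans(rec$data[fp, , drop = FALSE])

  rec <- select_channels(rec, options$exclude_channels, strict = FALSE)
  stages <- c(stages, "channel_selection")
  if (isTRUE(options$notch))
    rec <- apply_filter(rec, filter_spec("notch", 4, c(48, 52)))
  rec <- apply_filter(rec, filter_spec("lowpass", 4, options$lowpass_hz))
  stages <- c(stages, "lowpass_40hz")

  # rejection statistics on raw-rate epochs
  ep_raw <- epoch_recording(rec, vo$onsets, options$epoch_window_s,
                            labels = conditions[rt_table$code],
                            subject_id = subject_id)
  rep_edge <- rejection_report(rt_table$trial,
                               lapply(seq_len(nrow(rt_table)), function(i)
                                 if (!ep_raw$kept[i]) "edge" else character(0)))
  rep_amp <- reject_by_amplitude(ep_raw, options$amplitude_limit_uv)
  rep_stat <- reject_statistical_outliers(ep_raw, options$z_limit,
                                          aggregate = options$stat_aggregate)
  report <- merge_reports(rep_rt, rep_flag, rep_edge, rep_amp, rep_stat)
  stages <- c(stages, "amplitude_rejection", "statistical_rejection")

  ica_dec <- NULL
  if (isTRUE(options$ica)) {
    cleaned <- remove_ocular_components(rec, eog_reference = eog_ref)
    rec <- cleaned$recording
    ica_dec <- cleaned$decomposition
    stages <- c(stages, "ica_eog_removal")
  }
  rec <- common_average_reference(rec)
  stages <- c(stages, "car")
  rec <- apply_filter(rec, filter_spec("bandpass", 4, options$bandpass_hz))
  stages <- c(stages, "bandpass_0.3_3hz")
  factor <- as.integer(round(fs / options$target_hz))
  rec <- downsample(rec, options$target_hz)
  stages <- c(stages, "downsample")

  epochs <- epoch_recording(rec, vo$onsets %/% factor,
                            options$epoch_window_s,
                            labels = conditions[rt_table$code],
                            subject_id = subject_id)
  epochs <- mark_rejected(epochs, !report$kept, "preprocessing")
  stages <- c(stages, "epoch")

  list(epochs = epochs, report = report, rt_table = rt_table,
       mean_rt_s = vo$mean_rt_s, onsets = vo$onsets, ica = ica_dec,
       stages = stages)
}

#' Run the full analysis pipeline on simulated subjects
#'
#' Simulates \code{n_subjects} subjects, preprocesses each one, computes
#' behavioral statistics, grand-average MRCPs with sample-wise tests,
#' sliding-window decoding for all binary contrasts and the five-class
#' problem, and writes every artifact (CSV/JSON) plus a run manifest with
#' file digests into \code{output_dir}. Re-running with the same
#' configuration and seed reproduces every artifact bit-exactly.
#'
#' @param output_dir Output directory (created if needed).
#' @param config A \code{grasp_config}.
#' @param n_subjects Number of simulated subjects.
#' @param seed Base seed; subject s uses seed + 7919 * (s - 1).
#' @param effect_scale Template effect scale passed to the generator.
#' @param behavior,noise Generator component models.
#' @param options A \code{preprocess_options} list.
#' @param scheme A \code{window_scheme}.
#' @param folds,repetitions Cross-validation settings.
#' @return The run manifest (list), invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(output_dir,
                         config = grasp_config(),
                         n_subjects = 9L,
                         seed = 1L,
                         effect_scale = 1,
                         behavior = behavior_model(),
                         noise = noise_artifact_model(),
                         options = preprocess_options(),
                         scheme = window_scheme(),
                         folds = 5L, repetitions = 10L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  templates <- mrcp_templates(config, effect_scale = effect_scale)
  grasp <- config$condition_codes[1:5]
  nomove <- config$condition_codes[6]
  subjects <- paste0("S", seq_len(n_subjects))
  all_curves <- list(); all_epochs <- list(); stage_counts <- list()
  mean_summ <- list()
  stages <- NULL

  for (s in seq_len(n_subjects)) {
    sid <- subjects[s]
    sseed <- seed + 7919L * (s - 1L)
    sim <- withCallingHandlers(
      simulate_subject(config, templates, behavior, noise, seed = sseed),
      error = function(e) stop("stage 'simulate' failed for ", sid, ": ",
                               conditionMessage(e)))
    write_ground_truth(sim, file.path(output_dir,
                                      paste0("ground_truth_", sid, ".csv")))
    pp <- tryCatch(preprocess_subject(sim, options, subject_id = sid),
                   error = function(e) stop("stage 'preprocess' failed for ",
                                            sid, ": ", conditionMessage(e)))
    stages <- pp$stages
    utils::write.csv(as.data.frame(pp$report),
                     file.path(output_dir, paste0("rejection_", sid, ".csv")),
                     row.names = FALSE)
    bs <- behavioral_summary(sim, options$rt_threshold_s,
                             conditions = config$condition_codes)
    utils::write.csv(bs$trials,
                     file.path(output_dir, paste0("behavior_", sid, ".csv")),
                     row.names = FALSE)
    mean_summ[[sid]] <- bs
    all_epochs[[sid]] <- pp$epochs
    stage_counts[[sid]] <- list(simulated = nrow(sim$ground_truth),
                                kept = sum(pp$epochs$kept),
                                rejected = sum(!pp$epochs$kept))

    curves <- tryCatch({
      cl <- list()
      for (g in grasp)
        cl[[paste0(g, "_vs_", nomove)]] <-
          cross_validated_curve(pp$epochs, c(g, nomove), scheme, folds,
                                repetitions, seed = sseed)
      prs <- utils::combn(grasp, 2, simplify = FALSE)
      for (pr in prs)
        cl[[paste0(pr[1], "_vs_", pr[2])]] <-
          cross_validated_curve(pp$epochs, pr, scheme, folds,
                                repetitions, seed = sseed)
      cl[["multiclass"]] <-
        cross_validated_curve(pp$epochs, grasp, scheme, folds,
                              repetitions, seed = sseed)
      cl
    }, error = function(e) stop("stage 'decode' failed for ", sid, ": ",
                                conditionMessage(e)))
    all_curves[[sid]] <- curves
    cdf <- do.call(rbind, lapply(names(curves), function(nm)
      data.frame(subject = sid, contrast = nm,
                 window_time_s = curves[[nm]]$window_time_s,
                 accuracy = curves[[nm]]$accuracy, sd = curves[[nm]]$sd,
                 n_trials = attr(curves[[nm]], "n_trials"))))
    utils::write.csv(cdf, file.path(output_dir,
                                    paste0("curves_", sid, ".csv")),
                     row.names = FALSE)
    message(sprintf("[%s] %d/%d trials kept (%.1f%% rejected); multiclass peak %.1f%%",
                    sid, stage_counts[[sid]]$kept,
                    stage_counts[[sid]]$simulated,
                    100 * stage_counts[[sid]]$rejected /
                      stage_counts[[sid]]$simulated,
                    100 * peak_performance(curves[["multiclass"]])$accuracy))
  }

  # grand-average MRCPs, CIs, sample-wise contrasts at Cz
  ga <- grand_average(all_epochs)
  ga_df <- do.call(rbind, lapply(dimnames(ga$mean)[[1]], function(cond)
    do.call(rbind, lapply(seq_along(ga$channel_labels), function(ci)
      data.frame(condition = cond, channel = ga$channel_labels[ci],
                 time_s = ga$time_axis, mean_uv = ga$mean[cond, ci, ],
                 lower_uv = ga$lower[cond, ci, ],
                 upper_uv = ga$upper[cond, ci, ])))))
  utils::write.csv(ga_df, file.path(output_dir, "grand_average.csv"),
                   row.names = FALSE)
  pool_cz <- function(cond) {
    do.call(rbind, lapply(all_epochs, function(e) {
      ci <- match("Cz", e$channel_labels)
      e$data[e$kept & e$labels == cond, ci, , drop = TRUE]
    }))
  }
  sig <- do.call(rbind, lapply(grasp, function(g) {
    tr <- samplewise_ranksum(pool_cz(g), pool_cz(nomove))
    data.frame(contrast = paste0(g, "_vs_", nomove), channel = "Cz",
               time_s = all_epochs[[1]]$time_axis, p = tr$p,
               significant = tr$significant)
  }))
  utils::write.csv(sig, file.path(output_dir, "significance_cz.csv"),
                   row.names = FALSE)

  # behavioral duration ANOVA across subjects
  dur <- t(sapply(mean_summ, function(b) b$condition_durations[grasp]))
  anova_res <- if (n_subjects >= 3) duration_anova(dur)
  if (!is.null(anova_res))
    jsonlite::write_json(unclass(anova_res),
                         file.path(output_dir, "duration_anova.json"),
                         auto_unbox = TRUE, digits = NA)

  tables <- report_tables(output_dir)

  n5 <- sapply(all_epochs, function(e) sum(e$kept & e$labels %in% grasp))
  bounds <- data.frame(subject = subjects, n_trials = as.integer(n5),
                       n_classes = 5L,
                       chance_bound = sapply(n5, function(n)
                         chance_upper_bound(n, 5)$bound))
  utils::write.csv(bounds, file.path(output_dir, "chance_bounds.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrcpgrasp")),
    seed = seed,
    subject_seeds = seed + 7919L * (seq_len(n_subjects) - 1L),
    config = unclass(config),
    effect_scale = effect_scale,
    cv = list(folds = folds, repetitions = repetitions,
              windows = length(scheme$window_ends_s)),
    stages = c(stages, "decode"),
    trial_counts = stage_counts)
  files <- setdiff(list.files(output_dir), "manifest.json")
  dig <- tools::md5sum(file.path(output_dir, files))
  manifest$files <- as.list(setNames(as.character(dig), files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build the peak-performance report tables
#'
#' Reads the per-subject accuracy-curve CSVs from a pipeline output
#' directory and writes three analogue tables: subject-specific
#' grasp-vs-no-movement peaks, grand-average pairwise grasp peaks (10
#' combinations plus a mean row), and subject-specific multiclass peaks
#' (one column per subject plus the mean).
#'
#' @param output_dir Directory containing \code{curves_S*.csv}.
#' @return List with data.frames \code{table1}, \code{table2},
#'   \code{table3}; also written as CSVs.
#' @export
report_tables <- function(output_dir) {
  files <- list.files(output_dir, pattern = "^curves_S[0-9]+\\.csv$",
                      full.names = TRUE)
  if (!length(files))
    stop("missing decoding input: no curves_S*.csv in ", output_dir)
  cur <- do.call(rbind, lapply(files, utils::read.csv,
                               stringsAsFactors = FALSE))
  subjects <- unique(cur$subject)
  subjects <- subjects[order(as.integer(sub("^S", "", subjects)))]
  contrasts <- unique(cur$contrast)
  vs_nomove <- grep("_vs_no_movement$", contrasts, value = TRUE)
  pairwise <- setdiff(setdiff(contrasts, vs_nomove), "multiclass")
  if (!"multiclass" %in% contrasts)
    stop("missing decoding input: contrast 'multiclass' not found")

  peak_of <- function(df) {
    i <- which(df$accuracy == max(df$accuracy))[1]
    c(acc = df$accuracy[i], time = df$window_time_s[i])
  }

  t1 <- do.call(rbind, lapply(subjects, function(s)
    do.call(rbind, lapply(vs_nomove, function(ct) {
      pk <- peak_of(cur[cur$subject == s & cur$contrast == ct, ])
      data.frame(subject = s, contrast = ct,
                 peak_accuracy_pct = 100 * pk[["acc"]],
                 time_s = pk[["time"]])
    }))))

  t2 <- do.call(rbind, lapply(pairwise, function(ct) {
    sub <- cur[cur$contrast == ct, ]
    A <- sapply(subjects, function(s)
      sub$accuracy[sub$subject == s][order(sub$window_time_s[sub$subject == s])])
    tt <- sort(unique(sub$window_time_s))
    gm <- rowMeans(as.matrix(A))
    i <- which(gm == max(gm))[1]
    sd_i <- stats::sd(as.matrix(A)[i, ])
    data.frame(combination = ct, peak_accuracy_pct = 100 * gm[i],
               sd_pct = 100 * ifelse(is.na(sd_i), 0, sd_i),
               time_s = tt[i])
  }))
  t2 <- rbind(t2, data.frame(combination = "Mean",
                             peak_accuracy_pct = mean(t2$peak_accuracy_pct),
                             sd_pct = mean(t2$sd_pct),
                             time_s = mean(t2$time_s)))

  pk3 <- sapply(subjects, function(s)
    peak_of(cur[cur$subject == s & cur$contrast == "multiclass", ]))
  t3 <- data.frame(measure = c("peak_accuracy_pct", "time_s"))
  for (s in subjects) t3[[s]] <- c(100 * pk3["acc", s], pk3["time", s])
  t3[["Mean"]] <- c(mean(100 * pk3["acc", ]), mean(pk3["time", ]))

  utils::write.csv(t1, file.path(output_dir, "table1_grasp_vs_nomove.csv"),
                   row.names = FALSE)
  utils::write.csv(t2, file.path(output_dir, "table2_pairwise_grand.csv"),
                   row.names = FALSE)
  utils::write.csv(t3, file.path(output_dir, "table3_multiclass.csv"),
                   row.names = FALSE)
  list(table1 = t1, table2 = t2, table3 = t3)
}
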