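# Study-level orchestration: synthesize a demo cohort to disk, then run the
# full analysis chain (stage -> spectra -> spindles -> evoked -> stats) from
# a config file, producing per-subject metric tables, group statistics and a
# run log.

#' Genotype effect presets
#'
#' Multiplicative effect configurations per genotype emulating published
#' mutant contrasts: `grin2a_like` (gene dose-dependent gamma power increase,
#' spindle density increase, reduced 50 Hz ASSR entrainment), `akap11_like`
#' (gene dose-dependent spindle reduction, ~10% NREM reduction and ~70% P3a
#' reduction in the homozygote), and `null` (no effects).
#'
#' Note `gamma_amp` scales spectral *amplitude*, so a +20% power effect is
#' `sqrt(1.2)`; `assr_gain` scales the entrainment amplitude, so a -30%
#' effect on the excess power ratio is `sqrt(0.7)`.
#'
#' @param preset one of "grin2a_like", "akap11_like", "null".
#' @return named list of [effect_config()] per genotype (WT, Het, KO).
#' @export
effect_presets <- function(preset = c("grin2a_like", "akap11_like", "null")) {
  preset <- match.arg(preset)
  switch(preset,
    null = list(WT = effect_config(), Het = effect_config(), KO = effect_config()),
    grin2a_like = list(
      WT = effect_config(),
      Het = effect_config(gamma_amp = sqrt(1.10), spindle_rate = 1.25,
                          assr_gain = sqrt(0.70)),
      KO = effect_config(gamma_amp = sqrt(1.20), spindle_rate = 1.40,
                         assr_gain = sqrt(0.70))),
    akap11_like = list(
      WT = effect_config(),
      Het = effect_config(spindle_rate = 0.75),
      KO = effect_config(gamma_amp = sqrt(1.10), spindle_rate = 0.375,
                         nrem_fraction = 0.90, p3a_amp = 0.30)))
}

#' Write a synthetic demo study to disk
#'
#' Generates EDF recordings plus event/ground-truth tables for
#' `n_per_group` subjects per genotype under a chosen effect preset, and a
#' ready-to-run YAML config. Sessions are desk-scale by default (1-h sleep
#' sessions); full 24-h sessions are a config choice.
#'
#' @param effect_preset preset name for [effect_presets()].
#' @param n_per_group subjects per genotype (default 12).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @param genotypes genotype labels (subset of WT/Het/KO).
#' @param modalities any of "sleep", "assr", "mmn".
#' @param sleep_duration_s sleep-session length (default 3600 s).
#' @param target_nrem_fraction baseline NREM fraction (default 0.55).
#' @param sleep_onset_latency_s baseline sleep-onset latency (default 300 s).
#' @param fs sampling rate (default 1000 Hz).
#' @param assr_n_trains trains per ASSR frequency (default 20).
#' @param assr_stim_freqs ASSR stimulation frequencies.
#' @param mmn_n_standard,mmn_n_deviant oddball trial counts (defaults 900/100).
#' @param effects optional named list of [effect_config()] per genotype,
#'   overriding the preset.
#' @return the config as a list (also written to `<out_dir>/config.yaml`),
#'   invisibly.
#' @export
make_demo_study <- function(effect_preset = c("grin2a_like", "akap11_like", "null"),
                            n_per_group = 12, seed = 1, out_dir = tempfile("study"),
                            genotypes = c("WT", "Het", "KO"),
                            modalities = c("sleep", "assr", "mmn"),
                            sleep_duration_s = 3600, target_nrem_fraction = 0.55,
                            sleep_onset_latency_s = 300, fs = 1000,
                            assr_n_trains = 20, assr_stim_freqs = seq(10, 50, 10),
                            mmn_n_standard = 900, mmn_n_deviant = 100,
                            effects = NULL) {
  effect_preset <- match.arg(effect_preset)
  if (is.null(effects)) effects <- effect_presets(effect_preset)
  if (!all(genotypes %in% names(effects))) stop("missing effect config for some genotype")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  subjects <- list()
  si <- 0L
  for (g in genotypes) {
    for (i in seq_len(n_per_group)) {
      si <- si + 1L
      id <- sprintf("s%02d_%s", si, g)
      eff <- effects[[g]]
      sseed <- seed + 104729L * si
      entry <- list(id = id, genotype = g)
      meta <- list(subject = id, genotype = g)

      if ("sleep" %in% modalities) {
        hyp <- generate_hypnogram(
          sleep_duration_s,
          target_nrem_fraction = target_nrem_fraction * eff$nrem_fraction,
          sleep_onset_latency_s = sleep_onset_latency_s, seed = sseed + 1L)
        ses <- synthesize_session(hyp, fs = fs, seed = sseed + 2L,
                                  effects = eff, meta = meta)
        entry$sleep_edf <- paste0(id, "_sleep.edf")
        write_edf(ses$recording, file.path(out_dir, entry$sleep_edf))
        write_hypnogram(hyp, file.path(out_dir, paste0(id, "_truth_hypnogram.tsv")))
        utils::write.table(ses$spindles,
                           file.path(out_dir, paste0(id, "_truth_spindles.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if ("assr" %in% modalities) {
        ases <- generate_assr_session(stim_freqs = assr_stim_freqs,
                                      n_trains_per_freq = assr_n_trains,
                                      fs = fs, seed = sseed + 3L,
                                      effects = eff, meta = meta)
        entry$assr_edf <- paste0(id, "_assr.edf")
        entry$assr_events <- paste0(id, "_assr_events.tsv")
        write_edf(ases$recording, file.path(out_dir, entry$assr_edf))
        write_events(ases$events, file.path(out_dir, entry$assr_events))
      }
      if ("mmn" %in% modalities) {
        mses <- generate_mmn_session(n_standard = mmn_n_standard,
                                     n_deviant = mmn_n_deviant, fs = fs,
                                     seed = sseed + 4L, effects = eff, meta = meta)
        entry$mmn_edf <- paste0(id, "_mmn.edf")
        entry$mmn_events <- paste0(id, "_mmn_events.tsv")
        write_edf(mses$recording, file.path(out_dir, entry$mmn_edf))
        write_events(mses$events, file.path(out_dir, entry$mmn_events))
      }
      subjects[[si]] <- entry
    }
  }

  config <- list(
    study = list(out_dir = normalizePath(out_dir), seed = seed, fs = fs,
                 epoch_len_s = 10, effect_preset = effect_preset),
    params = list(
      staging = list(theta_delta_thr = 1.5, threshold_method = "bimodal"),
      spectra = list(fit_range = c(1, 50), bands = "default"),
      spindles = list(centers_hz = c(9, 11, 13, 15), detect_thr = 3,
                      boundary_thr = 1.5),
      assr = list(stim_freqs = assr_stim_freqs, window_s = 0.5, overlap_s = 0.25),
      mmn = list(t_min = -0.1, t_max = 0.35, baseline = c(-0.05, 0),
                 reject_uv = 400)),
    subjects = subjects)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(config)
}

analyze_subject <- function(entry, cfg) {
  root <- cfg$study$out_dir
  p <- cfg$params
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = entry$id, genotype = entry$genotype,
      metric = metric, value = as.numeric(value))
  }

  if (!is.null(entry$sleep_edf)) {
    rec <- read_edf(file.path(root, entry$sleep_edf))
    feats <- epoch_features(rec$channels$EEG, rec$channels$EMG, rec$fs,
                            epoch_len_s = cfg$study$epoch_len_s)
    hyp <- classify_stages(feats, theta_delta_thr = p$staging$theta_delta_thr,
                           threshold_method = p$staging$threshold_method,
                           epoch_len_s = cfg$study$epoch_len_s)
    sm <- sleep_metrics(hyp)
    add("pct_nrem", sm$pct_nrem)
    add("pct_rem", sm$pct_rem)
    add("pct_wake", sm$pct_wake)
    add("sleep_onset_score", sm$sleep_onset_score)
    add("nrem_bout_mean_s", sm$bouts$NREM$mean_s)
    add("transitions_per_h", sm$transitions_per_h)

    sp <- stage_psd(rec$channels$EEG, rec$fs, hyp, "NREM")
    bands <- eeg_bands()
    for (b in seq_len(nrow(bands))) {
      add(paste0("nrem_power_", bands$band[b]),
          band_power(sp, bands$low_hz[b], bands$high_hz[b]))
    }
    add("nrem_spectral_entropy", spectral_entropy(sp))
    fit <- fit_aperiodic(sp, fit_range = p$spectra$fit_range)
    add("nrem_aperiodic_exponent", fit$exponent)

    ev <- detect_spindles_multi(rec$channels$EEG, rec$fs, hyp,
                                centers_hz = p$spindles$centers_hz,
                                detect_thr = p$spindles$detect_thr,
                                boundary_thr = p$spindles$boundary_thr)
    dens <- spindle_density(ev, hyp, freqs = p$spindles$centers_hz)
    for (b in seq_len(nrow(dens))) {
      add(paste0("spindle_density_", dens$freq_hz[b], "hz"), dens$density_per_min[b])
    }
  }

  if (!is.null(entry$assr_edf)) {
    rec <- read_edf(file.path(root, entry$assr_edf))
    ev <- read_events(file.path(root, entry$assr_events))
    ep <- epoch_events(rec, ev, t_min = -0.5, t_max = 1.0,
                       baseline_window = NULL, reject_uv = Inf)
    for (f in p$assr$stim_freqs) {
      r <- assr_power_ratio(ep, f, window_s = p$assr$window_s,
                            overlap_s = p$assr$overlap_s)
      add(paste0("assr_ratio_", f, "hz"), r$ratio)
    }
  }

  if (!is.null(entry$mmn_edf)) {
    rec <- read_edf(file.path(root, entry$mmn_edf))
    ev <- read_events(file.path(root, entry$mmn_events))
    ep <- epoch_events(rec, ev, t_min = p$mmn$t_min, t_max = p$mmn$t_max,
                       baseline_window = p$mmn$baseline,
                       reject_uv = p$mmn$reject_uv)
    er <- erp_average(ep)
    for (cond in c("standard", "deviant")) {
      pk <- find_erp_peaks(erp_condition(er, cond))
      for (j in seq_len(nrow(pk))) {
        add(paste0("mmn_", cond, "_", pk$component[j], "_amp"), pk$amplitude_uv[j])
      }
    }
    dif <- erp_difference(erp_condition(er, "standard"), erp_condition(er, "deviant"))
    pk <- find_erp_peaks(dif)
    for (j in seq_len(nrow(pk))) {
      add(paste0("mmn_difference_", pk$component[j], "_amp"), pk$amplitude_uv[j])
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline over a study
#'
#' For every subject in the config: sleep staging and sleep metrics, NREM
#' spectral metrics (band powers, entropy, aperiodic exponent), spindle
#' densities, ASSR power ratios and MMN peak amplitudes; then per-metric
#' genotype group statistics (one-way ANOVA, Tukey HSD, percent change vs
#' WT). Subject failures are recorded and the run continues.
#'
#' @param config a config list from [make_demo_study()] or a path to a
#'   `config.yaml`.
#' @param results_dir where to write output tables (default
#'   `<out_dir>/results`).
#' @return list of class `study_report`: `metrics` (long per-subject table),
#'   `anova`, `tukey`, `failures` (character), `results_dir`, `status`
#'   ("ok" or "partial").
#' @export
run_study <- function(config, results_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$subjects) || length(cfg$subjects) == 0) {
    stop("validation error: empty subject manifest")
  }
  root <- cfg$study$out_dir
  for (s in cfg$subjects) {
    for (f in intersect(names(s), c("sleep_edf", "assr_edf", "assr_events",
                                    "mmn_edf", "mmn_events"))) {
      if (!file.exists(file.path(root, s[[f]]))) {
        stop("validation error: missing file ", s[[f]], " for subject ", s$id)
      }
    }
  }
  if (is.null(results_dir)) results_dir <- file.path(root, "results")
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("eegpheno run, seed=", cfg$study$seed,
                        ", fs=", cfg$study$fs,
                        ", epoch_len_s=", cfg$study$epoch_len_s),
                 paste0("resolved params: ",
                        yaml::as.yaml(cfg$params)))

  metrics <- list()
  failures <- character(0)
  for (s in cfg$subjects) {
    res <- tryCatch(analyze_subject(s, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, s$id)
      log_lines <- c(log_lines, paste0("FAIL ", s$id, ": ", conditionMessage(res)))
    } else {
      metrics[[length(metrics) + 1L]] <- res
      log_lines <- c(log_lines, paste0("ok   ", s$id, " (", nrow(res), " metrics)"))
    }
  }
  if (!length(metrics)) stop("all subjects failed")
  metrics <- do.call(rbind, metrics)

  anova_rows <- list()
  tukey_rows <- list()
  for (m in unique(metrics$metric)) {
    d <- metrics[metrics$metric == m & !is.na(metrics$value), ]
    tb <- table(d$genotype)
    if (length(tb) < 2 || any(tb < 2)) next
    a <- tryCatch(one_way_anova(d$value, d$genotype), error = function(e) NULL)
    if (is.null(a)) next
    pc <- if ("WT" %in% d$genotype) {
      tryCatch(percent_change(d$value, d$genotype, "WT"), error = function(e) NULL)
    } else NULL
    row <- data.frame(metric = m, F = a$F, df_between = a$df_between,
                      df_within = a$df_within, p = a$p)
    for (g in names(pc)) row[[paste0("pct_change_", g)]] <- pc[[g]]
    anova_rows[[length(anova_rows) + 1L]] <- row
    tk <- tukey_hsd(d$value, d$genotype)
    tk <- cbind(metric = m, tk)
    tukey_rows[[length(tukey_rows) + 1L]] <- tk
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  tukey_tab <- if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL

  utils::write.table(metrics, file.path(results_dir, "subject_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(anova_tab)) {
    utils::write.table(anova_tab, file.path(results_dir, "group_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tukey_tab)) {
    utils::write.table(tukey_tab, file.path(results_dir, "group_tukey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  status <- if (length(failures)) "partial" else "ok"
  yaml::write_yaml(list(status = status, n_subjects = length(cfg$subjects),
                        n_failed = length(failures), failures = failures,
                        seed = cfg$study$seed,
                        metrics = unique(metrics$metric)),
                   file.path(results_dir, "summary.yaml"))
  writeLines(log_lines, file.path(results_dir, "run_log.txt"))
  structure(list(metrics = metrics, anova = anova_tab, tukey = tukey_tab,
                 failures = failures, results_dir = results_dir,
                 status = status),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> status=", x$status, ", ",
      length(unique(x$metrics$subject)), " subjects, ",
      length(unique(x$metrics$metric)), " metrics -> ", x$results_dir, "\n",
      sep = "")
  if (!is.null(x$anova)) {
    sig <- x$anova[x$anova$p < 0.05, "metric"]
    if (length(sig)) cat("  ANOVA p<0.05:", paste(sig, collapse = ", "), "\n")
  }
  invisible(x)
}
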