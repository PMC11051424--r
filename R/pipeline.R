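#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable the pipeline honours, with defaults matching the
#' study design: 61 participants, a day-0 fraction of 8/61, +/- 4 h window
#' tolerance, a 20% discarded-IPI quality gate, and 10,000 bootstrap
#' iterations for effect sizes.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param n_participants cohort size.
#' @param effects `"reference"` (post-drug pattern), `"null"`, or a list of
#'   [day_effect()] objects.
#' @param day0_fraction fraction of participants with a pre-injection day.
#' @param recording_duration per-day recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param artifacts `TRUE` for the default [artifact_spec()], `FALSE` for
#'   clean signals, or an `artifact_spec`.
#' @param tolerance_h segment window tolerance, hours.
#' @param max_discarded segment quality threshold (discarded-IPI fraction).
#' @param spectral_fs tachogram resampling rate for the spectral features, Hz.
#' @param welch_segment_s Welch segment length, seconds.
#' @param n_boot bootstrap iterations.
#' @param out_dir output directory for [run_all()].
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_participants = 61L,
                       effects = "reference", day0_fraction = 8 / 61,
                       recording_duration = 1200, fs = 32,
                       artifacts = TRUE, tolerance_h = 4,
                       max_discarded = 0.20, spectral_fs = 4,
                       welch_segment_s = 120, n_boot = 10000L,
                       out_dir = "ppghrv-run") {
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         effects = effects, day0_fraction = day0_fraction,
         recording_duration = recording_duration, fs = fs,
         artifacts = artifacts, tolerance_h = tolerance_h,
         max_discarded = max_discarded, spectral_fs = spectral_fs,
         welch_segment_s = welch_segment_s, n_boot = as.integer(n_boot),
         out_dir = out_dir),
    class = "run_config")
}

#' Write / read a run configuration as a plain-text `key: value` file
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config` that round-trips identically.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  eff <- config$effects
  eff_str <- if (is.character(eff)) eff else {
    paste(vapply(eff, function(e) {
      sprintf("%d,%g,%g,%g", e$day_index, e$hr_shift, e$hf_scale,
              e$amplitude_scale)
    }, character(1)), collapse = ";")
  }
  art <- config$artifacts
  art_str <- if (is.logical(art)) as.character(art) else {
    sprintf("%g,%g,%g,%g,%g", art$motion_burst_rate, art$motion_burst_sd,
            art$motion_burst_duration, art$detachment_rate,
            art$detachment_duration)
  }
  lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("cohort.n_participants: %d", config$n_participants),
    sprintf("cohort.effects: %s", eff_str),
    sprintf("cohort.day0_fraction: %.17g", config$day0_fraction),
    sprintf("cohort.recording_duration: %.17g", config$recording_duration),
    sprintf("cohort.fs: %.17g", config$fs),
    sprintf("cohort.artifacts: %s", art_str),
    sprintf("segment.tolerance_h: %.17g", config$tolerance_h),
    sprintf("segment.max_discarded: %.17g", config$max_discarded),
    sprintf("spectral.fs_resample: %.17g", config$spectral_fs),
    sprintf("spectral.welch_segment_s: %.17g", config$welch_segment_s),
    sprintf("stats.n_boot: %d", config$n_boot),
    sprintf("output.dir: %s", config$out_dir))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  eff_raw <- get("cohort.effects", "reference")
  effects <- if (eff_raw %in% c("reference", "null")) eff_raw else {
    lapply(strsplit(eff_raw, ";")[[1]], function(s) {
      p <- as.numeric(strsplit(s, ",")[[1]])
      day_effect(p[1], hr_shift = p[2], hf_scale = p[3],
                 amplitude_scale = p[4])
    })
  }
  art_raw <- get("cohort.artifacts", "TRUE")
  artifacts <- if (art_raw %in% c("TRUE", "FALSE")) as.logical(art_raw) else {
    p <- as.numeric(strsplit(art_raw, ",")[[1]])
    artifact_spec(p[1], p[2], p[3], p[4], p[5])
  }
  run_config(
    seed = as.integer(get("seed", "1")),
    n_participants = as.integer(get("cohort.n_participants", "61")),
    effects = effects,
    day0_fraction = as.numeric(get("cohort.day0_fraction", 8 / 61)),
    recording_duration = as.numeric(get("cohort.recording_duration", "1200")),
    fs = as.numeric(get("cohort.fs", "32")),
    artifacts = artifacts,
    tolerance_h = as.numeric(get("segment.tolerance_h", "4")),
    max_discarded = as.numeric(get("segment.max_discarded", "0.2")),
    spectral_fs = as.numeric(get("spectral.fs_resample", "4")),
    welch_segment_s = as.numeric(get("spectral.welch_segment_s", "120")),
    n_boot = as.integer(get("stats.n_boot", "10000")),
    out_dir = get("output.dir", "ppghrv-run"))
}

.resolve_effects <- function(effects) {
  if (is.character(effects)) {
    switch(effects,
           reference = reference_day_effects(),
           null = null_day_effects(),
           stop("unknown effects preset: ", effects, call. = FALSE))
  } else effects
}

.resolve_artifacts <- function(artifacts) {
  if (isTRUE(artifacts)) artifact_spec()
  else if (isFALSE(artifacts)) NULL
  else artifacts
}

#' Extract HRV and morphology feature tables from a cohort
#'
#' Slices each accepted segment, runs the IPI pipeline and both feature
#' layers, and returns tidy per-participant-day tables.
#'
#' @param cohort a `ppg_cohort`.
#' @param segments segment report from [select_cohort_segments()].
#' @param morphology also compute morphology features (slower).
#' @param spectral_fs,welch_segment_s spectral settings for [hrv_features()].
#' @return list with `hrv` and `morph` data frames (participant_id, day,
#'   feature columns), `ensembles` (per-day ensemble pulses) and the
#'   `segments` report.
#' @export
extract_cohort_features <- function(cohort, segments, morphology = TRUE,
                                    spectral_fs = 4, welch_segment_s = 120) {
  hrv_rows <- list()
  morph_rows <- list()
  pulses_by_day <- list()
  acc <- segments[segments$accepted, , drop = FALSE]
  for (i in seq_len(nrow(acc))) {
    row <- acc[i, ]
    key <- sprintf("%s_d%d", row$participant_id, row$day_index)
    rec <- cohort$recordings[[key]]
    seg <- slice_recording(rec, row$start, row$duration)
    ipis <- ipi_series(seg)
    if (length(ipis$clean_ipis) < 4L) next
    hrv_rows[[key]] <- cbind(
      data.frame(participant_id = row$participant_id, day = row$day_index,
                 stringsAsFactors = FALSE),
      hrv_features(ipis, fs_resample = spectral_fs,
                   seg_len_s = welch_segment_s))
    if (morphology) {
      mf <- morph_features(seg, ipis)
      if (!is.null(mf$features)) {
        morph_rows[[key]] <- cbind(
          data.frame(participant_id = row$participant_id,
                     day = row$day_index, stringsAsFactors = FALSE),
          mf$features)
        dkey <- as.character(row$day_index)
        pulses_by_day[[dkey]] <- c(pulses_by_day[[dkey]], mf$pulses)
      }
    }
  }
  ensembles <- lapply(sort(names(pulses_by_day)), function(d) {
    ensemble_average(pulses_by_day[[d]], day_index = as.integer(d))
  })
  list(hrv = do.call(rbind, c(hrv_rows, list(make.row.names = FALSE))),
       morph = if (length(morph_rows)) {
         do.call(rbind, c(morph_rows, list(make.row.names = FALSE)))
       } else NULL,
       ensembles = ensembles, segments = segments)
}

#' Render a per-feature text report of comparison results
#'
#' One block per feature: the omnibus p-value on top, then one line per
#' significant pairwise contrast with its adjusted p and bootstrap effect
#' size, mirroring the arrow annotations of the study's figures.
#'
#' @param results list with `omnibus` and `pairwise` as returned by the
#'   analysis drivers.
#' @param title report heading.
#' @return character vector of report lines.
#' @export
format_report <- function(results, title = "Comparison report") {
  lines <- c(paste0("# ", title), "")
  for (f in results$omnibus$feature) {
    om <- results$omnibus[results$omnibus$feature == f, ]
    lines <- c(lines, sprintf("## %s", f),
               sprintf("omnibus: chi2 = %.3f, df = %d, p = %.4g (n = %d)",
                       om$statistic, om$df, om$p_value, om$n))
    pw <- results$pairwise[results$pairwise$feature == f, ]
    sig <- pw[!is.na(pw$p_adj) & pw$p_adj < 0.05, ]
    if (nrow(sig) == 0L) {
      lines <- c(lines, "no significant pairwise contrasts", "")
    } else {
      lines <- c(lines, sprintf(
        "%s -> %s: p_adj = %.4g, mean d = %.2f [%.2f, %.2f]",
        sig$group_a, sig$group_b, sig$p_adj, sig$mean_d, sig$ci_low,
        sig$ci_high), "")
    }
  }
  lines
}

#' Run the full pipeline: simulate, extract, compute features, compare, report
#'
#' All outputs (feature tables, segment report, statistical results, text
#' report, settings log) are written under `config$out_dir` and are
#' byte-identical across runs with the same configuration.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the feature tables and results.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("ppghrv run, seed %d", config$seed),
                 "settings:",
                 paste0("  ", readLines(write_run_config(
                   config, file.path(config$out_dir, "config.txt")))))

  cohort <- generate_cohort(
    n_participants = config$n_participants,
    day_effects = .resolve_effects(config$effects),
    day0_fraction = config$day0_fraction,
    recording_duration = config$recording_duration,
    fs = config$fs,
    artifacts = .resolve_artifacts(config$artifacts),
    seed = config$seed)
  log_lines <- c(log_lines, sprintf("simulated %d recordings",
                                    length(cohort$recordings)))

  segments <- select_cohort_segments(cohort, tolerance_h = config$tolerance_h,
                                     max_discarded = config$max_discarded)
  utils::write.csv(segments, file.path(config$out_dir, "segments.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("%d/%d segments accepted",
                                    sum(segments$accepted), nrow(segments)))

  feats <- extract_cohort_features(cohort, segments,
                                   spectral_fs = config$spectral_fs,
                                   welch_segment_s = config$welch_segment_s)
  if (is.null(feats$hrv) || nrow(feats$hrv) == 0L) {
    writeLines(c(log_lines, "FAILED at stage: features (empty cohort)"), logf)
    stop("no usable segments: feature tables are empty", call. = FALSE)
  }
  utils::write.csv(feats$hrv, file.path(config$out_dir, "features_hrv.csv"),
                   row.names = FALSE)
  if (!is.null(feats$morph)) {
    utils::write.csv(feats$morph,
                     file.path(config$out_dir, "features_morph.csv"),
                     row.names = FALSE)
  }
  if (length(feats$ensembles)) {
    ens <- do.call(rbind, lapply(feats$ensembles, function(e) {
      data.frame(day = e$day_index, grid = e$grid, mean = e$mean,
                 n_pulses = e$n_pulses)
    }))
    utils::write.csv(ens, file.path(config$out_dir, "ensemble_pulses.csv"),
                     row.names = FALSE)
  }

  hrv_res <- run_paired_hrv_analysis(feats$hrv, n_boot = config$n_boot,
                                     seed = derive_seed(config$seed, "hrv"))
  utils::write.csv(hrv_res$omnibus,
                   file.path(config$out_dir, "results_hrv_omnibus.csv"),
                   row.names = FALSE)
  utils::write.csv(hrv_res$pairwise,
                   file.path(config$out_dir, "results_hrv_pairwise.csv"),
                   row.names = FALSE)
  morph_res <- NULL
  if (!is.null(feats$morph)) {
    morph_res <- run_unpaired_morph_analysis(
      feats$morph, n_boot = config$n_boot,
      seed = derive_seed(config$seed, "morph"))
    utils::write.csv(morph_res$omnibus,
                     file.path(config$out_dir, "results_morph_omnibus.csv"),
                     row.names = FALSE)
    utils::write.csv(morph_res$pairwise,
                     file.path(config$out_dir, "results_morph_pairwise.csv"),
                     row.names = FALSE)
  }
  report <- c(format_report(hrv_res, "Paired HRV comparison"),
              if (!is.null(morph_res)) {
                format_report(morph_res, "Unpaired morphology comparison")
              })
  writeLines(report, file.path(config$out_dir, "report.md"))
  writeLines(c(log_lines, "completed"), logf)
  invisible(list(cohort = cohort, segments = segments, features = feats,
                 hrv = hrv_res, morph = morph_res))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract`, `ipi`, `features`, `compare`,
#' `report`, `run-all`. Invoke via
#' `Rscript -e 'ppghrv::ppghrv_main()' -- <cmd> ...` or the wrapper script in
#' `inst/cli/`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
ppghrv_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(name, default = NULL) {
    i <- match(paste0("--", name), args)
    if (is.na(i) || i == length(args)) default else args[i + 1L]
  }
  cmd <- if (length(args)) args[1] else "help"
  status <- 0L
  switch(cmd,
    simulate = {
      cohort <- generate_cohort(
        n_participants = as.integer(opt("n", "10")),
        day_effects = .resolve_effects(opt("effects", "reference")),
        recording_duration = as.numeric(opt("duration", "420")),
        seed = as.integer(opt("seed", "1")))
      write_cohort(cohort, opt("out", "cohort"))
      message("cohort written to ", opt("out", "cohort"))
    },
    extract = {
      dir <- dirname(opt("manifest", "cohort/manifest.csv"))
      man <- read_manifest(opt("manifest", "cohort/manifest.csv"))
      recs <- lapply(seq_len(nrow(man)), function(i) {
        read_recording(file.path(dir, man$file[i]))
      })
      names(recs) <- sprintf("%s_d%d", man$participant_id, man$day)
      segs <- select_cohort_segments(
        list(manifest = man, recordings = recs),
        tolerance_h = as.numeric(opt("tolerance-h", "4")))
      out <- opt("out", "segments.csv")
      utils::write.csv(segs, out, row.names = FALSE)
      message("segment report written to ", out)
    },
    ipi = {
      rec <- read_recording(opt("in"))
      write_ipi_series(ipi_series(rec), opt("out", "ipis.csv"))
    },
    features = {
      rec <- read_recording(opt("in"))
      ipis <- ipi_series(rec)
      what <- if (length(args) > 1L && !startsWith(args[2], "--")) args[2]
              else "hrv"
      out <- opt("out", paste0("features_", what, ".csv"))
      if (what == "morph") {
        mf <- morph_features(rec, ipis)
        utils::write.csv(mf$features, out, row.names = FALSE)
      } else {
        utils::write.csv(hrv_features(ipis), out, row.names = FALSE)
      }
    },
    compare = {
      tbl <- utils::read.csv(opt("hrv", opt("morph", "features.csv")))
      design <- opt("design", "paired")
      res <- if (design == "paired") run_paired_hrv_analysis(tbl)
             else run_unpaired_morph_analysis(tbl)
      out <- opt("out", "results.csv")
      utils::write.csv(res$pairwise, out, row.names = FALSE)
      writeLines(format_report(res), sub("\\.csv$", ".md", out))
    },
    report = {
      om <- utils::read.csv(opt("omnibus"))
      pw <- utils::read.csv(opt("pairwise"))
      writeLines(format_report(list(omnibus = om, pairwise = pw),
                               opt("title", "Comparison report")),
                 opt("out", "report.md"))
    },
    `run-all` = {
      cfg <- if (!is.null(opt("config"))) read_run_config(opt("config"))
             else run_config(seed = as.integer(opt("seed", "1")),
                             n_participants = as.integer(opt("n", "61")),
                             out_dir = opt("out", "ppghrv-run"))
      run_all(cfg)
    },
    {
      message("usage: ppghrv <simulate|extract|ipi|features|compare|report|run-all> [--key value ...]")
      status <- if (cmd == "help") 0L else 1L
    })
  invisible(status)
}
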