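#' Analysis configuration
#'
#' One configuration object governs all stages. Defaults follow the
#' conventions of long canine Holter work: 15-min spectral epochs, VLF/LF/HF
#' bands 0.003-0.04 / 0.04-0.15 / 0.15-0.4 Hz, per-beat QT correction,
#' Lown thresholds at 30 isolated PVBs per hour. Parameters the underlying
#' methods leave open (tachogram resampling rate, epoch coverage threshold,
#' physiologic NN guard) carry documented package defaults.
#'
#' @param qtc_mode `"per-beat"` or `"trace-mean"`.
#' @param nn_min,nn_max physiologic NN guard, ms.
#' @param epoch_min spectral epoch length, minutes.
#' @param min_coverage minimum NN coverage per epoch.
#' @param resample_hz tachogram resampling rate.
#' @param nfft FFT segment length.
#' @param overlap Welch segment overlap fraction.
#' @param max_gap_ms longest interpolated cleaning gap.
#' @param min_alternations bigeminy detection threshold.
#' @return list of class `hrv_config`.
#' @export
hrv_config <- function(qtc_mode = "per-beat", nn_min = 200, nn_max = 3000,
                       epoch_min = 15, min_coverage = 0.8, resample_hz = 2,
                       nfft = 512, overlap = 0.5, max_gap_ms = 5000,
                       min_alternations = 4) {
  structure(as.list(environment()), class = "hrv_config")
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in every output row so
#' results are traceable to the exact analysis parameters.
#'
#' @param config an `hrv_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Analyse one recording end to end
#'
#' Runs every per-trace stage on one beat stream — interval/QTc summary,
#' arrhythmia quantification with Lown grade, time-domain and Poincare HRV,
#' spectral band powers — and flattens the results into a single summary
#' row. Partial failures degrade gracefully: a trace without fiducials gets
#' `NA` PR/QT/QTc but complete HRV; absent values are explicit `NA`, never
#' zero-filled. Deterministic for fixed input and configuration.
#'
#' @param x a `beat_series` or a path readable by [read_beats()].
#' @param config an [hrv_config()].
#' @return one-row data.frame of class `trace_summary` with recording
#'   metadata, all analysis fields and provenance (`package_version`,
#'   `config_hash`, `synthetic_seed` when present).
#' @export
run_trace <- function(x, config = hrv_config()) {
  series <- if (inherits(x, "beat_series")) x else read_beats(x)
  m <- series$meta
  iv <- tryCatch(
    summarize_intervals(series, qtc_mode = config$qtc_mode,
                        nn_min = config$nn_min, nn_max = config$nn_max),
    error = function(e) NULL)
  arr <- arrhythmia_summary(series, min_alternations = config$min_alternations)
  nn <- clean_to_nn(series, nn_min = config$nn_min, nn_max = config$nn_max)
  td <- tryCatch(time_domain(nn), error = function(e) NULL)
  pc <- tryCatch(poincare(nn), error = function(e) NULL)
  sp <- spectral_summary(nn, duration_ms = m$duration_ms,
                         epoch_min = config$epoch_min,
                         min_coverage = config$min_coverage,
                         fs_hz = config$resample_hz, nfft = config$nfft,
                         overlap = config$overlap,
                         max_gap_ms = config$max_gap_ms)
  g <- function(v) if (is.null(v) || length(v) == 0) NA else v
  row <- data.frame(
    recording_id = g(m$recording_id), subject = g(m$subject_id),
    group = g(m$group), age_months = g(m$age_months),
    duration_ms = g(m$duration_ms),
    n_beats = n_beats(series), n_nn = length(nn$rr_ms),
    nn_excluded = nn$n_excluded, nn_guard_excluded = nn$n_guard_excluded,
    hr_bpm = g(iv$hr_bpm), mean_nn_ms = g(iv$mean_nn_ms),
    pr_ms = g(iv$pr_ms), qt_ms = g(iv$qt_ms),
    qtc_b_ms = g(iv$qtc_ms$B), qtc_f_ms = g(iv$qtc_ms$F),
    qtc_v_ms = g(iv$qtc_ms$V), qtc_m_ms = g(iv$qtc_ms$M),
    n_pvb = arr$n_pvb, pvb_per_hr = arr$pvb_per_hr, pvb_pct = arr$pvb_pct,
    n_doublets = arr$n_doublets, n_triplets = arr$n_triplets,
    n_salvos = arr$n_salvos, max_run_len = arr$max_run_len,
    bigeminy = arr$bigeminy, polymorphic = arr$polymorphic,
    r_on_t = arr$r_on_t, lown = as.character(arr$lown),
    sdnn_ms = g(td$sdnn_ms), cv_rr = g(td$cv_rr), rmssd_ms = g(td$rmssd_ms),
    hrv_ti = g(td$hrv_ti), pnn50_pct = g(td$pnn50_pct),
    pnn10pct_meanrr_pct = g(td$pnn10pct_meanrr_pct),
    stv_ms = g(pc$stv_ms), ltv_ms = g(pc$ltv_ms),
    stv_ltv_ratio = g(pc$stv_ltv_ratio),
    vlf_ms2 = sp$vlf_ms2, lf_ms2 = sp$lf_ms2, hf_ms2 = sp$hf_ms2,
    total_ms2 = sp$total_ms2, lf_hf = sp$lf_hf, hf_nu_pct = sp$hf_nu_pct,
    n_epochs_used = sp$n_epochs_used,
    n_epochs_rejected = sp$n_epochs_rejected,
    package_version = as.character(utils::packageVersion("holterhrv")),
    config_hash = config_hash(config),
    synthetic_seed = g(m$synthetic_seed),
    stringsAsFactors = FALSE
  )
  class(row) <- c("trace_summary", "data.frame")
  row
}

#' Analyse a cohort manifest end to end
#'
#' Reads the manifest (`subject,group,age_months,recording_path` plus
#' optional outcome/covariate columns), runs [run_trace()] per recording
#' (rows whose file is missing or unreadable are skipped with a logged
#' reason and the run continues), assembles the long [cohort_table()], runs
#' the per-timepoint LSD group contrasts for the requested variables and
#' the Spearman screen of early predictors against the outcome, and can
#' write a markdown report of group x age means.
#'
#' @param manifest data.frame or path to a manifest CSV. In-memory beat
#'   series can be supplied via `series` (named by `recording_path`),
#'   bypassing disk reads.
#' @param config an [hrv_config()].
#' @param base_dir directory recording paths are relative to (default: the
#'   manifest's directory, or `"."`).
#' @param compare_vars variables to contrast between groups (default a core
#'   panel).
#' @param screen_predictors data.frame `variable, age_months` for the
#'   outcome screen, or `NULL` to skip.
#' @param outcome outcome column name (default `"lvfs_24m"`).
#' @param series optional named list of `beat_series`.
#' @param report_path optional path for a markdown report.
#' @return list of class `cohort_result`: `summaries` (wide per-recording
#'   table), `table` (long cohort table), `comparisons` (named list of
#'   [lsd_compare()] results), `screen`, `skipped` (data.frame of skipped
#'   rows and reasons).
#' @export
run_cohort <- function(manifest, config = hrv_config(), base_dir = NULL,
                       compare_vars = c("hr_bpm", "qtc_v_ms", "pr_ms",
                                        "pnn50_pct", "stv_ms", "vlf_ms2"),
                       screen_predictors = NULL, outcome = "lvfs_24m",
                       series = NULL, report_path = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (!nrow(manifest)) stop("empty manifest")
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    mr <- manifest[i, ]
    bs <- NULL
    if (!is.null(series) && mr$recording_path %in% names(series)) {
      bs <- series[[mr$recording_path]]
    } else {
      path <- file.path(base_dir, mr$recording_path)
      bs <- tryCatch(read_beats(path, meta = list(
        subject_id = mr$subject, group = mr$group,
        age_months = mr$age_months)),
        error = function(e) {
          message("skipping ", mr$recording_path, ": ", conditionMessage(e))
          NULL
        })
    }
    if (is.null(bs)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        recording_path = mr$recording_path, reason = "unreadable",
        stringsAsFactors = FALSE)
      next
    }
    bs$meta$subject_id <- mr$subject
    bs$meta$group <- mr$group
    bs$meta$age_months <- mr$age_months
    row <- tryCatch(run_trace(bs, config), error = function(e) {
      message("skipping ", mr$recording_path, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        recording_path = mr$recording_path, reason = "analysis failed",
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no analysable recordings in manifest")
  summaries <- do.call(rbind, rows)

  cov_cols <- intersect(c("lvfs_24m", "ctni", "ntprobnp"), names(manifest))
  covariates <- NULL
  if (length(cov_cols)) {
    covariates <- unique(manifest[, c("subject", "group", cov_cols)])
    covariates <- covariates[rowSums(!is.na(covariates[, cov_cols, drop = FALSE])) > 0, ]
    if (!nrow(covariates)) covariates <- NULL
  }
  tab <- cohort_table(summaries, covariates)

  comparisons <- list()
  for (v in compare_vars) {
    comparisons[[v]] <- tryCatch(lsd_compare(tab, v), error = function(e) NULL)
  }
  comparisons <- Filter(Negate(is.null), comparisons)

  screen <- NULL
  if (!is.null(screen_predictors) && outcome %in% tab$variable) {
    screen <- early_late_screen(tab, screen_predictors, outcome = outcome)
  }
  res <- structure(
    list(summaries = summaries, table = tab, comparisons = comparisons,
         screen = screen,
         skipped = if (length(skipped)) do.call(rbind, skipped)
                   else data.frame(recording_path = character(0),
                                   reason = character(0))),
    class = "cohort_result")
  if (!is.null(report_path)) write_cohort_report(res, report_path)
  res
}

#' Write a markdown report of a cohort analysis
#'
#' Group x age mean (SD) tables per compared variable with the LSD p-value
#' per timepoint, followed by the outcome screen when present.
#'
#' @param res a `cohort_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(res, path) {
  ln <- c("# Cohort analysis report", "",
          sprintf("%d recordings analysed, %d skipped.",
                  nrow(res$summaries), nrow(res$skipped)), "")
  for (v in names(res$comparisons)) {
    cmp <- res$comparisons[[v]]
    ln <- c(ln, sprintf("## %s", v), "",
            sprintf("| Age (months) | %s mean (SD), n | %s mean (SD), n | LSD p |",
                    cmp$groups[1], cmp$groups[2]),
            "|---|---|---|---|")
    for (i in seq_len(nrow(cmp$per_age))) {
      r <- cmp$per_age[i, ]
      ln <- c(ln, sprintf("| %g | %.1f (%.1f), n=%d | %.1f (%.1f), n=%d | %.3g |",
                          r$age_months, r$mean_1, r$sd_1, r$n_1,
                          r$mean_2, r$sd_2, r$n_2, r$p))
    }
    ln <- c(ln, "")
  }
  if (!is.null(res$screen)) {
    ln <- c(ln, "## Outcome screen", "",
            "| Variable | Age | rho | n | p | p (BH) |", "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(res$screen))) {
      r <- res$screen[i, ]
      ln <- c(ln, sprintf("| %s | %g | %.3f | %d | %.3g | %.3g |",
                          r$variable, r$age_months, r$rho, r$n, r$p, r$p_bh))
    }
  }
  writeLines(ln, path)
  invisible(path)
}
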