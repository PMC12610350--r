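#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the input mode (synthetic
#' cohort or raw CSV files plus a manifest), the segmentation settings, the
#' measure options and the statistics options.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param profiles Named list of [task_profile()]s (synthetic mode).
#' @param paths Named character vector of raw CSV paths, one per
#'   participant (files mode).
#' @param manifest_path Path to the session manifest JSON (files mode).
#' @param seg A [segmentation_config()].
#' @param accel_sd `"signed"` or `"rectified"` acceleration SD; recorded in
#'   the report.
#' @param gate_alpha Normality-gate level for the omnibus choice. Default
#'   0.05.
#' @param corrected_alpha Bonferroni-corrected per-test level. Default
#'   0.004 (familywise 0.05 over 12 tests).
#' @param icc_forms Named character vector mapping each measure to its ICC
#'   form; duration is rated as a single measurement, the averaged signal
#'   measures as average-of-k.
#' @param outdir Output directory (`NULL` for no files).
#' @param verbose Emit per-stage progress messages. Default `FALSE`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       cohort = cohort_config(),
                       profiles = default_task_profiles(),
                       paths = NULL, manifest_path = NULL,
                       seg = segmentation_config(),
                       accel_sd = c("signed", "rectified"),
                       gate_alpha = 0.05, corrected_alpha = 0.004,
                       icc_forms = c(duration_s = "single",
                                     avg_total_ang_vel_dps = "average",
                                     total_sd_accel_ms2 = "average"),
                       outdir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  accel_sd <- match.arg(accel_sd)
  if (mode == "files" && (is.null(paths) || is.null(manifest_path))) {
    stop("files mode needs `paths` and `manifest_path`", call. = FALSE)
  }
  structure(list(mode = mode, cohort = cohort, profiles = profiles,
                 paths = paths, manifest_path = manifest_path, seg = seg,
                 accel_sd = accel_sd, gate_alpha = gate_alpha,
                 corrected_alpha = corrected_alpha, icc_forms = icc_forms,
                 outdir = outdir, verbose = isTRUE(verbose)),
            class = "run_config")
}

measure_columns <- c("duration_s", "avg_total_ang_vel_dps",
                     "total_sd_accel_ms2")

## participants x conditions wide matrix for one task/measure
wide_measure <- function(measures, task, measure, conditions) {
  sub <- measures[measures$task == task & measures$condition %in% conditions, ]
  ids <- unique(measures$participant)
  out <- matrix(NA_real_, length(ids), length(conditions),
                dimnames = list(ids, conditions))
  for (j in seq_along(conditions)) {
    rows <- sub[sub$condition == conditions[j], ]
    out[match(rows$participant, ids), j] <- rows[[measure]]
  }
  out
}

#' Statistical battery over a measure table
#'
#' Runs, for every task and each of the three outcome measures: the
#' within-session reliability ICC on the two repeated comfortable 10-rep
#' trials (form per `icc_forms`), the normality-gated omnibus test over the
#' 5/10/20-repetition comfortable conditions, and the paired fast-versus-
#' comfortable comparison, all on complete cases per analysis.
#'
#' @param measures Long measure table (from [compute_measure_table()] or
#'   [truth_measure_table()]) with columns `participant`, `task`,
#'   `condition`, and the three measure columns.
#' @param gate_alpha,corrected_alpha,icc_forms,accel_sd See [run_config()].
#' @param exclusions Optional [exclusion_summary()] to embed in the report.
#' @return A list of class `psychometric_report` with data frames
#'   `reliability`, `omnibus`, `paired`, plus `exclusions`, `options` and
#'   `version`.
#' @export
analyze_measures <- function(measures, gate_alpha = 0.05,
                             corrected_alpha = 0.004,
                             icc_forms = c(duration_s = "single",
                                           avg_total_ang_vel_dps = "average",
                                           total_sd_accel_ms2 = "average"),
                             accel_sd = "signed", exclusions = NULL) {
  tasks <- unique(measures$task)
  rel <- omn <- par <- list()
  for (task in tasks) {
    for (meas in measure_columns) {
      ## reliability: repeated 10-rep comfortable trials
      relmat <- wide_measure(measures, task, meas, c("c10", "c10r"))
      icc <- tryCatch(icc_agreement(relmat, form = icc_forms[[meas]]),
                      error = function(e) NULL)
      rel[[length(rel) + 1L]] <- data.frame(
        task = task, measure = meas,
        form = icc_forms[[meas]],
        n = if (is.null(icc)) NA_integer_ else icc$n,
        n_dropped = if (is.null(icc)) NA_integer_ else icc$n_dropped,
        icc = if (is.null(icc)) NA_real_ else icc$estimate,
        ci_lower = if (is.null(icc)) NA_real_ else icc$lower,
        ci_upper = if (is.null(icc)) NA_real_ else icc$upper,
        label = if (is.null(icc)) NA_character_ else icc$label
      )

      ## omnibus: 5 / 10 / 20 comfortable repetitions
      omat <- wide_measure(measures, task, meas, c("c5", "c10", "c20"))
      omat <- omat[stats::complete.cases(omat), , drop = FALSE]
      ot <- tryCatch(omnibus_test(omat, gate_alpha), error = function(e) NULL)
      if (is.null(ot)) {
        # cell explicitly marked excluded (e.g. too few complete cases)
        ot <- list(n = nrow(omat), test = NA_character_,
                   statistic = NA_real_, df = c(NA_real_, NA_real_),
                   p = NA_real_, gg_p = NA_real_, mauchly_w = NA_real_,
                   mauchly_p = NA_real_, sphericity_violated = NA,
                   effect_size = NA_real_, effect_size_name = NA_character_,
                   cond_mean = colMeans(omat), cond_sd = apply(omat, 2L,
                                                               stats::sd))
        ot$test <- "excluded"
      }
      omn[[length(omn) + 1L]] <- data.frame(
        task = task, measure = meas, n = ot$n, test = ot$test,
        statistic = ot$statistic,
        df1 = ot$df[1L], df2 = if (length(ot$df) > 1L) ot$df[2L] else NA,
        p = ot$p,
        gg_p = if (identical(ot$test, "rm_anova")) ot$gg_p else NA_real_,
        mauchly_w = if (identical(ot$test, "rm_anova")) ot$mauchly_w else
          NA_real_,
        mauchly_p = if (identical(ot$test, "rm_anova")) ot$mauchly_p else
          NA_real_,
        sphericity_violated = if (identical(ot$test, "rm_anova"))
          ot$sphericity_violated else NA,
        effect_size = ot$effect_size, effect_size_name = ot$effect_size_name,
        mean_c5 = ot$cond_mean[1L], sd_c5 = ot$cond_sd[1L],
        mean_c10 = ot$cond_mean[2L], sd_c10 = ot$cond_sd[2L],
        mean_c20 = ot$cond_mean[3L], sd_c20 = ot$cond_sd[3L],
        significant = if (is.na(ot$p)) NA else ot$p < corrected_alpha
      )

      ## paired: 10 fast vs 10 comfortable
      pmat <- wide_measure(measures, task, meas, c("c10", "f10"))
      pc <- tryCatch(paired_comparison(pmat[, "c10"], pmat[, "f10"],
                                       alpha = corrected_alpha),
                     error = function(e) NULL)
      if (is.null(pc)) {
        pc <- list(n = sum(stats::complete.cases(pmat)),
                   comfortable_mean = NA_real_, comfortable_sd = NA_real_,
                   fast_mean = NA_real_, fast_sd = NA_real_,
                   mean_diff = NA_real_, sd_diff = NA_real_, t = NA_real_,
                   df = NA_integer_, p = NA_real_, ci = c(NA_real_, NA_real_),
                   cohens_d = NA_real_, significant = NA)
      }
      par[[length(par) + 1L]] <- data.frame(
        task = task, measure = meas, n = pc$n,
        comfortable_mean = pc$comfortable_mean,
        comfortable_sd = pc$comfortable_sd,
        fast_mean = pc$fast_mean, fast_sd = pc$fast_sd,
        mean_diff = pc$mean_diff, sd_diff = pc$sd_diff,
        t = pc$t, df = pc$df, p = pc$p,
        ci_lower = pc$ci[1L], ci_upper = pc$ci[2L],
        cohens_d = pc$cohens_d, significant = pc$significant
      )
    }
  }
  structure(list(
    reliability = do.call(rbind, rel),
    omnibus = do.call(rbind, omn),
    paired = do.call(rbind, par),
    exclusions = exclusions,
    options = list(gate_alpha = gate_alpha,
                   corrected_alpha = corrected_alpha,
                   icc_forms = as.list(icc_forms), accel_sd = accel_sd),
    version = as.character(utils::packageVersion("wristrep"))
  ), class = "psychometric_report")
}

#' @export
print.psychometric_report <- function(x, ...) {
  cat(sprintf("<psychometric_report> %d reliability, %d omnibus, %d paired rows",
              nrow(x$reliability), nrow(x$omnibus), nrow(x$paired)))
  if (!is.null(x$exclusions)) cat(" | excluded", x$exclusions$label)
  cat("\n")
  invisible(x)
}

process_session <- function(id, stream, manifest_rows, seg, accel_sd,
                            verbose = FALSE) {
  val <- validate_stream(stream)
  if (!val$ok) {
    stop(sprintf("stage validate, session %s: %d monotonicity violation(s)",
                 id, val$n_monotonicity_violations), call. = FALSE)
  }
  rect <- rectify(stream)
  windows <- detect_trials(rect, seg)
  windows <- flag_ambiguous(windows, rect, seg,
                            expected_n = nrow(manifest_rows))
  labeled <- tryCatch(assign_conditions(windows, manifest_rows),
                      error = function(e) {
                        stop("stage assign, ", conditionMessage(e),
                             call. = FALSE)
                      })
  tab <- compute_measure_table(stream, labeled, accel_sd = accel_sd)
  if (verbose) {
    message(sprintf("session %s: %d windows, %d flagged, %d measured",
                    id, nrow(windows), sum(windows$flagged), nrow(tab)))
  }
  list(measures = tab, n_windows = nrow(windows),
       n_flagged = sum(windows$flagged))
}

#' Run the full pipeline
#'
#' End-to-end run: obtain sessions (generate a synthetic cohort or read raw
#' CSVs), validate, rectify, segment, flag, label, measure, and run the
#' statistical battery. Deterministic given the seed and inputs. When
#' `outdir` is set, writes `measures.csv` and the report in csv, json and
#' markdown forms.
#'
#' @param config A [run_config()].
#' @return A `psychometric_report`; the measure table is attached as
#'   attribute `measures`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort, config$profiles,
                              render_streams = TRUE)
    ids <- names(cohort$sessions)
    get_stream <- function(id) cohort$sessions[[id]]$stream
    get_manifest <- function(id) cohort$sessions[[id]]$manifest
  } else {
    manifest_all <- read_manifest(config$manifest_path)
    ids <- names(config$paths)
    get_stream <- function(id) read_raw_csv(config$paths[[id]])
    get_manifest <- function(id)
      manifest_all[manifest_all$participant == id, ]
  }

  tabs <- list()
  n_windows <- 0L
  n_flagged <- 0L
  for (id in ids) {
    res <- process_session(id, get_stream(id), get_manifest(id),
                           config$seg, config$accel_sd, config$verbose)
    tabs[[id]] <- res$measures
    n_windows <- n_windows + res$n_windows
    n_flagged <- n_flagged + res$n_flagged
  }
  measures <- do.call(rbind, tabs)
  rownames(measures) <- NULL
  excl <- exclusion_summary(n_flagged, n_windows)
  if (config$verbose) {
    message(sprintf("cohort: %d sessions, %d windows, excluded %s, %d rows analyzed",
                    length(ids), n_windows, excl$label, nrow(measures)))
  }
  report <- analyze_measures(measures, config$gate_alpha,
                             config$corrected_alpha, config$icc_forms,
                             config$accel_sd, exclusions = excl)
  attr(report, "measures") <- measures
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measures, file.path(config$outdir, "measures.csv"),
                     row.names = FALSE)
    for (fmt in c("csv", "json", "markdown")) {
      render_report(report, fmt, config$outdir)
    }
  }
  report
}

fmt_msd <- function(m, s) sprintf("%.2f (%.2f)", m, s)

#' Render a psychometric report
#'
#' Writes the reliability, omnibus and paired-comparison tables in the
#' requested format. The markdown rendering follows the usual footnote
#' conventions: `^` marks rows where the Friedman test (Kendall W) was used
#' instead of the repeated-measures ANOVA, `*` marks significance at the
#' corrected level.
#'
#' @param report A `psychometric_report`.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, format = c("csv", "json", "markdown"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(report, "psychometric_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    files <- file.path(dir, c("reliability.csv", "omnibus.csv", "paired.csv"))
    utils::write.csv(report$reliability, files[1L], row.names = FALSE)
    utils::write.csv(report$omnibus, files[2L], row.names = FALSE)
    utils::write.csv(report$paired, files[3L], row.names = FALSE)
    return(invisible(files))
  }
  if (format == "json") {
    file <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(reliability = report$reliability, omnibus = report$omnibus,
           paired = report$paired,
           exclusions = report$exclusions, options = report$options,
           version = report$version),
      file, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(file))
  }
  ## markdown
  file <- file.path(dir, "report.md")
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Psychometric report (wristrep %s)", report$version)
  if (!is.null(report$exclusions)) {
    w("\nExcluded trials: %s", report$exclusions$label)
  }
  w("\n## Within-session reliability (ICC, two-way mixed, absolute agreement)\n")
  w("| Task | Measure | Form | n | ICC | 95%% CI | Label |")
  w("|---|---|---|---|---|---|---|")
  r <- report$reliability
  for (i in seq_len(nrow(r))) {
    w("| %s | %s | %s | %d | %.2f | [%.2f, %.2f] | %s |",
      r$task[i], r$measure[i], r$form[i], r$n[i], r$icc[i],
      r$ci_lower[i], r$ci_upper[i], r$label[i])
  }
  w("\n## Repetition-count omnibus (5 vs 10 vs 20 comfortable)\n")
  w("| Task | Measure | n | 5 reps M (SD) | 10 reps M (SD) | 20 reps M (SD) | Statistic | Effect size |")
  w("|---|---|---|---|---|---|---|---|")
  o <- report$omnibus
  for (i in seq_len(nrow(o))) {
    fried <- isTRUE(o$test[i] == "friedman")
    w("| %s | %s | %d | %s | %s | %s | %.2f%s%s | %.2f%s |",
      o$task[i], o$measure[i], o$n[i],
      fmt_msd(o$mean_c5[i], o$sd_c5[i]), fmt_msd(o$mean_c10[i], o$sd_c10[i]),
      fmt_msd(o$mean_c20[i], o$sd_c20[i]),
      o$statistic[i], if (fried) " ^" else "",
      if (isTRUE(o$significant[i])) " *" else "",
      o$effect_size[i], if (fried) " ^" else "")
  }
  w("\nNote: `^` Friedman test with Kendall's W; `*` p < corrected alpha.")
  w("\n## Pace contrast (10 fast vs 10 comfortable)\n")
  w("| Task | Measure | n | Comfortable M (SD) | Fast M (SD) | Mean diff M (SD) | t | 95%% CI | d |")
  w("|---|---|---|---|---|---|---|---|---|")
  p <- report$paired
  for (i in seq_len(nrow(p))) {
    w("| %s | %s | %d | %s | %s | %s | %.2f%s | [%.2f, %.2f] | %.2f |",
      p$task[i], p$measure[i], p$n[i],
      fmt_msd(p$comfortable_mean[i], p$comfortable_sd[i]),
      fmt_msd(p$fast_mean[i], p$fast_sd[i]),
      fmt_msd(p$mean_diff[i], p$sd_diff[i]),
      p$t[i], if (isTRUE(p$significant[i])) " *" else "",
      p$ci_lower[i], p$ci_upper[i], p$cohens_d[i])
  }
  w("\nNote: `*` significant at the Bonferroni-corrected level (%.3f).",
    report$options$corrected_alpha)
  invisible(file)
}

#' Reference paired-comparison summaries
#'
#' Published summary statistics for the fast- versus comfortable-pace
#' contrast in the validation study that motivated these measures (25
#' healthy adults, four tasks, three measures): per task and measure, the
#' per-condition means and SDs, the mean difference with its SD, the sample
#' size, and the printed t statistic. The `exact_2dp` column marks the rows
#' whose printed t can be reproduced to two decimals from the printed
#' 2-decimal difference summaries (for the remaining rows the rounding of
#' small SDs moves the recomputed t beyond the last printed digit).
#'
#' @return A data frame with columns `task`, `measure`, `n`,
#'   `comfortable_mean`, `comfortable_sd`, `fast_mean`, `fast_sd`,
#'   `diff_mean`, `diff_sd`, `t_printed`, `exact_2dp`.
#' @export
reference_paired_summaries <- function() {
  path <- system.file("extdata", "reference_paired_summaries.csv",
                      package = "wristrep", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
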