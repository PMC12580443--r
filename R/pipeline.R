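#' Run the full analysis on in-memory recordings
#'
#' Pipeline order: derivatives -> pulse segmentation -> per-subject
#' selection and medians -> classification -> cohort statistics. Raw-unit
#' recordings are normalized first using the `mvc` column of `metadata`
#' (aborting with the subject's id if it is missing).
#'
#' @param recordings named list of [force_recording()] objects.
#' @param metadata data.frame with `subject_id`, `group`, optionally `mvc`.
#' @param window_ms slope window (ms).
#' @param rfd_threshold pulse threshold (%MVC/s).
#' @param lo,hi,k pulse selection parameters.
#' @param alpha significance level.
#' @param master_seed integer master seed for pulse selection.
#' @param overrides optional manual-override table or CSV path.
#' @return list with `pulse_table` (per-pulse rows, all subjects),
#'   `summaries` (subject-summary table), `report` (a `cohort_report`),
#'   and `config` (resolved parameters).
#' @export
analyze_recordings <- function(recordings, metadata, window_ms = 50,
                               rfd_threshold = 20, lo = 20, hi = 60, k = 41,
                               alpha = 0.05, master_seed = 1L,
                               overrides = NULL) {
  if (is.character(overrides)) {
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  }
  pulse_sets <- vector("list", length(recordings))
  tables <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    sid <- rec$subject_id
    if (!rec$normalized) {
      mvc <- metadata$mvc[match(sid, metadata$subject_id)]
      if (is.null(mvc) || length(mvc) != 1L || is.na(mvc)) {
        stop("recording_io: missing MVC for subject ", sid)
      }
      rec <- normalize_to_mvc(rec, mvc)
    }
    ps <- tryCatch(
      segment_pulses(rec, window_ms = window_ms,
                     rfd_threshold = rfd_threshold),
      error = function(e) stop("pulse_segmentation failed for subject ",
                               sid, ": ", conditionMessage(e)))
    if (!is.null(overrides)) ps <- apply_overrides(ps, overrides)
    pulse_sets[[i]] <- ps
    tables[[i]] <- as.data.frame(ps)
  }
  summaries <- summarize_cohort(pulse_sets, metadata, lo = lo, hi = hi,
                                k = k, master_seed = master_seed)
  report <- cohort_stats_report(summaries, alpha = alpha)
  list(pulse_table = do.call(rbind, tables), summaries = summaries,
       report = report,
       config = list(window_ms = window_ms, rfd_threshold = rfd_threshold,
                     amplitude_range = c(lo, hi), k = k, alpha = alpha,
                     master_seed = master_seed))
}

#' Analyze a cohort directory
#'
#' Disk-facing entry point: reads `metadata.csv` and one recording CSV per
#' subject (`<subject_id>.csv`, `time,force` layout, already in %MVC unless
#' `normalized = FALSE` and an `mvc` metadata column is provided) from
#' `input_dir`, runs [analyze_recordings()], and writes
#' `pulse_table.csv`, `subject_summaries.csv`, `stats_report.json`, the
#' resolved `config.json` and a `run_log.txt` into `output_dir`. Reruns
#' with the same inputs, parameters and master seed produce identical
#' numeric outputs.
#'
#' @inheritParams analyze_recordings
#' @param input_dir directory of recordings + metadata.
#' @param output_dir directory for result tables (created if needed).
#' @param normalized whether recording files are already in %MVC.
#' @return the [analyze_recordings()] result, invisibly.
#' @export
analyze_cohort <- function(input_dir, output_dir, window_ms = 50,
                           rfd_threshold = 20, lo = 20, hi = 60, k = 41,
                           alpha = 0.05, master_seed = 1L, overrides = NULL,
                           normalized = TRUE) {
  metadata <- read_subject_metadata(file.path(input_dir, "metadata.csv"))
  recordings <- lapply(metadata$subject_id, function(sid) {
    path <- file.path(input_dir, paste0(sid, ".csv"))
    if (!file.exists(path)) stop("recording_io: no recording file for subject ", sid)
    load_recording(path, subject_id = sid, normalized = normalized)
  })
  names(recordings) <- metadata$subject_id
  res <- analyze_recordings(recordings, metadata, window_ms = window_ms,
                            rfd_threshold = rfd_threshold, lo = lo, hi = hi,
                            k = k, alpha = alpha, master_seed = master_seed,
                            overrides = overrides)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$pulse_table, file.path(output_dir, "pulse_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summaries,
                   file.path(output_dir, "subject_summaries.csv"),
                   row.names = FALSE)
  write_report_json(res$report, file.path(output_dir, "stats_report.json"))
  jsonlite::write_json(res$config, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("forceseg %s", as.character(utils::packageVersion("forceseg"))),
               sprintf("R %s", getRversion()),
               sprintf("master_seed %d", master_seed),
               sprintf("subjects %d, pulses %d", nrow(res$summaries),
                       nrow(res$pulse_table)),
               sprintf("run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(output_dir, "run_log.txt"))
  invisible(res)
}

#' Recompute cohort statistics from a subject-summary table
#'
#' Accepts a subject-summary CSV (possibly hand-edited) or data.frame and
#' reruns only the inference layer. Required columns: `subject_id`,
#' `group_final` (or `group_raw` + `med_n_seg_f90`, from which the final
#' classification is recomputed).
#'
#' @param summaries data.frame or CSV path.
#' @param output_path optional JSON output path.
#' @param alpha significance level.
#' @return a `cohort_report`.
#' @export
stats_from_summaries <- function(summaries, output_path = NULL, alpha = 0.05) {
  if (is.character(summaries)) {
    summaries <- utils::read.csv(summaries, stringsAsFactors = FALSE)
  }
  if (!"group_final" %in% names(summaries)) {
    if (all(c("group_raw", "med_n_seg_f90") %in% names(summaries))) {
      summaries$group_final <- classify_segmentation(summaries)
    } else {
      stop("summary table missing columns: group_final (or group_raw + med_n_seg_f90)")
    }
  }
  if (!"subject_id" %in% names(summaries)) {
    stop("summary table missing columns: subject_id")
  }
  report <- cohort_stats_report(summaries, alpha = alpha)
  if (!is.null(output_path)) write_report_json(report, output_path)
  report
}
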