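#' Construct a force recording
#'
#' A `force_recording` holds one session's single-channel isometric force
#' series together with its sample rate, MVC (maximal voluntary contraction
#' force) and normalization state. Time is sample-indexed: sample `i`
#' (1-based in R) occurs at `(i - 1) / sample_rate` seconds from recording
#' start, which avoids floating-point time-grid drift.
#'
#' @param force numeric vector of force samples. Newtons when raw,
#'   %MVC once normalized.
#' @param sample_rate sampling rate in Hz (positive).
#' @param subject_id subject identifier.
#' @param mvc_force MVC in Newtons, or `NA` until known.
#' @param normalized logical; `TRUE` once force is expressed in %MVC.
#' @param session_label free-text session label.
#' @return An object of class `force_recording`.
#' @export
force_recording <- function(force, sample_rate, subject_id = "S1",
                            mvc_force = NA_real_, normalized = FALSE,
                            session_label = "") {
  force <- as.numeric(force)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  if (anyNA(force) || any(!is.finite(force))) {
    stop("force samples must all be finite")
  }
  if (isTRUE(normalized) && length(force) &&
      (min(force) < -20 || max(force) > 150)) {
    stop("normalized force outside [-20, 150] %MVC: corrupt input?")
  }
  structure(
    list(force = force, sample_rate = sample_rate,
         subject_id = as.character(subject_id),
         mvc_force = as.numeric(mvc_force),
         normalized = isTRUE(normalized),
         session_label = as.character(session_label)),
    class = "force_recording"
  )
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> subject %s%s\n", x$subject_id,
              if (nzchar(x$session_label)) paste0(" [", x$session_label, "]") else ""))
  cat(sprintf("  %d samples at %g Hz (%.2f s), units %s\n",
              length(x$force), x$sample_rate,
              length(x$force) / x$sample_rate,
              if (x$normalized) "%MVC" else "N"))
  if (is.finite(x$mvc_force)) cat(sprintf("  MVC = %g N\n", x$mvc_force))
  invisible(x)
}

#' Load a force recording from a delimited text file
#'
#' Accepts comma- or tab-delimited files, with or without a header row, in
#' two layouts: (time, force) columns, where the sample rate is inferred
#' from the (required near-constant) time spacing; or a single force column
#' with the sample rate supplied via `sample_rate`. Decimal points only.
#'
#' @param path file path.
#' @param sample_rate sampling rate in Hz; required for force-only files,
#'   checked against the time column (1% jitter tolerance) if both given.
#' @param time_col,force_col column names or indices; by default a file
#'   with >= 2 columns is treated as (time, force) using the first two.
#' @param subject_id,session_label metadata carried on the recording.
#' @param mvc_force optional MVC in Newtons.
#' @param normalized set `TRUE` when re-loading an already-normalized file.
#' @return A [force_recording()].
#' @export
load_recording <- function(path, sample_rate = NULL,
                           time_col = NULL, force_col = NULL,
                           subject_id = "S1", session_label = "",
                           mvc_force = NA_real_, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !grepl("^[-+0-9.eE \t,]+$", first)
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           colClasses = "character",
                           strip.white = TRUE, comment.char = "")
  pick <- function(col, default) {
    if (is.null(col)) return(default)
    if (is.character(col)) {
      j <- match(col, names(raw))
      if (is.na(j)) stop("column not found: ", col)
      j
    } else as.integer(col)
  }
  two_col <- ncol(raw) >= 2L || !is.null(time_col)
  as_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      stop(sprintf("non-numeric %s value at data row %d: '%s'",
                   what, bad[1L], x[bad[1L]]))
    }
    v
  }
  if (two_col && ncol(raw) >= 2L) {
    ti <- pick(time_col, 1L); fi <- pick(force_col, 2L)
    tv <- as_num(raw[[ti]], "time")
    fv <- as_num(raw[[fi]], "force")
    dt <- diff(tv)
    if (length(dt) < 1L) stop("need at least 2 samples to infer sample rate")
    mdt <- stats::median(dt)
    if (mdt <= 0 || any(abs(dt - mdt) > 0.01 * mdt)) {
      stop("nonuniform time grid (beyond 1% jitter tolerance)")
    }
    fs_inferred <- 1 / mdt
    if (!is.null(sample_rate) &&
        abs(fs_inferred - sample_rate) > 0.01 * sample_rate) {
      stop(sprintf("declared sample rate %g Hz disagrees with time column (%g Hz)",
                   sample_rate, fs_inferred))
    }
    fs <- if (is.null(sample_rate)) fs_inferred else sample_rate
  } else {
    if (is.null(sample_rate)) {
      stop("force-only file: sample_rate must be supplied")
    }
    fi <- pick(force_col, 1L)
    fv <- as_num(raw[[fi]], "force")
    fs <- sample_rate
  }
  force_recording(fv, fs, subject_id = subject_id, mvc_force = mvc_force,
                  normalized = normalized, session_label = session_label)
}

#' Write a force recording as CSV
#'
#' Emits a two-column `time,force` CSV (time in seconds on the sample grid)
#' that [load_recording()] reads back.
#'
#' @param rec a [force_recording()].
#' @param path output path.
#' @param digits significant digits written (enough for a 1e-9 round trip).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 15L) {
  stopifnot(inherits(rec, "force_recording"))
  n <- length(rec$force)
  tt <- (seq_len(n) - 1L) / rec$sample_rate
  df <- data.frame(time = format(tt, digits = digits, trim = TRUE,
                                 scientific = FALSE),
                   force = format(rec$force, digits = digits, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pick the best MVC from repeated trials
#'
#' MVC trials are repeated; the greatest per-trial peak force is used as
#' the normalization denominator for the whole session.
#'
#' @param trial_forces numeric vector of per-trial peak forces (N).
#' @return the maximum, a single number in N.
#' @export
best_mvc <- function(trial_forces) {
  trial_forces <- as.numeric(trial_forces)
  if (length(trial_forces) == 0L) stop("no MVC trials supplied")
  if (any(!is.finite(trial_forces)) || any(trial_forces <= 0)) {
    stop("MVC trial forces must be finite and positive")
  }
  max(trial_forces)
}

#' Normalize a recording to %MVC
#'
#' Maps each raw force sample F (N) to 100 * F / mvc (%MVC). All downstream
#' analysis (derivatives, pulse detection, segmentation) requires normalized
#' recordings; operations on raw-unit recordings refuse rather than rescale
#' silently.
#'
#' @param rec a raw-unit [force_recording()].
#' @param mvc MVC in Newtons (> 0).
#' @return the normalized recording with `mvc_force` stored.
#' @export
normalize_to_mvc <- function(rec, mvc) {
  stopifnot(inherits(rec, "force_recording"))
  if (rec$normalized) stop("recording is already normalized")
  if (!is.numeric(mvc) || length(mvc) != 1L || !is.finite(mvc) || mvc <= 0) {
    stop("mvc must be a single positive number")
  }
  force_recording(100 * rec$force / mvc, rec$sample_rate,
                  subject_id = rec$subject_id, mvc_force = mvc,
                  normalized = TRUE, session_label = rec$session_label)
}

#' Read a subject metadata table
#'
#' One row per subject: `subject_id`, `group` (OA or PD; the PD_Seg /
#' PD_NoSeg split is assigned downstream from the force data), and any
#' clinical covariate columns (carried through, never computed). Covariate
#' values must be finite where present; an `hy_stage` column, if present,
#' must lie in [0, 5].
#'
#' @param path CSV path.
#' @return a data.frame with character `subject_id` and factor-free `group`.
#' @export
read_subject_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (!all(df$group %in% c("OA", "PD"))) {
    stop("group must be 'OA' or 'PD' (subgroups are assigned downstream)")
  }
  cov_cols <- setdiff(names(df), need)
  for (cc in cov_cols) {
    v <- df[[cc]]
    if (is.numeric(v) && any(!is.finite(v) & !is.na(v))) {
      stop("non-finite covariate in column ", cc)
    }
  }
  if ("hy_stage" %in% names(df)) {
    hs <- df$hy_stage
    if (any(!is.na(hs) & (hs < 0 | hs > 5))) stop("hy_stage outside [0, 5]")
  }
  df
}
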