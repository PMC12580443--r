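#' Per-subject selection seed derived from a master seed
#'
#' One master seed drives the whole analysis; each subject's pulse
#' selection uses a seed derived by a stable string hash of the subject id,
#' so results do not depend on the order subjects are processed. The hash
#' is a 31-multiplier polynomial over the id's bytes, reduced modulo
#' 2^31 - 1.
#'
#' @param master_seed integer master seed.
#' @param subject_id subject identifier.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(master_seed, subject_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (b in utf8ToInt(as.character(subject_id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Randomly select analysis pulses within an amplitude range
#'
#' Eligible pulses have peak force between `lo` and `hi` %MVC (inclusive)
#' and are neither QC-flagged nor dropped by override. If at least `k` are
#' eligible, `k` are drawn uniformly without replacement with the supplied
#' seed (selection operates on pulses in onset order, so it is invariant to
#' how pulses were stored); otherwise all eligible pulses are returned with
#' a warning. An odd `k` keeps medians of integer segment counts integral.
#'
#' @param ps a `pulse_set` (see [segment_pulses()]).
#' @param lo,hi eligibility bounds on peak force, %MVC.
#' @param k number of pulses to select.
#' @param seed integer selection seed (see [subject_seed()]).
#' @return the `pulse_set` with a logical `selected` column added and
#'   attributes `n_eligible`, `n_used`, `selection_seed` on the table.
#' @export
select_pulses <- function(ps, lo = 20, hi = 60, k = 41, seed) {
  stopifnot(inherits(ps, "pulse_set"))
  if (missing(seed)) stop("a selection seed is required")
  if (k %% 2L == 0L) {
    warning("even k: medians of integer segment counts can be half-integral")
  }
  p <- ps$pulses
  elig <- p$peak_force >= lo & p$peak_force <= hi &
    !p$dropped & !p$qc_merged & !p$qc_onset_ambiguous
  n_elig <- sum(elig)
  if (n_elig == 0L) {
    stop("no eligible pulses for subject ", ps$subject_id)
  }
  idx <- which(elig)[order(p$onset_idx[elig])]
  if (n_elig >= k) {
    chosen <- with_seed(seed, sort(sample(idx, k)))
  } else {
    warning(sprintf("subject %s: only %d eligible pulses (< %d); using all",
                    ps$subject_id, n_elig, k))
    chosen <- idx
  }
  p$selected <- FALSE
  p$selected[chosen] <- TRUE
  attr(p, "n_eligible") <- n_elig
  attr(p, "n_used") <- length(chosen)
  attr(p, "selection_seed") <- as.integer(seed)
  ps$pulses <- p
  ps
}

#' Summarize one subject's selected pulses
#'
#' Computes per-subject medians of each per-pulse metric over the selected
#' pulses (standard median: even counts average the two central values),
#' the percentage of pulses with >= 2 segments to F90, and per-ordinal
#' median segment/slowing durations (ordinal j uses only pulses that have
#' a j-th segment or slowing period, so n shrinks with j).
#'
#' @param ps a `pulse_set` after [select_pulses()].
#' @param group_raw subject group, `"OA"` or `"PD"`.
#' @return one-row data.frame (a subject summary).
#' @export
summarize_subject <- function(ps, group_raw = c("PD", "OA")) {
  group_raw <- match.arg(group_raw)
  stopifnot(inherits(ps, "pulse_set"))
  if (is.null(ps$pulses$selected)) stop("run select_pulses() first")
  wide <- as.data.frame(ps, max_ordinal = 5L)
  wide <- wide[ps$pulses$selected, , drop = FALSE]
  if (nrow(wide) == 0L) stop("no selected pulses for subject ", ps$subject_id)
  med <- function(v) stats::median(v[is.finite(v)])
  out <- data.frame(
    subject_id = ps$subject_id,
    group_raw = group_raw,
    n_eligible = attr(ps$pulses, "n_eligible"),
    n_used = nrow(wide),
    selection_seed = attr(ps$pulses, "selection_seed"),
    med_n_seg_f90 = med(wide$n_seg_f90),
    med_n_seg_peak = med(wide$n_seg_peak),
    med_peak_force = med(wide$peak_force),
    med_t_pf = med(wide$t_pf),
    med_t_f90 = med(wide$t_f90),
    med_rfd_pk = med(wide$rfd_pk),
    med_t_rfd_pk = med(wide$t_rfd_pk),
    med_rfd_pk_seg1 = med(wide$rfd_pk_seg1),
    med_seg_of_rfd_pk = med(wide$seg_of_rfd_pk),
    med_first_seg_dur = med(wide$seg1),
    pct_multiseg = 100 * mean(wide$n_seg_f90 >= 2),
    stringsAsFactors = FALSE
  )
  for (j in 1:5) {
    v <- wide[[paste0("seg", j)]]
    out[[paste0("med_seg_dur", j)]] <- if (any(is.finite(v))) med(v) else NA_real_
    v <- wide[[paste0("slow", j)]]
    out[[paste0("med_slow_dur", j)]] <- if (any(is.finite(v))) med(v) else NA_real_
  }
  out$group_final <- classify_segmentation(out)
  out
}

#' Classify a subject's segmentation status
#'
#' PD subjects whose median number of segments to F90 is at least 2 are
#' classified `PD_Seg` (inclusive threshold); other PD subjects are
#' `PD_NoSeg`; OA subjects keep their label.
#'
#' @param summary a subject summary row with `group_raw` and
#'   `med_n_seg_f90`.
#' @return `"PD_Seg"`, `"PD_NoSeg"` or `"OA"`.
#' @export
classify_segmentation <- function(summary) {
  ifelse(summary$group_raw == "OA", "OA",
         ifelse(summary$med_n_seg_f90 >= 2, "PD_Seg", "PD_NoSeg"))
}

#' Summarize a whole cohort of segmented recordings
#'
#' Runs [select_pulses()] (with per-subject seeds derived from the master
#' seed) and [summarize_subject()] for every subject, returning the cohort
#' subject-summary table used by the inference layer.
#'
#' @param pulse_sets named list of `pulse_set` objects (names = subject ids,
#'   or taken from the objects).
#' @param metadata data.frame with `subject_id` and `group` (`OA`/`PD`).
#' @param lo,hi,k selection parameters (see [select_pulses()]).
#' @param master_seed integer master seed.
#' @return data.frame with one row per subject.
#' @export
summarize_cohort <- function(pulse_sets, metadata, lo = 20, hi = 60, k = 41,
                             master_seed = 1L) {
  rows <- lapply(pulse_sets, function(ps) {
    g <- metadata$group[match(ps$subject_id, metadata$subject_id)]
    if (is.na(g)) stop("subject ", ps$subject_id, " missing from metadata")
    sel <- select_pulses(ps, lo = lo, hi = hi, k = k,
                         seed = subject_seed(master_seed, ps$subject_id))
    summarize_subject(sel, group_raw = g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
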