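#' Detect rapid force pulses by RFD threshold
#'
#' Candidate peaks are local force maxima of at least `min_peak` %MVC,
#' separated by at least `min_separation` seconds (taller peaks suppress
#' smaller neighbours). For each peak the pulse onset is found by scanning
#' backward from the peak for the last sample at which the RFD is below
#' `rfd_threshold` *and* force is near baseline (at most `onset_force_max`
#' %MVC); the onset is the sample immediately after it. The near-baseline
#' guard matters for segmented pulses, whose RFD can dip below threshold
#' during slowing periods while force is still high. The offset is found by
#' scanning forward from the peak: once the RFD has gone below
#' `-rfd_threshold` (relaxation under way), the offset is the sample
#' immediately before the first sample at which it rises back above
#' `-rfd_threshold`. Pulses whose searches collide with a neighbouring
#' pulse or run off the recording are flagged.
#'
#' @param rec a normalized [force_recording()].
#' @param deriv the matching [compute_derivatives()] result.
#' @param rfd_threshold pulse start/end RFD threshold, %MVC/s.
#' @param min_peak minimum candidate peak height, %MVC.
#' @param min_separation minimum peak separation, s.
#' @param onset_force_max force ceiling (in %MVC) for a sample to count as
#'   pre-onset baseline during the backward onset scan.
#' @return data.frame with one row per pulse: `onset_idx`, `peak_idx`,
#'   `offset_idx` (1-based sample indices), `peak_force`, `t_pf`, `t_f90`,
#'   `f90_idx`, and logical QC columns `qc_merged`, `qc_onset_ambiguous`.
#' @export
detect_pulses <- function(rec, deriv, rfd_threshold = 20, min_peak = 10,
                          min_separation = 1.0, onset_force_max = 10) {
  stopifnot(inherits(rec, "force_recording"), inherits(deriv, "deriv_set"))
  if (!rec$normalized) stop("recording must be normalized to %MVC")
  if (deriv$n != length(rec$force)) stop("derivative set does not match recording")
  f <- rec$force; rfd <- deriv$rfd; fs <- rec$sample_rate
  n <- length(f)
  empty <- data.frame(onset_idx = integer(0), peak_idx = integer(0),
                      offset_idx = integer(0), peak_force = numeric(0),
                      t_pf = numeric(0), t_f90 = numeric(0),
                      f90_idx = integer(0), qc_merged = logical(0),
                      qc_onset_ambiguous = logical(0))
  if (n < 3L) return(empty)
  d <- diff(f)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[f[cand] >= min_peak]
  if (!length(cand)) return(empty)
  # non-maximum suppression within min_separation
  sep <- as.integer(round(min_separation * fs))
  keep <- logical(length(cand))
  for (j in order(f[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < sep)) keep[j] <- TRUE
  }
  peaks <- sort(cand[keep])
  m <- length(peaks)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    pk <- peaks[j]
    lo <- if (j > 1L) peaks[j - 1L] + 1L else 1L
    hi <- if (j < m) peaks[j + 1L] - 1L else n
    merged <- FALSE; ambiguous <- FALSE
    # backward onset scan
    onset <- NA_integer_
    i <- pk - 1L
    while (i >= lo) {
      if (rfd[i] < rfd_threshold && f[i] <= onset_force_max) {
        onset <- i + 1L; break
      }
      i <- i - 1L
    }
    if (is.na(onset)) {
      onset <- lo
      ambiguous <- TRUE
      if (j > 1L) merged <- TRUE
    }
    # forward offset scan
    offset <- NA_integer_
    armed <- FALSE
    i <- pk + 1L
    while (i <= hi) {
      if (!armed) {
        if (rfd[i] < -rfd_threshold) armed <- TRUE
      } else if (rfd[i] > -rfd_threshold) {
        offset <- i - 1L; break
      }
      i <- i + 1L
    }
    if (is.na(offset)) {
      offset <- hi
      if (j < m) merged <- TRUE
    }
    pf <- f[pk]
    f90_idx <- onset - 1L + which(f[onset:pk] >= 0.9 * pf)[1L]
    out[[j]] <- data.frame(onset_idx = onset, peak_idx = pk,
                           offset_idx = offset, peak_force = pf,
                           t_pf = (pk - onset) / fs,
                           t_f90 = (f90_idx - onset) / fs,
                           f90_idx = f90_idx,
                           qc_merged = merged, qc_onset_ambiguous = ambiguous)
  }
  do.call(rbind, out)
}

#' Time from force initiation to 90% of peak force
#'
#' `t_F90 = (j - onset) / fs` where `j` is the first sample in
#' `[onset, peak]` whose force reaches 90% of the pulse's peak force. No
#' interpolation: at 200 Hz the worst-case bias (5 ms) is small against the
#' reported group differences, and the sample rule is deterministic.
#'
#' @param rec a normalized [force_recording()].
#' @param pulse one row of the [detect_pulses()] table (list or data.frame row).
#' @return time in seconds.
#' @export
time_to_f90 <- function(rec, pulse) {
  f <- rec$force
  on <- pulse$onset_idx; pk <- pulse$peak_idx
  j <- on - 1L + which(f[on:pk] >= 0.9 * f[pk])[1L]
  (j - on) / rec$sample_rate
}

#' Count strict sign changes of F''(t) on an interval
#'
#' Counts sign changes between consecutive non-zero-sign samples of `f2` on
#' the closed index interval `[a, b]`; samples exactly zero inherit the
#' previous non-zero sign (so plateaus at zero are bridged, never
#' double-counted). Each crossing's position is recorded as the index of
#' the first sample carrying the new sign.
#'
#' @param f2 numeric vector (second derivative of force).
#' @param interval integer length-2 vector `c(a, b)`, 1-based, `a < b`.
#' @return list with `count` and integer `positions`.
#' @export
zero_crossings <- function(f2, interval) {
  a <- as.integer(interval[1L]); b <- as.integer(interval[2L])
  if (a < 1L || b > length(f2) || a >= b) {
    stop("interval must satisfy 1 <= a < b <= length(f2)")
  }
  s <- sign(f2[a:b])
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(count = 0L, positions = integer(0)))
  ss <- s[nz]
  ch <- which(ss[-1L] != ss[-length(ss)])
  list(count = length(ch), positions = a - 1L + nz[ch + 1L])
}

#' Number of force segments from a zero-crossing count
#'
#' Segments are counted as `(zero crossings + 1) / 2`, rounded up: an even
#' crossing count means the interval ends mid-acceleration, and the segment
#' in progress at the right edge still counts (the segment delivering F90
#' must be counted when the interval is onset-to-F90).
#'
#' @param n_zc non-negative crossing count.
#' @return integer segment count (>= 1).
#' @export
segment_count <- function(n_zc) {
  if (any(n_zc < 0)) stop("crossing count must be non-negative")
  as.integer(ceiling((n_zc + 1) / 2))
}

#' Segment and slowing-period boundaries from F''(t)
#'
#' With pre-peak crossings z1 < z2 < ...: segment 1 runs from the pulse
#' onset to the minimum of F'' between z1 and z2; segment k (k >= 2) runs
#' from the maximum of F'' between z(2k-2) and z(2k-1) to the minimum
#' between z(2k-1) and z(2k). A missing right bound is replaced by the peak
#' sample, and a final in-progress segment whose closing crossing never
#' arrives ends at the peak. Slowing periods are the gaps between
#' consecutive segments, so segments and slowing periods interleave and
#' exactly tile [first segment start, last segment end].
#'
#' @param f2 second-derivative series.
#' @param pulse one detected pulse (row of [detect_pulses()] table).
#' @param crossings result of [zero_crossings()] on `[onset_idx, peak_idx]`.
#' @param sample_rate Hz, for durations.
#' @return list with integer matrices `segments`, `slowing` (columns
#'   `start`, `end`), and numeric `segment_durations`, `slowing_durations`
#'   in seconds.
#' @export
extract_boundaries <- function(f2, pulse, crossings, sample_rate) {
  on <- pulse$onset_idx; pk <- pulse$peak_idx
  z <- crossings$positions
  m <- length(z)
  n_seg <- segment_count(m)
  seg <- matrix(NA_integer_, nrow = n_seg, ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  argmin_on <- function(a, b) a - 1L + which.min(f2[a:b])
  argmax_on <- function(a, b) a - 1L + which.max(f2[a:b])
  for (k in seq_len(n_seg)) {
    if (k == 1L) {
      start <- on
    } else {
      a <- z[2L * k - 2L]
      b <- if (2L * k - 1L <= m) z[2L * k - 1L] else pk
      start <- argmax_on(a, b)
    }
    if (2L * k - 1L <= m) {
      a <- z[2L * k - 1L]
      b <- if (2L * k <= m) z[2L * k] else pk
      end <- argmin_on(a, b)
    } else {
      end <- pk  # in-progress segment: still accelerating at the peak
    }
    seg[k, ] <- c(start, end)
  }
  if (n_seg > 1L) {
    slow <- cbind(start = seg[-n_seg, "end"], end = seg[-1L, "start"])
  } else {
    slow <- matrix(integer(0), nrow = 0L, ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  }
  list(segments = seg, slowing = slow,
       segment_durations = (seg[, "end"] - seg[, "start"]) / sample_rate,
       slowing_durations = if (nrow(slow)) (slow[, "end"] - slow[, "start"]) / sample_rate else numeric(0))
}

#' Per-pulse RFD metrics
#'
#' Completes a pulse's segmentation profile with the peak RFD over the
#' rising phase, its latency from onset (earliest sample on ties), the peak
#' RFD within the first segment, and the ordinal of the segment containing
#' the RFD peak. If the RFD peak falls inside a slowing period it is
#' assigned to the nearer adjacent segment (earlier one on an exact tie).
#'
#' @param rec normalized recording.
#' @param deriv matching derivative set.
#' @param pulse one detected pulse.
#' @param bounds result of [extract_boundaries()].
#' @return list with `rfd_pk`, `t_rfd_pk`, `rfd_pk_seg1`, `seg_of_rfd_pk`.
#' @export
pulse_metrics <- function(rec, deriv, pulse, bounds) {
  rfd <- deriv$rfd; fs <- rec$sample_rate
  on <- pulse$onset_idx; pk <- pulse$peak_idx
  arg <- on - 1L + which.max(rfd[on:pk])
  seg <- bounds$segments
  seg1 <- seg[1L, ]
  in_seg <- which(arg >= seg[, "start"] & arg <= seg[, "end"])
  if (length(in_seg)) {
    seg_of <- in_seg[1L]
  } else {
    # inside a slowing period: nearer adjacent segment, earlier on tie
    prev <- max(which(seg[, "end"] < arg))
    d_prev <- arg - seg[prev, "end"]
    d_next <- seg[prev + 1L, "start"] - arg
    seg_of <- if (d_prev <= d_next) prev else prev + 1L
  }
  list(rfd_pk = rfd[arg],
       t_rfd_pk = (arg - on) / fs,
       rfd_pk_seg1 = max(rfd[seg1["start"]:seg1["end"]]),
       seg_of_rfd_pk = as.integer(seg_of))
}

#' Segment every pulse in a recording
#'
#' Runs the full per-recording pipeline: pulse detection, zero-crossing
#' counts to F90 and to peak force, segment counts, segment/slowing-period
#' boundaries and per-pulse RFD metrics. Returns a classed object with
#' print, summary, plot and as.data.frame methods.
#'
#' @param rec a normalized [force_recording()].
#' @param deriv optional precomputed [compute_derivatives()] result.
#' @param window_ms slope window if derivatives are computed here.
#' @inheritParams detect_pulses
#' @return An object of class `pulse_set`: list with `pulses` (per-pulse
#'   metric table), `boundaries` (per-pulse segment/slowing intervals),
#'   `subject_id`, `sample_rate`, `params`, and the `recording`/`deriv`
#'   used (for plotting).
#' @export
segment_pulses <- function(rec, deriv = NULL, window_ms = 50,
                           rfd_threshold = 20, min_peak = 10,
                           min_separation = 1.0, onset_force_max = 10) {
  stopifnot(inherits(rec, "force_recording"))
  if (is.null(deriv)) deriv <- compute_derivatives(rec, window_ms)
  det <- detect_pulses(rec, deriv, rfd_threshold = rfd_threshold,
                       min_peak = min_peak, min_separation = min_separation,
                       onset_force_max = onset_force_max)
  np <- nrow(det)
  bounds <- vector("list", np)
  extra <- vector("list", np)
  for (i in seq_len(np)) {
    p <- det[i, ]
    zc_pk <- zero_crossings(deriv$f2, c(p$onset_idx, p$peak_idx))
    zc_f90 <- if (p$f90_idx > p$onset_idx) {
      zero_crossings(deriv$f2, c(p$onset_idx, p$f90_idx))
    } else list(count = 0L, positions = integer(0))
    b <- extract_boundaries(deriv$f2, p, zc_pk, rec$sample_rate)
    met <- pulse_metrics(rec, deriv, p, b)
    bounds[[i]] <- b
    extra[[i]] <- data.frame(
      zc_to_f90 = zc_f90$count, zc_to_peak = zc_pk$count,
      n_seg_f90 = segment_count(zc_f90$count),
      n_seg_peak = segment_count(zc_pk$count),
      rfd_pk = met$rfd_pk, t_rfd_pk = met$t_rfd_pk,
      rfd_pk_seg1 = met$rfd_pk_seg1, seg_of_rfd_pk = met$seg_of_rfd_pk,
      first_seg_dur = b$segment_durations[1L])
  }
  pulses <- if (np) cbind(pulse = seq_len(np), det, do.call(rbind, extra))
            else cbind(det, data.frame(pulse = integer(0)))
  pulses$dropped <- rep(FALSE, np)
  pulses$drop_reason <- rep(NA_character_, np)
  structure(
    list(pulses = pulses, boundaries = bounds,
         subject_id = rec$subject_id, sample_rate = rec$sample_rate,
         params = list(window_ms = window_ms, rfd_threshold = rfd_threshold,
                       min_peak = min_peak, min_separation = min_separation,
                       onset_force_max = onset_force_max),
         recording = rec, deriv = deriv),
    class = "pulse_set"
  )
}

#' @export
print.pulse_set <- function(x, ...) {
  p <- x$pulses
  cat(sprintf("<pulse_set> subject %s: %d pulses at %g Hz\n",
              x$subject_id, nrow(p), x$sample_rate))
  if (nrow(p)) {
    cat(sprintf("  peak force %.1f-%.1f %%MVC; segments to F90: %s\n",
                min(p$peak_force), max(p$peak_force),
                paste(names(table(p$n_seg_f90)),
                      table(p$n_seg_f90), sep = "x", collapse = ", ")))
    if (any(p$qc_merged | p$qc_onset_ambiguous)) {
      cat(sprintf("  QC flags: %d merged, %d ambiguous onset\n",
                  sum(p$qc_merged), sum(p$qc_onset_ambiguous)))
    }
  }
  invisible(x)
}

#' @export
summary.pulse_set <- function(object, ...) {
  p <- object$pulses
  out <- list(subject_id = object$subject_id, n_pulses = nrow(p),
              median_n_seg_f90 = stats::median(p$n_seg_f90),
              median_t_pf = stats::median(p$t_pf),
              median_rfd_pk = stats::median(p$rfd_pk),
              pct_multiseg = if (nrow(p)) 100 * mean(p$n_seg_f90 >= 2) else NA_real_)
  class(out) <- "summary.pulse_set"
  out
}

#' @export
print.summary.pulse_set <- function(x, ...) {
  cat(sprintf("subject %s: %d pulses, median segments to F90 = %g, %.0f%% multi-segment\n",
              x$subject_id, x$n_pulses, x$median_n_seg_f90, x$pct_multiseg))
  cat(sprintf("  median t_PF %.3f s, median peak RFD %.0f %%MVC/s\n",
              x$median_t_pf, x$median_rfd_pk))
  invisible(x)
}

#' Per-pulse table with wide duration columns
#'
#' @param x a `pulse_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @param max_ordinal number of per-ordinal duration columns to emit.
#' @return data.frame: one row per pulse with metrics plus `seg1..segK` and
#'   `slow1..slowK-1` duration columns (seconds; NA where the pulse lacks
#'   that ordinal).
#' @export
as.data.frame.pulse_set <- function(x, row.names = NULL, optional = FALSE,
                                    max_ordinal = 5L, ...) {
  p <- x$pulses
  fs <- x$sample_rate
  df <- data.frame(subject_id = rep(x$subject_id, nrow(p)), p[, setdiff(names(p), "f90_idx")],
                   onset_time = (p$onset_idx - 1L) / fs)
  for (j in seq_len(max_ordinal)) {
    df[[paste0("seg", j)]] <- vapply(x$boundaries, function(b) {
      d <- b$segment_durations
      if (length(d) >= j) d[j] else NA_real_
    }, numeric(1))
  }
  for (j in seq_len(max_ordinal)) {
    df[[paste0("slow", j)]] <- vapply(x$boundaries, function(b) {
      d <- b$slowing_durations
      if (length(d) >= j) d[j] else NA_real_
    }, numeric(1))
  }
  df
}

#' Plot a pulse with shaded segments
#'
#' Draws the force trace of one pulse with segments shaded and slowing
#' periods left blank, over panels of force, RFD and F''(t).
#'
#' @param x a `pulse_set`.
#' @param pulse which pulse to draw.
#' @param pad_s seconds of context either side.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pulse_set <- function(x, pulse = 1L, pad_s = 0.25, ...) {
  p <- x$pulses[pulse, ]
  b <- x$boundaries[[pulse]]
  fs <- x$sample_rate
  a <- max(1L, p$onset_idx - as.integer(pad_s * fs))
  z <- min(length(x$recording$force), p$offset_idx + as.integer(pad_s * fs))
  idx <- a:z
  tt <- (idx - 1L) / fs
  old <- graphics::par(mfrow = c(3, 1), mar = c(3.2, 4, 1, 1))
  on.exit(graphics::par(old))
  f <- x$recording$force
  graphics::plot(tt, f[idx], type = "l", xlab = "", ylab = "force (%MVC)", ...)
  for (k in seq_len(nrow(b$segments))) {
    graphics::rect((b$segments[k, 1L] - 1L) / fs, min(f[idx]),
                   (b$segments[k, 2L] - 1L) / fs, max(f[idx]),
                   col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  }
  graphics::abline(v = (p$peak_idx - 1L) / fs, lty = 3)
  graphics::plot(tt, x$deriv$rfd[idx], type = "l", xlab = "", ylab = "RFD (%MVC/s)")
  graphics::abline(h = 0, col = "grey")
  graphics::plot(tt, x$deriv$f2[idx], type = "l", xlab = "time (s)",
                 ylab = "F″ (%MVC/s²)")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Apply a manual pulse override file
#'
#' The override table (CSV with columns `subject_id`, `pulse`, `action`
#' (`keep` or `drop`), optional `note`) stands in for investigator visual
#' confirmation: `drop` removes a pulse from eligibility; `keep` rescinds a
#' programmatic QC flag.
#'
#' @param ps a `pulse_set`.
#' @param overrides data.frame or CSV path.
#' @return the `pulse_set` with `dropped`/`drop_reason` updated.
#' @export
apply_overrides <- function(ps, overrides) {
  stopifnot(inherits(ps, "pulse_set"))
  if (is.character(overrides)) overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  need <- c("subject_id", "pulse", "action")
  if (!all(need %in% names(overrides))) {
    stop("override table needs columns: ", paste(need, collapse = ", "))
  }
  ov <- overrides[overrides$subject_id == ps$subject_id, , drop = FALSE]
  for (i in seq_len(nrow(ov))) {
    j <- match(ov$pulse[i], ps$pulses$pulse)
    if (is.na(j)) next
    if (ov$action[i] == "drop") {
      ps$pulses$dropped[j] <- TRUE
      ps$pulses$drop_reason[j] <- if ("note" %in% names(ov) && nzchar(ov$note[i])) ov$note[i] else "manual override"
    } else if (ov$action[i] == "keep") {
      ps$pulses$dropped[j] <- FALSE
      ps$pulses$qc_merged[j] <- FALSE
      ps$pulses$qc_onset_ambiguous[j] <- FALSE
      ps$pulses$drop_reason[j] <- NA_character_
    }
  }
  ps
}
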