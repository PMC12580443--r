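#' Simulator configuration
#'
#' Study conditions for the synthetic burst-drive force simulator:
#' 200 Hz sampling with a 50 Hz forward-backward low-pass (the acquisition
#' chain), pulse peaks near 40 %MVC (SD 3.5), cue spacing 3-5 s, and
#' archetype-dependent burst structure. Burst (segment) duration means are
#' 86 / 65 / 52.5 ms for the first, second and later bursts, and
#' inter-burst gap (slowing period) means 80 / 60 / 50 ms, with the
#' coefficients of variation reported for segmented Parkinson's pulses
#' (about 16-26%); draws are truncated at +/- 3 SD so times stay positive.
#' The neural drive sets the *rate* of force: force is the running integral
#' of the burst train convolved with a critically damped twitch kernel
#' (time constant `twitch_tau`), which makes force plateau between bursts
#' rather than decay. White Gaussian noise (`noise_sd` %MVC) is added after
#' filtering.
#'
#' @param sample_rate Hz.
#' @param lowpass_hz acquisition low-pass corner.
#' @param twitch_tau twitch kernel time constant, s.
#' @param noise_sd additive noise SD, %MVC.
#' @param ipi_range inter-pulse-interval range, s.
#' @param peak_mean,peak_sd pulse target peak distribution, %MVC.
#' @param burst_dur_means,burst_dur_cvs per-ordinal burst duration means
#'   (s) and CVs; the last entry recycles for later ordinals.
#' @param gap_means,gap_cvs per-ordinal gap means (s) and CVs.
#' @param later_amp_mean,later_amp_sd drive amplitude of bursts after the
#'   first, relative to the first burst.
#' @param multi_prob per-archetype probability that a pulse is multi-burst;
#'   for `PD_Seg` a per-subject value is drawn from `seg_multi_range`.
#' @param seg_multi_range range of per-subject multi-burst probability for
#'   the PD_Seg archetype.
#' @param burst_count_probs probabilities of 2, 3, 4, 5, 6 bursts given
#'   multi-burst (up to six bursts, so 5th-ordinal segment and slowing
#'   durations occur as they do in segmented patients).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 200, lowpass_hz = 50, twitch_tau = 0.025,
                       noise_sd = 0.3, ipi_range = c(3, 5),
                       peak_mean = 40, peak_sd = 3.5,
                       burst_dur_means = c(0.086, 0.065, 0.0525),
                       burst_dur_cvs = c(0.255, 0.185, 0.16),
                       gap_means = c(0.080, 0.060, 0.050),
                       gap_cvs = c(0.199, 0.216, 0.22),
                       later_amp_mean = 1.3, later_amp_sd = 0.3,
                       multi_prob = c(OA = 0.05, PD_NoSeg = 0.05, PD_Seg = NA),
                       seg_multi_range = c(0.80, 0.95),
                       burst_count_probs = c(0.35, 0.30, 0.20, 0.10, 0.05)) {
  cfg <- list(sample_rate = sample_rate, lowpass_hz = lowpass_hz,
              twitch_tau = twitch_tau, noise_sd = noise_sd,
              ipi_range = ipi_range, peak_mean = peak_mean, peak_sd = peak_sd,
              burst_dur_means = burst_dur_means, burst_dur_cvs = burst_dur_cvs,
              gap_means = gap_means, gap_cvs = gap_cvs,
              later_amp_mean = later_amp_mean, later_amp_sd = later_amp_sd,
              multi_prob = multi_prob, seg_multi_range = seg_multi_range,
              burst_count_probs = burst_count_probs)
  stopifnot(sample_rate > 0, twitch_tau > 0, noise_sd >= 0,
            all(burst_dur_means > 0), all(gap_means > 0))
  class(cfg) <- "sim_config"
  cfg
}

# truncated-normal draw at +/- 3 SD (keeps times positive for CV <= 1/3)
rtrunc3 <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  pmin(pmax(v, mean - 3 * sd), mean + 3 * sd)
}

ordinal_par <- function(means, j) means[min(j, length(means))]

# critically damped second-order impulse response, unit steady-state gain
twitch_kernel <- function(tau, fs) {
  tt <- seq(0, 8 * tau, by = 1 / fs)
  h <- (tt / tau^2) * exp(-tt / tau)
  h / (sum(h) / fs)
}

#' Simulate one rapid force pulse
#'
#' Draws a burst train for the requested archetype (or a fixed burst
#' structure when `burst_durs` / `gap_durs` are supplied), converts it to
#' force (see [sim_config()]), scales the noiseless pulse to its drawn
#' target peak, applies the forward-backward Butterworth low-pass and adds
#' noise. Randomness comes from the current RNG state; seed the caller.
#'
#' @param config a [sim_config()].
#' @param archetype `"OA"`, `"PD_NoSeg"` or `"PD_Seg"`.
#' @param n_bursts override the drawn burst count.
#' @param burst_durs,gap_durs,amps optional fixed burst durations, gaps
#'   (s) and relative amplitudes.
#' @param target_peak override the drawn target peak (%MVC).
#' @param multi_prob override the archetype multi-burst probability.
#' @param lead_s,tail_s quiet baseline before the drive and relaxation time
#'   kept after the peak, s.
#' @param include_noise set `FALSE` to defer noise (used by
#'   [simulate_session()], which adds noise over the whole session).
#' @return list with `force` (numeric, %MVC), `truth` (list: `n_bursts`,
#'   `burst_durs`, `gap_durs`, `amps`, `target_peak`, `onset_time` (s, start
#'   of the drive within the returned vector), `peak_time`).
#' @export
simulate_pulse <- function(config = sim_config(), archetype = "OA",
                           n_bursts = NULL, burst_durs = NULL,
                           gap_durs = NULL, amps = NULL, target_peak = NULL,
                           multi_prob = NULL, lead_s = 1, tail_s = 1,
                           include_noise = TRUE) {
  fs <- config$sample_rate
  tau <- config$twitch_tau
  if (is.null(burst_durs)) {
    if (is.null(n_bursts)) {
      if (is.null(multi_prob)) {
        multi_prob <- config$multi_prob[[archetype]]
        if (is.na(multi_prob)) multi_prob <- mean(config$seg_multi_range)
      }
      n_bursts <- if (stats::runif(1) < multi_prob) {
        sample(seq_len(length(config$burst_count_probs)) + 1L, 1L,
               prob = config$burst_count_probs)
      } else 1L
    }
    burst_durs <- vapply(seq_len(n_bursts), function(j) {
      m <- ordinal_par(config$burst_dur_means, j)
      rtrunc3(1L, m, m * ordinal_par(config$burst_dur_cvs, j))
    }, numeric(1))
    gap_durs <- if (n_bursts > 1L) {
      vapply(seq_len(n_bursts - 1L), function(j) {
        m <- ordinal_par(config$gap_means, j)
        rtrunc3(1L, m, m * ordinal_par(config$gap_cvs, j))
      }, numeric(1))
    } else numeric(0)
  } else {
    n_bursts <- length(burst_durs)
    if (is.null(gap_durs)) gap_durs <- numeric(0)
  }
  if (length(gap_durs) && any(gap_durs <= 0)) stop("burst gaps must be positive")
  if (any(burst_durs <= 0)) stop("burst durations must be positive")
  if (is.null(amps)) {
    amps <- c(1, if (n_bursts > 1L) {
      pmax(0.2, rtrunc3(n_bursts - 1L, config$later_amp_mean, config$later_amp_sd))
    })
  }
  if (is.null(target_peak)) {
    target_peak <- rtrunc3(1L, config$peak_mean, config$peak_sd)
  }
  dt <- 1 / fs
  # rectangular drive on the sample grid
  drive_len_s <- sum(burst_durs) + sum(gap_durs)
  rise_extra <- 2.5 * tau  # switching time: peak occurs here, before relaxation
  nd <- as.integer(ceiling((drive_len_s + rise_extra) * fs)) + 1L
  e <- numeric(nd)
  t0 <- 0
  for (j in seq_len(n_bursts)) {
    i0 <- as.integer(round(t0 * fs)) + 1L
    i1 <- min(nd, as.integer(round((t0 + burst_durs[j]) * fs)))
    e[i0:i1] <- amps[j]
    t0 <- t0 + burst_durs[j] + if (j < n_bursts) gap_durs[j] else 0
  }
  h <- twitch_kernel(tau, fs)
  rate <- stats::convolve(e, rev(h), type = "open")[seq_len(nd)] * dt
  rise <- cumsum(rate) * dt
  peak_val <- rise[nd]
  # relaxation: exponential decay from the peak
  tau_rel <- 0.12
  nt <- as.integer(round(tail_s * fs))
  decay <- peak_val * exp(-(seq_len(nt)) / (tau_rel * fs))
  nl <- as.integer(round(lead_s * fs))
  force <- c(numeric(nl), rise, decay) * (target_peak / peak_val)
  # acquisition low-pass (forward-backward Butterworth)
  wn <- config$lowpass_hz / (fs / 2)
  if (wn < 1) {
    bf <- signal::butter(2, wn)
    force <- as.numeric(signal::filtfilt(bf, force))
  }
  if (include_noise && config$noise_sd > 0) {
    force <- force + stats::rnorm(length(force), 0, config$noise_sd)
  }
  list(force = force,
       truth = list(n_bursts = n_bursts, burst_durs = burst_durs,
                    gap_durs = gap_durs, amps = amps,
                    target_peak = target_peak,
                    onset_time = nl / fs,
                    peak_time = (nl + nd - 1L) / fs))
}

#' Simulate one subject session
#'
#' Concatenates pulses on a quiet baseline with uniform 3-5 s spacing (per
#' `config$ipi_range`); noise is added over the whole session so baseline
#' and pulses share the same noise floor. For the `PD_Seg` archetype the
#' subject's multi-burst probability is drawn once from
#' `config$seg_multi_range`.
#'
#' @param archetype `"OA"`, `"PD_NoSeg"` or `"PD_Seg"`.
#' @param n_pulses number of pulses (>= 45 leaves 41 after eligibility).
#' @param seed integer seed for this session.
#' @param config a [sim_config()].
#' @param subject_id carried onto the recording.
#' @return list with `recording` (a normalized [force_recording()]) and
#'   `truth` (data.frame: one row per pulse with `pulse`, `onset_time`,
#'   `n_bursts`, `target_peak`, and `;`-joined `burst_durs`, `gap_durs`).
#' @export
simulate_session <- function(archetype = c("OA", "PD_NoSeg", "PD_Seg"),
                             n_pulses = 45L, seed, config = sim_config(),
                             subject_id = "S1") {
  archetype <- match.arg(archetype)
  if (missing(seed)) stop("a session seed is required")
  fs <- config$sample_rate
  if (n_pulses == 0L) {
    return(list(recording = force_recording(numeric(0), fs,
                                            subject_id = subject_id,
                                            normalized = TRUE),
                truth = data.frame(subject_id = character(0),
                                   pulse = integer(0),
                                   onset_time = numeric(0),
                                   n_bursts = integer(0),
                                   target_peak = numeric(0),
                                   burst_durs = character(0),
                                   gap_durs = character(0))))
  }
  with_seed(seed, {
    multi_prob <- if (archetype == "PD_Seg") {
      stats::runif(1, config$seg_multi_range[1], config$seg_multi_range[2])
    } else config$multi_prob[[archetype]]
    pulses <- vector("list", n_pulses)
    onsets <- numeric(n_pulses)
    t_cursor <- 2
    for (i in seq_len(n_pulses)) {
      pulses[[i]] <- simulate_pulse(config, archetype = archetype,
                                    multi_prob = multi_prob,
                                    lead_s = 0, tail_s = 1,
                                    include_noise = FALSE)
      onsets[i] <- t_cursor
      t_cursor <- t_cursor + stats::runif(1, config$ipi_range[1],
                                          config$ipi_range[2])
    }
    total_s <- onsets[n_pulses] +
      length(pulses[[n_pulses]]$force) / fs + 2
    force <- numeric(as.integer(ceiling(total_s * fs)))
    rows <- vector("list", n_pulses)
    for (i in seq_len(n_pulses)) {
      i0 <- as.integer(round(onsets[i] * fs)) + 1L
      seg <- pulses[[i]]$force
      force[i0:(i0 + length(seg) - 1L)] <- seg
      tr <- pulses[[i]]$truth
      rows[[i]] <- data.frame(
        subject_id = subject_id, pulse = i, onset_time = onsets[i],
        n_bursts = tr$n_bursts, target_peak = tr$target_peak,
        burst_durs = paste(signif(tr$burst_durs, 8), collapse = ";"),
        gap_durs = paste(signif(tr$gap_durs, 8), collapse = ";"),
        stringsAsFactors = FALSE)
    }
    if (config$noise_sd > 0) {
      force <- force + stats::rnorm(length(force), 0, config$noise_sd)
    }
    list(recording = force_recording(force, fs, subject_id = subject_id,
                                     normalized = TRUE,
                                     session_label = archetype),
         truth = do.call(rbind, rows))
  })
}

#' Simulate a full cohort with ground truth
#'
#' Generates one session per subject: `n_seg` PD subjects of the
#' segmented archetype, `n_noseg` non-segmented PD, and `n_oa` healthy
#' older adults (defaults mirror a 39 / 18 / 22 cohort). Per-subject
#' session seeds are derived from the master seed by the same stable hash
#' used for pulse selection, so the cohort is reproducible and independent
#' of processing order.
#'
#' @param n_seg,n_noseg,n_oa subject counts per archetype.
#' @param master_seed integer master seed.
#' @param n_pulses pulses per session.
#' @param config a [sim_config()].
#' @return list with `recordings` (named list of recordings), `metadata`
#'   (subject_id, group — OA/PD only, as the analyst would see), `truth`
#'   (per-pulse ground truth), `subjects` (subject_id, archetype,
#'   multi-burst share actually generated), and `config`.
#' @export
simulate_cohort <- function(n_seg = 39L, n_noseg = 18L, n_oa = 22L,
                            master_seed = 1L, n_pulses = 45L,
                            config = sim_config()) {
  stopifnot(n_seg >= 0, n_noseg >= 0, n_oa >= 0)
  ids <- c(sprintf("PDS%02d", seq_len(n_seg)),
           sprintf("PDN%02d", seq_len(n_noseg)),
           sprintf("OA%02d", seq_len(n_oa)))
  arch <- c(rep("PD_Seg", n_seg), rep("PD_NoSeg", n_noseg), rep("OA", n_oa))
  recordings <- vector("list", length(ids))
  names(recordings) <- ids
  truths <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ses <- simulate_session(arch[i], n_pulses = n_pulses,
                            seed = subject_seed(master_seed, paste0("sim:", ids[i])),
                            config = config, subject_id = ids[i])
    recordings[[i]] <- ses$recording
    truths[[i]] <- ses$truth
  }
  truth <- do.call(rbind, truths)
  subjects <- data.frame(
    subject_id = ids, archetype = arch,
    pct_multi_generated = vapply(seq_along(ids), function(i) {
      tr <- truths[[i]]
      if (nrow(tr)) 100 * mean(tr$n_bursts >= 2) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  metadata <- data.frame(subject_id = ids,
                         group = ifelse(arch == "OA", "OA", "PD"),
                         stringsAsFactors = FALSE)
  list(recordings = recordings, metadata = metadata, truth = truth,
       subjects = subjects, config = config, master_seed = master_seed)
}

#' Write a simulated cohort to disk
#'
#' Emits the same formats the reader side consumes: one `time,force` CSV
#' per subject, a cohort metadata CSV, a ground-truth sidecar CSV keyed by
#' (subject_id, pulse), and a JSON echo of the resolved configuration and
#' seeds.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_cohort_files <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings)) {
    write_recording(cohort$recordings[[id]],
                    file.path(dir, paste0(id, ".csv")), digits = 9L)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(list(master_seed = cohort$master_seed, config = cfg),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
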