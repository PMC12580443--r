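# minimal pulse_set stub: enough structure for selection/summary tests
fake_pulse_set <- function(peaks, n_seg_f90 = NULL, subject_id = "S1") {
  n <- length(peaks)
  if (is.null(n_seg_f90)) n_seg_f90 <- rep(1L, n)
  pulses <- data.frame(
    pulse = seq_len(n), onset_idx = seq_len(n) * 800L,
    peak_idx = seq_len(n) * 800L + 60L, offset_idx = seq_len(n) * 800L + 160L,
    peak_force = peaks, t_pf = 0.3, t_f90 = 0.25,
    f90_idx = seq_len(n) * 800L + 50L,
    qc_merged = FALSE, qc_onset_ambiguous = FALSE,
    zc_to_f90 = 2L * n_seg_f90 - 2L, zc_to_peak = 2L * n_seg_f90 - 1L,
    n_seg_f90 = n_seg_f90, n_seg_peak = n_seg_f90,
    rfd_pk = 300, t_rfd_pk = 0.1, rfd_pk_seg1 = 250,
    seg_of_rfd_pk = 1L, first_seg_dur = 0.1,
    dropped = FALSE, drop_reason = NA_character_)
  bounds <- replicate(n, list(segments = cbind(start = 1L, end = 2L),
                              slowing = cbind(start = integer(0), end = integer(0)),
                              segment_durations = 0.1,
                              slowing_durations = numeric(0)),
                      simplify = FALSE)
  structure(list(pulses = pulses, boundaries = bounds,
                 subject_id = subject_id, sample_rate = 200,
                 params = list()),
            class = "pulse_set")
}

test_that("selection draws k unique pulses deterministically", {
  ps <- fake_pulse_set(runif(60, 25, 55))
  s1 <- select_pulses(ps, k = 41, seed = 99)
  s2 <- select_pulses(ps, k = 41, seed = 99)
  expect_equal(sum(s1$pulses$selected), 41L)
  expect_identical(which(s1$pulses$selected), which(s2$pulses$selected))
  s3 <- select_pulses(ps, k = 41, seed = 100)
  expect_false(identical(which(s1$pulses$selected), which(s3$pulses$selected)))
})

test_that("selection is invariant to stored pulse order", {
  set.seed(5)
  peaks <- runif(60, 25, 55)
  ps <- fake_pulse_set(peaks)
  perm <- sample(60)
  ps_shuf <- ps
  ps_shuf$pulses <- ps$pulses[perm, ]
  a <- select_pulses(ps, k = 41, seed = 7)
  b <- select_pulses(ps_shuf, k = 41, seed = 7)
  sel_a <- sort(a$pulses$onset_idx[a$pulses$selected])
  sel_b <- sort(b$pulses$onset_idx[b$pulses$selected])
  expect_identical(sel_a, sel_b)
})

test_that("selection respects eligibility bounds and shortfalls", {
  ps <- fake_pulse_set(c(rep(40, 30), 61, 19.9))
  expect_warning(sel <- select_pulses(ps, k = 41, seed = 1), "only 30")
  expect_equal(sum(sel$pulses$selected), 30L)
  expect_false(sel$pulses$selected[31])  # 61 %MVC is out of range
  expect_false(sel$pulses$selected[32])  # 19.9 %MVC is out of range

  ps_bad <- fake_pulse_set(rep(70, 10), subject_id = "S9")
  expect_error(select_pulses(ps_bad, k = 41, seed = 1), "S9")

  expect_warning(select_pulses(fake_pulse_set(runif(50, 25, 55)),
                               k = 40, seed = 1), "even k")
})

test_that("QC-flagged and dropped pulses are ineligible", {
  ps <- fake_pulse_set(rep(40, 45))
  ps$pulses$qc_merged[1:2] <- TRUE
  ps$pulses$dropped[3] <- TRUE
  expect_warning(sel <- select_pulses(ps, k = 43, seed = 1), "only 42")
  expect_false(any(sel$pulses$selected[1:3]))
})

test_that("subject medians follow the order statistics of segment counts", {
  # all single-segment pulses
  ps <- fake_pulse_set(rep(40, 41))
  sel <- select_pulses(ps, k = 41, seed = 3)
  s <- summarize_subject(sel, "PD")
  expect_equal(s$med_n_seg_f90, 1)
  expect_equal(s$pct_multiseg, 0)
  expect_equal(s$group_final, "PD_NoSeg")
  # 21 of 41 pulses multi-segment: the median must be >= 2
  counts <- c(rep(3L, 21), rep(1L, 20))
  ps2 <- fake_pulse_set(rep(40, 41), n_seg_f90 = counts)
  sel2 <- select_pulses(ps2, k = 41, seed = 3)
  s2 <- summarize_subject(sel2, "PD")
  expect_gte(s2$med_n_seg_f90, 2)
  expect_equal(s2$med_n_seg_f90, sort(counts)[21])  # brute-force order statistic
  expect_equal(s2$group_final, "PD_Seg")
  # odd k keeps integer medians of integer counts
  expect_equal(s2$med_n_seg_f90 %% 1, 0)
})

test_that("classification uses the inclusive >= 2 threshold on PD only", {
  base <- data.frame(group_raw = c("PD", "PD", "PD", "OA"),
                     med_n_seg_f90 = c(4, 1, 2, 4))
  expect_equal(classify_segmentation(base),
               c("PD_Seg", "PD_NoSeg", "PD_Seg", "OA"))
})

test_that("per-subject seeds are stable, bounded, and id-sensitive", {
  a <- subject_seed(1, "PDS01")
  expect_identical(a, subject_seed(1, "PDS01"))
  expect_true(a >= 0 && a < 2^31)
  expect_false(a == subject_seed(1, "PDS02"))
  expect_false(a == subject_seed(2, "PDS01"))
})

test_that("cohort summary assembles one row per subject with ordinals", {
  cfg <- sim_config()
  coh <- simulate_cohort(2, 1, 1, master_seed = 4, n_pulses = 12,
                         config = cfg)
  pss <- lapply(coh$recordings, segment_pulses)
  summ <- suppressWarnings(summarize_cohort(pss, coh$metadata, k = 11,
                                            master_seed = 4))
  expect_equal(nrow(summ), 4L)
  expect_true(all(c("med_seg_dur1", "med_slow_dur1", "pct_multiseg",
                    "group_final") %in% names(summ)))
  expect_true(all(summ$med_n_seg_f90 >= 1))
  expect_true(all(summ$pct_multiseg >= 0 & summ$pct_multiseg <= 100))
})
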