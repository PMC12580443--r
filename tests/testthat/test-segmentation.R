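test_that("zero crossings count strict sign changes, bridging zeros", {
  expect_equal(zero_crossings(c(1, 1, -1, -1), c(1, 4))$count, 1L)
  zc <- zero_crossings(c(1, 0, 0, -1), c(1, 4))
  expect_equal(zc$count, 1L)
  expect_equal(zc$positions, 4L)
  expect_equal(zero_crossings(c(1, -1, 1, -1, 1, -1), c(1, 6))$count, 5L)
  expect_equal(zero_crossings(c(0, 0, 1, -1), c(1, 4))$count, 1L)
  expect_error(zero_crossings(c(1, -1), c(1, 5)), "interval")
})

test_that("segment count is (crossings + 1) / 2 rounded up", {
  expect_identical(segment_count(1), 1L)
  expect_identical(segment_count(5), 3L)
  expect_identical(segment_count(0), 1L)
  expect_identical(segment_count(2), 2L)
  expect_error(segment_count(-1), "non-negative")
})

test_that("pulse detection finds isolated pulses with accurate onsets", {
  flat <- force_recording(rep(0, 2000), 200, normalized = TRUE)
  d <- compute_derivatives(flat)
  expect_equal(nrow(detect_pulses(flat, d)), 0L)

  rec <- make_triangle()
  d <- compute_derivatives(rec)
  det <- detect_pulses(rec, d)
  expect_equal(nrow(det), 1L)
  ramp_start <- round(1.5 * 200) + 1
  expect_lte(abs(det$onset_idx - ramp_start), 3)
  expect_equal(det$peak_force, 40)
  # brute-force backward threshold scan agrees
  oracle_onset <- brute_onset_scan(rec$force, d$rfd, 20, det$peak_idx)
  expect_equal(det$onset_idx, oracle_onset)

  rec2 <- make_triangle(n_pulses = 2)
  det2 <- detect_pulses(rec2, compute_derivatives(rec2))
  expect_equal(nrow(det2), 2L)
  expect_lt(det2$offset_idx[1], det2$onset_idx[2])
  expect_false(any(det2$qc_merged))
})

test_that("time to F90 uses the first sample reaching 90% of peak", {
  fs <- 200
  # linear rise 0 -> 40 over 0.2 s: first sample >= 36 is onset + 36
  f <- c(rep(0, 100), seq(0, 40, length.out = 41), rep(0, 100))
  rec <- force_recording(f, fs, normalized = TRUE)
  pulse <- list(onset_idx = 101L, peak_idx = 141L)
  expect_equal(time_to_f90(rec, pulse), 0.180)
  # single-sample step: t_f90 = 1/fs
  f2 <- c(rep(0, 100), 40, rep(0, 100))
  rec2 <- force_recording(f2, fs, normalized = TRUE)
  expect_equal(time_to_f90(rec2, list(onset_idx = 100L, peak_idx = 101L)), 1 / fs)
  # force first reaches 90% at the peak sample itself
  f3 <- c(rep(0, 100), seq(0, 30, length.out = 31), 40, rep(0, 100))
  rec3 <- force_recording(f3, fs, normalized = TRUE)
  p3 <- list(onset_idx = 101L, peak_idx = 132L)
  expect_equal(time_to_f90(rec3, p3), (132 - 101) / fs)
})

test_that("boundaries recover generative gaps and tile the rising phase", {
  cfg <- sim_config(noise_sd = 0)
  p <- simulate_pulse(cfg, burst_durs = c(0.086, 0.065),
                      gap_durs = 0.080, amps = c(1, 1.3), target_peak = 40)
  rec <- force_recording(p$force, 200, normalized = TRUE)
  ps <- segment_pulses(rec)
  b <- ps$boundaries[[1]]
  expect_equal(nrow(b$segments), 2L)
  expect_equal(nrow(b$slowing), 1L)
  expect_lt(abs(b$slowing_durations[1] - 0.080), 0.015)
  # tiling: slowing periods are exactly the gaps between segments
  expect_equal(b$slowing[, "start"], b$segments[1, "end"], ignore_attr = TRUE)
  expect_equal(b$slowing[, "end"], b$segments[2, "start"], ignore_attr = TRUE)
  expect_equal(sum(b$segment_durations) + sum(b$slowing_durations),
               (b$segments[2, "end"] - b$segments[1, "start"]) / 200,
               ignore_attr = TRUE)
})

test_that("no crossings gives a single segment spanning onset to peak", {
  f2 <- rep(1, 100)
  pulse <- list(onset_idx = 10L, peak_idx = 50L)
  b <- extract_boundaries(f2, pulse, list(count = 0L, positions = integer(0)), 200)
  expect_equal(nrow(b$segments), 1L)
  expect_equal(b$segments[1, ], c(start = 10L, end = 50L))
  expect_equal(nrow(b$slowing), 0L)
})

test_that("segment/slowing structure holds across random noisy pulses", {
  set.seed(202)
  cfg <- sim_config()
  for (i in 1:40) {
    p <- simulate_pulse(cfg, archetype = sample(c("OA", "PD_Seg"), 1))
    rec <- force_recording(p$force, 200, normalized = TRUE)
    ps <- segment_pulses(rec)
    if (nrow(ps$pulses) != 1) next
    row <- ps$pulses[1, ]
    b <- ps$boundaries[[1]]
    expect_equal(nrow(b$segments), row$n_seg_peak)
    expect_equal(nrow(b$slowing), row$n_seg_peak - 1L)
    expect_lte(row$n_seg_f90, row$n_seg_peak)
    expect_lte(sum(b$segment_durations) + sum(b$slowing_durations),
               row$t_pf + 2 / 200)
    # interleaving: each slowing period shares its ends with its segments
    if (nrow(b$slowing)) {
      expect_equal(b$slowing[, "start"], b$segments[-nrow(b$segments), "end"],
                   ignore_attr = TRUE)
      expect_equal(b$slowing[, "end"], b$segments[-1, "start"],
                   ignore_attr = TRUE)
    }
    expect_gte(row$rfd_pk, row$rfd_pk_seg1)
    expect_true(row$seg_of_rfd_pk >= 1 && row$seg_of_rfd_pk <= row$n_seg_peak)
    if (row$n_seg_peak == 1L) expect_equal(row$rfd_pk_seg1, row$rfd_pk)
  }
})

test_that("RFD metrics locate the peak and its segment", {
  rec <- make_triangle()
  ps <- segment_pulses(rec)
  row <- ps$pulses[1, ]
  expect_equal(row$seg_of_rfd_pk, 1L)
  expect_equal(row$rfd_pk_seg1, row$rfd_pk)
  expect_equal(row$rfd_pk, 200, tolerance = 0.05)  # 40 %MVC over 0.2 s

  cfg <- sim_config(noise_sd = 0)
  p <- simulate_pulse(cfg, burst_durs = c(0.086, 0.065), gap_durs = 0.080,
                      amps = c(1, 1.5), target_peak = 40)
  ps2 <- segment_pulses(force_recording(p$force, 200, normalized = TRUE))
  expect_equal(ps2$pulses$seg_of_rfd_pk, 2L)
  expect_gt(ps2$pulses$rfd_pk, ps2$pulses$rfd_pk_seg1)
})

test_that("manual overrides drop and reinstate pulses", {
  rec <- make_triangle(n_pulses = 2)
  ps <- segment_pulses(rec)
  ov <- data.frame(subject_id = "S1", pulse = 1, action = "drop",
                   note = "merged with cue artifact")
  ps2 <- apply_overrides(ps, ov)
  expect_true(ps2$pulses$dropped[1])
  expect_match(ps2$pulses$drop_reason[1], "artifact")
  ps3 <- apply_overrides(ps2, data.frame(subject_id = "S1", pulse = 1,
                                         action = "keep"))
  expect_false(ps3$pulses$dropped[1])
})

test_that("per-pulse table carries wide duration columns", {
  rec <- make_triangle(n_pulses = 2)
  df <- as.data.frame(segment_pulses(rec))
  expect_true(all(c("seg1", "seg5", "slow1", "slow5") %in% names(df)))
  expect_equal(nrow(df), 2L)
  expect_true(all(is.na(df$slow1)))  # single-segment pulses
})
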