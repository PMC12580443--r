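# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths: slopes by explicit per-window
# normal-equation fits, crossing counts by an explicit sign-carrying loop,
# Dunn z by direct evaluation of the pooled-rank formula with hand-computed
# midranks.

# least-squares slope of y on t, one window at a time
brute_moving_slope <- function(y, fs, window_ms = 50) {
  w <- round(window_ms * fs / 1000)
  if (w %% 2 == 0) w <- w + 1
  n <- length(y)
  h <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- min(max(1, i - h), n - w + 1)
    idx <- a:(a + w - 1)
    tt <- (idx - 1) / fs
    fit <- stats::lm.fit(cbind(1, tt), y[idx])
    out[i] <- fit$coefficients[2]
  }
  out
}

# sign-carrying crossing scan; zeros keep the previous non-zero sign
brute_sign_scan <- function(f2, a, b) {
  last <- 0
  count <- 0
  for (i in a:b) {
    s <- sign(f2[i])
    if (s == 0) next
    if (last != 0 && s != last) count <- count + 1
    last <- s
  }
  count
}

brute_segment_recount <- function(f2, a, b) {
  ceiling((brute_sign_scan(f2, a, b) + 1) / 2)
}

# midranks without rank(): average positions of equal values
brute_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  pos <- seq_along(x)
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}

# Dunn z for groups i, j by direct formula on pooled midranks
brute_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  rk <- brute_midrank(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rbar_i <- mean(rk[starts[i]:ends[i]])
  rbar_j <- mean(rk[starts[j]:ends[j]])
  tt <- table(x)
  T <- sum(tt^3 - tt)
  sig2 <- N * (N + 1) / 12 - T / (12 * (N - 1))
  unname((rbar_i - rbar_j) / sqrt(sig2 * (1 / sizes[i] + 1 / sizes[j])))
}

# first index where a forward threshold scan says the ramp is under way
brute_onset_scan <- function(force, rfd, threshold, peak_idx) {
  i <- peak_idx
  while (i > 1 && !(rfd[i - 1] < threshold && force[i - 1] <= 10)) i <- i - 1
  i
}

# a plain triangular pulse embedded in baseline, exact sample grid
make_triangle <- function(fs = 200, baseline_s = 1.5, up_s = 0.2,
                          down_s = 0.3, peak = 40, n_pulses = 1,
                          gap_s = 3) {
  one <- c(seq(0, peak, length.out = round(up_s * fs) + 1),
           seq(peak, 0, length.out = round(down_s * fs) + 1)[-1])
  parts <- list(numeric(round(baseline_s * fs)))
  for (i in seq_len(n_pulses)) {
    parts <- c(parts, list(one))
    pad <- if (i < n_pulses) round((gap_s - up_s - down_s) * fs) else round(baseline_s * fs)
    parts <- c(parts, list(numeric(pad)))
  }
  force_recording(unlist(parts), fs, normalized = TRUE)
}
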