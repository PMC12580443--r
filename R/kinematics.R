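#' Windowed least-squares slope (moving slope)
#'
#' At each interior sample the slope of a straight line fitted by least
#' squares to a centered window of `window_samples` samples is returned, in
#' input units per second. Near the edges the full-width window is shifted
#' to stay in bounds and that window's fitted slope is reported (a straight
#' line's slope does not depend on where in the window it is evaluated), so
#' the output has the same length as the input.
#'
#' The window length is `round(window_ms * sample_rate / 1000)`, forced odd
#' by rounding up: 50 ms at 200 Hz gives 11 samples, spanning exactly 50 ms
#' of sampling intervals.
#'
#' @param series numeric vector.
#' @param sample_rate Hz.
#' @param window_ms window width in milliseconds (default 50).
#' @return numeric vector of slopes, same length as `series`.
#' @export
moving_slope <- function(series, sample_rate, window_ms = 50) {
  series <- as.numeric(series)
  w <- slope_window_samples(window_ms, sample_rate)
  n <- length(series)
  if (w < 3L) stop("window must span at least 3 samples")
  if (n < w) stop(sprintf("series length %d shorter than window (%d samples)", n, w))
  h <- (w - 1L) %/% 2L
  # least-squares slope of window starting at j:
  #   slope_j = sum_k c_k * y[j+k] * fs / sum(c^2),  c_k = k - (w-1)/2
  cc <- (0:(w - 1L)) - h
  denom <- sum(cc^2) / sample_rate
  # stats::filter(..., sides = 2) centers the (odd) filter; entries outside
  # the series give NA, filled below by the shifted edge windows.
  sl <- as.numeric(stats::filter(series, rev(cc) / denom, sides = 2))
  first <- sum(cc * series[1:w]) / denom
  last <- sum(cc * series[(n - w + 1L):n]) / denom
  sl[1:h] <- first
  sl[(n - h + 1L):n] <- last
  sl
}

slope_window_samples <- function(window_ms, sample_rate) {
  w <- as.integer(round(window_ms * sample_rate / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' First and second time derivatives of force
#'
#' Computes the rate of force development RFD (%MVC/s) as the moving slope
#' of the normalized force, and the second derivative F''(t) (%MVC/s^2) as
#' the moving slope of the RFD, both with the same window (default 50 ms).
#' No smoothing beyond the two slope passes is applied: the 50 Hz hardware
#' low-pass is an acquisition property, not re-applied here.
#'
#' @param rec a normalized [force_recording()].
#' @param window_ms slope window in milliseconds.
#' @return An object of class `deriv_set` with elements `rfd`, `f2`,
#'   `window_ms`, `window_samples`, `sample_rate`, `n`.
#' @export
compute_derivatives <- function(rec, window_ms = 50) {
  stopifnot(inherits(rec, "force_recording"))
  if (!rec$normalized) stop("recording must be normalized to %MVC first")
  w <- slope_window_samples(window_ms, rec$sample_rate)
  if (length(rec$force) < 2L * w) {
    stop("recording too short for the requested derivative window")
  }
  rfd <- moving_slope(rec$force, rec$sample_rate, window_ms)
  f2 <- moving_slope(rfd, rec$sample_rate, window_ms)
  # snap floating-point residue to an exact zero so piecewise-linear force
  # (F'' identically zero between corners) does not produce phantom sign
  # changes; the zero-bridging rule in zero_crossings() then applies
  big <- max(abs(f2))
  if (big > 0) f2[abs(f2) < 1e-9 * big] <- 0
  structure(
    list(rfd = rfd, f2 = f2, window_ms = window_ms, window_samples = w,
         sample_rate = rec$sample_rate, n = length(rec$force)),
    class = "deriv_set"
  )
}

#' @export
print.deriv_set <- function(x, ...) {
  cat(sprintf("<deriv_set> %d samples, %g ms window (%d samples) at %g Hz\n",
              x$n, x$window_ms, x$window_samples, x$sample_rate))
  cat(sprintf("  RFD range [%.1f, %.1f] %%MVC/s\n", min(x$rfd), max(x$rfd)))
  invisible(x)
}

#' Export force and derivatives as a data.frame
#'
#' @param rec a normalized [force_recording()].
#' @param deriv the matching [compute_derivatives()] result.
#' @return data.frame with columns `time`, `force`, `rfd`, `f2`.
#' @export
derivatives_frame <- function(rec, deriv) {
  stopifnot(inherits(rec, "force_recording"), inherits(deriv, "deriv_set"))
  if (deriv$n != length(rec$force)) stop("derivative set does not match recording")
  data.frame(time = (seq_along(rec$force) - 1L) / rec$sample_rate,
             force = rec$force, rfd = deriv$rfd, f2 = deriv$f2)
}
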