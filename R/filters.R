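#' Zero-phase band filters for slow-wave and spindle detection
#'
#' \code{bandpassSlow} isolates the slow-wave band the way the detection rules
#' expect: a 0.1 Hz high-pass followed by a 4 Hz low-pass, each a 4th-order
#' Butterworth applied forward-backward (\code{signal::filtfilt}) so event
#' timing is phase-true. DC is rejected.
#'
#' \code{bandpassSpindle} isolates 10-16 Hz with a single 4th-order Butterworth
#' band-pass applied forward-backward. A single band-pass is used (rather than
#' cascaded high/low-pass sections) because the band is narrow: cascading and
#' squaring two edge responses would sag mid-band gain to ~0.74, distorting
#' envelope amplitudes, whereas the band-pass keeps 12 Hz gain at 0.998.
#'
#' @param x numeric sample vector (microvolts).
#' @param fs sampling rate in Hz (>= 32 for the slow band, >= 64 for the
#'   spindle band).
#' @return filtered vector, same length as \code{x}.
#' @export
bandpassSlow <- function(x, fs) {
  stopifnot(fs >= 32)
  if (length(x) <= 27)
    stop("signal too short to filter (need > 3 filter lengths)")
  x <- x - mean(x)   # remove DC up front; the 0.1 Hz edge transient is long
  hp <- signal::butter(4, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 4 / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' @rdname bandpassSlow
#' @export
bandpassSpindle <- function(x, fs) {
  stopifnot(fs >= 64)
  if (length(x) <= 27)
    stop("signal too short to filter (need > 3 filter lengths)")
  bp <- signal::butter(4, c(10, 16) / (fs / 2), type = "pass")
  signal::filtfilt(bp, x)
}

# Analytic signal via the standard FFT construction: double positive
# frequencies, zero negative ones. Used because no installed package
# exposes a Hilbert transform.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unit-area Gaussian kernel of `support` seconds (sd = support/6), truncated
# and renormalized; convolution pads by edge reflection so the output keeps
# the input length.
gaussianSmooth <- function(x, fs, support = 0.2) {
  m <- max(3L, round(support * fs))
  if (m %% 2 == 0) m <- m + 1L
  half <- (m - 1L) / 2L
  t <- seq(-half, half) / fs
  k <- exp(-0.5 * (t / (support / 6))^2)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[(length(x) - half + 1):length(x)]))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Smoothed spindle-band envelope
#'
#' Band-passes the signal to 10-16 Hz (zero-phase Butterworth), takes the
#' magnitude of the analytic signal (Hilbert transform) and smooths it by
#' convolution with a unit-area Gaussian window of 200 ms support
#' (sd = support/6, truncated and renormalized). For a sustained tone in the
#' band the envelope equals the tone's amplitude.
#'
#' @param x numeric sample vector (microvolts).
#' @param fs sampling rate in Hz (>= 64).
#' @param smoothSupport Gaussian window support in seconds.
#' @return nonnegative envelope, same length as \code{x}.
#' @export
spindleEnvelope <- function(x, fs, smoothSupport = 0.2) {
  bp <- bandpassSpindle(x, fs)
  gaussianSmooth(Mod(analyticSignal(bp)), fs, smoothSupport)
}
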