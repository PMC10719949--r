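#' Envelope-based spindle thresholds
#'
#' Mean and standard deviation of the smoothed spindle-band envelope over the
#' masked-in samples of a channel (the whole recording's retained NREM, not
#' per epoch). The upper threshold is mu + 2.5 sigma, the lower mu + 1.5
#' sigma; sigma is the sample (n-1) standard deviation.
#'
#' @param envelope envelope vector from [spindleEnvelope()].
#' @param mask optional logical vector of retained samples.
#' @return list with \code{mu}, \code{sigma}, \code{upper}, \code{lower}
#'   (microvolts), or NULL with a warning when no samples are masked in.
#' @export
computeSpindleThresholds <- function(envelope, mask = NULL) {
  v <- if (is.null(mask)) envelope else envelope[mask]
  if (!length(v)) {
    warning("no masked-in samples; spindle detection aborted for channel")
    return(NULL)
  }
  mu <- mean(v)
  sigma <- if (length(v) > 1) stats::sd(v) else 0
  list(mu = mu, sigma = sigma,
       upper = mu + 2.5 * sigma, lower = mu + 1.5 * sigma)
}

#' Detect sleep spindles from the smoothed envelope
#'
#' A spindle is a maximal run of envelope samples above the lower threshold
#' that lasts at least \code{minDuration} (500 ms), contains at least one
#' sample above the upper threshold, and lies entirely in masked-in signal
#' (runs touching masked-out samples are discarded whole). Onset/offset are
#' the lower-threshold crossings reported half-open: onset is the time of the
#' first supra-threshold sample, offset the time just after the last, so
#' offset - onset is the run length in seconds. Adjacent runs separated by
#' even one sub-threshold sample stay distinct; there is no maximum duration.
#'
#' @param envelope envelope vector from [spindleEnvelope()].
#' @param thresholds list from [computeSpindleThresholds()].
#' @param fs sampling rate in Hz.
#' @param mask optional logical vector of retained samples.
#' @param minDuration minimum spindle duration in seconds.
#' @return data.frame with columns \code{onset}, \code{offset},
#'   \code{peak_time} (envelope maximum) and \code{peak_env}, ordered in time.
#' @export
detectSpindles <- function(envelope, thresholds, fs, mask = NULL,
                           minDuration = 0.5) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), peak_env = numeric(0))
  if (is.null(thresholds)) return(empty)
  above <- envelope > thresholds$lower
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= ceiling(minDuration * fs))
  if (!length(runs)) return(empty)
  rows <- lapply(runs, function(k) {
    span <- starts[k]:ends[k]
    if (!is.null(mask) && !all(mask[span])) return(NULL)
    if (!any(envelope[span] > thresholds$upper)) return(NULL)
    pk <- span[which.max(envelope[span])]
    data.frame(onset = (starts[k] - 1) / fs, offset = ends[k] / fs,
               peak_time = (pk - 1) / fs, peak_env = envelope[pk])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
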