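#' Extract slow-wave candidates from a filtered channel
#'
#' Scans the slow-band signal (see [bandpassSlow()]) for all
#' positive-to-negative zero crossings. Each crossing yields one candidate:
#' its peak is the signal maximum between the previous negative-to-positive
#' crossing and the crossing, its trough the minimum between the crossing and
#' the next negative-to-positive crossing. Candidates whose peak or trough
#' sample is masked out are discarded whole.
#'
#' Sample i carries time (i-1)/fs seconds.
#'
#' @param filtered slow-band filtered samples of one channel.
#' @param fs sampling rate in Hz.
#' @param mask optional logical vector of retained samples (TRUE = keep).
#' @return data.frame with columns \code{peak_time}, \code{peak_amp},
#'   \code{trough_time}, \code{trough_amp}, one row per candidate, ordered in
#'   time. Zero rows when there are no crossings.
#' @export
extractCandidates <- function(filtered, fs, mask = NULL) {
  x <- as.numeric(filtered)
  n <- length(x)
  empty <- data.frame(peak_time = numeric(0), peak_amp = numeric(0),
                      trough_time = numeric(0), trough_amp = numeric(0))
  if (n < 3) return(empty)
  pos <- x > 0
  p2n <- which(pos[-n] & !pos[-1])        # last positive sample of a cycle
  n2p <- which(!pos[-n] & pos[-1])        # last non-positive sample
  if (!length(p2n) || !length(n2p)) return(empty)

  prevN2p <- n2p[findInterval(p2n, n2p)]
  nextIdx <- findInterval(p2n, n2p) + 1L
  ok <- findInterval(p2n, n2p) >= 1L & nextIdx <= length(n2p)
  p2n <- p2n[ok]
  if (!length(p2n)) return(empty)
  prevN2p <- n2p[findInterval(p2n, n2p)]
  nextN2p <- n2p[findInterval(p2n, n2p) + 1L]

  peakIdx <- troughIdx <- integer(length(p2n))
  for (k in seq_along(p2n)) {
    posSpan <- (prevN2p[k] + 1L):p2n[k]
    negSpan <- (p2n[k] + 1L):nextN2p[k]
    peakIdx[k] <- posSpan[which.max(x[posSpan])]
    troughIdx[k] <- negSpan[which.min(x[negSpan])]
  }
  out <- data.frame(
    peak_time = (peakIdx - 1) / fs, peak_amp = x[peakIdx],
    trough_time = (troughIdx - 1) / fs, trough_amp = x[troughIdx])
  if (!is.null(mask)) {
    stopifnot(length(mask) == n)
    out <- out[mask[peakIdx] & mask[troughIdx], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Data-derived slow-wave amplitude thresholds
#'
#' The negative threshold is the 40th percentile of candidate trough
#' amplitudes (so troughs below it are the deepest 40\%), the positive
#' threshold the 85th percentile of peak amplitudes (peaks above it are the
#' top 15\%). Percentiles use linear interpolation between order statistics
#' (the h = (n-1)p + 1 convention, \code{stats::quantile} type 7), computed
#' per channel from that channel's candidates.
#'
#' @param candidates candidate data.frame from [extractCandidates()].
#' @param negativePercentile,positivePercentile percentile settings.
#' @return list with elements \code{negative} and \code{positive}
#'   (microvolts), or NULL with a warning when fewer than 5 candidates exist
#'   (detection is aborted for the channel).
#' @export
computeSlowThresholds <- function(candidates, negativePercentile = 0.40,
                                  positivePercentile = 0.85) {
  if (nrow(candidates) < 5) {
    warning("fewer than 5 slow-wave candidates; detection aborted for channel")
    return(NULL)
  }
  list(
    negative = unname(stats::quantile(candidates$trough_amp,
                                      negativePercentile, type = 7)),
    positive = unname(stats::quantile(candidates$peak_amp,
                                      positivePercentile, type = 7)))
}

#' Classify candidates into slow oscillations and delta waves
#'
#' A candidate becomes an SO when its trough is lower than the negative
#' threshold, its peak higher than the positive threshold, and the
#' peak-to-trough lag lies in \code{soDuration} (150-500 ms). It becomes a
#' delta wave when the trough is lower than the negative threshold, the peak
#' lower than the positive threshold, and the lag is at most
#' \code{deltaMaxDuration} (no lower bound by default). All other candidates
#' are discarded. The same candidate can never be both.
#'
#' @param candidates candidate data.frame from [extractCandidates()].
#' @param thresholds list from [computeSlowThresholds()].
#' @param soDuration length-2 peak-to-trough lag bounds for SOs (seconds).
#' @param deltaMaxDuration maximum peak-to-trough lag for delta waves.
#' @param deltaMinDuration optional lower lag bound for delta waves.
#' @return data.frame with the candidate columns plus \code{kind}
#'   (\code{"SO"} or \code{"delta"}) and \code{up_state_time}
#'   (= \code{peak_time}), sorted by \code{up_state_time}.
#' @export
classifySlowWaves <- function(candidates, thresholds,
                              soDuration = c(0.150, 0.500),
                              deltaMaxDuration = 0.500,
                              deltaMinDuration = 0) {
  empty <- cbind(candidates[0, ], kind = character(0),
                 up_state_time = numeric(0))
  if (is.null(thresholds) || nrow(candidates) == 0) return(empty)
  lag <- candidates$trough_time - candidates$peak_time
  deep <- candidates$trough_amp < thresholds$negative
  isSO <- deep & candidates$peak_amp > thresholds$positive &
    lag >= soDuration[1] & lag <= soDuration[2]
  isDelta <- deep & candidates$peak_amp < thresholds$positive &
    lag >= deltaMinDuration & lag <= deltaMaxDuration
  parts <- list()
  if (any(isSO)) {
    so <- candidates[isSO, , drop = FALSE]; so$kind <- "SO"
    parts$so <- so
  }
  if (any(isDelta)) {
    de <- candidates[isDelta, , drop = FALSE]; de$kind <- "delta"
    parts$delta <- de
  }
  if (!length(parts)) return(empty)
  out <- do.call(rbind, parts)
  out$up_state_time <- out$peak_time
  out <- out[order(out$up_state_time), ]
  rownames(out) <- NULL
  out
}
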