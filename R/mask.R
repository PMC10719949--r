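#' Build the per-sample analysis mask
#'
#' A sample is retained when (a) its 30-s epoch is scored NREM and (b) it is
#' not within \code{artifactPad} seconds of any sample whose absolute
#' amplitude exceeds \code{artifactThreshold} on that channel. The mask is
#' computed per channel; excluded samples are removed from both the event
#' search and the density denominator, so densities stay counts per retained
#' NREM minute.
#'
#' The hypnogram may fall short of the recording by at most one epoch
#' (partially covered tail epochs are truncated, and any unlabeled tail is
#' excluded); a larger shortfall raises an alignment error.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param hyp a \linkS4class{Hypnogram} covering the recording.
#' @param artifactThreshold absolute amplitude bound in microvolts (> 0).
#' @param artifactPad seconds excluded on each side of an artifact sample.
#' @param nremStages stage codes treated as NREM.
#' @return an \linkS4class{AnalysisMask}.
#' @export
buildMask <- function(rec, hyp, artifactThreshold = 500, artifactPad = 1,
                      nremStages = c("N1", "N2", "N3", "NREM")) {
  stopifnot(artifactThreshold > 0, artifactPad >= 0)
  fs <- samplingRate(rec)
  n <- nrow(samples(rec))
  covered <- nEpochs(hyp) * hyp@epochLength * fs
  if (covered < n - hyp@epochLength * fs)
    stop("hypnogram covers ", round(covered / fs), " s but recording lasts ",
         round(n / fs), " s (short by more than one epoch)")
  epochOfSample <- pmin(floor((seq_len(n) - 1) / (hyp@epochLength * fs)) + 1L,
                        nEpochs(hyp) + 1L)
  nrem <- c(isNREM(hyp, nremStages), FALSE)[epochOfSample]

  padN <- round(artifactPad * fs)
  keep <- matrix(FALSE, nrow = n, ncol = ncol(samples(rec)))
  for (ch in seq_len(ncol(keep))) {
    bad <- abs(samples(rec)[, ch]) > artifactThreshold
    if (any(bad) && padN > 0) {
      idx <- which(bad)
      lo <- pmax(idx - padN, 1L); hi <- pmin(idx + padN, n)
      for (k in seq_along(idx)) bad[lo[k]:hi[k]] <- TRUE
    }
    keep[, ch] <- nrem & !bad
  }
  new("AnalysisMask", keep = keep, fs = fs, channels = channelNames(rec))
}

#' Extract one channel's mask as a logical vector
#'
#' @param mask an \linkS4class{AnalysisMask}.
#' @param channel channel label.
#' @return logical vector of retained samples for that channel.
#' @export
maskChannel <- function(mask, channel) {
  i <- match(channel, mask@channels)
  if (is.na(i)) stop("unknown channel: ", channel)
  mask@keep[, i]
}
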