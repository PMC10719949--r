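#' Re-reference a recording
#'
#' Subtracts the mean of the two reference electrodes (A1/A2 for the auricle
#' average, M1/M2 for linked mastoids) from every other channel, drops the
#' reference channels from the output, and records the scheme. Recordings
#' already distributed in the target reference can declare
#' \code{preReferenced = TRUE}, which only sets the flag.
#'
#' Referencing is idempotent: after one pass the reference channels are zero
#' (they are removed here), so a second pass changes nothing.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param scheme \code{"auricle_average"} or \code{"linked_mastoids"}.
#' @param preReferenced if TRUE the samples are left untouched and only the
#'   reference flag is set (for data distributed already referenced).
#' @return a re-referenced \linkS4class{EEGRecording}.
#' @export
applyReference <- function(rec, scheme = c("auricle_average", "linked_mastoids"),
                           preReferenced = FALSE) {
  scheme <- match.arg(scheme)
  if (preReferenced) {
    rec@reference <- scheme
    validObject(rec)
    return(rec)
  }
  if (identical(rec@reference, scheme)) return(rec)
  refLabels <- if (scheme == "auricle_average") c("A1", "A2") else c("M1", "M2")
  idx <- match(refLabels, channelNames(rec))
  if (anyNA(idx))
    stop("reference channels ", paste(refLabels[is.na(idx)], collapse = ", "),
         " not present; pass preReferenced = TRUE if the data are already ",
         scheme, "-referenced")
  refSig <- rowMeans(samples(rec)[, idx, drop = FALSE])
  keep <- setdiff(seq_along(channelNames(rec)), idx)
  mat <- samples(rec)[, keep, drop = FALSE] - refSig
  new("EEGRecording", samples = mat, fs = samplingRate(rec),
      channels = channelNames(rec)[keep], reference = scheme)
}
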