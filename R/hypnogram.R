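#' Read and write hypnograms
#'
#' Hypnograms are two-column delimited text: epoch index (0- or 1-based,
#' ignored beyond ordering) and a stage code from
#' \code{W, N1, N2, N3, R, NREM}. Epochs are 30 s unless stated otherwise.
#'
#' @param path hypnogram file.
#' @param epochLength epoch duration in seconds.
#' @return a \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path, epochLength = 30) {
  if (!file.exists(path)) stop("cannot read hypnogram: ", path)
  dat <- utils::read.table(path, header = FALSE, col.names = c("epoch", "stage"),
                           colClasses = c("integer", "character"))
  dat <- dat[order(dat$epoch), ]
  new("Hypnogram", epochLength = epochLength, stages = toupper(dat$stage))
}

#' @rdname readHypnogram
#' @param hyp a \linkS4class{Hypnogram} to write.
#' @export
writeHypnogram <- function(hyp, path) {
  utils::write.table(
    data.frame(epoch = seq_along(hyp@stages) - 1L, stage = hyp@stages),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Which epochs count as NREM
#'
#' @param hyp a \linkS4class{Hypnogram}.
#' @param nremStages stage codes collapsed into NREM.
#' @return logical vector, one element per epoch.
#' @export
isNREM <- function(hyp, nremStages = c("N1", "N2", "N3", "NREM")) {
  hyp@stages %in% nremStages
}
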