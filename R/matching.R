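#' Match detections against ground truth
#'
#' Greedy one-to-one matching by increasing time difference: a detection
#' matches a ground-truth event of the same type on the same channel when
#' their anchors differ by at most \code{tol} seconds. Anchors are the trough
#' time for slow waves and the (envelope) peak time for spindles.
#'
#' @param truth ground-truth data.frame from [injectEvents()].
#' @param detection list from [detectEvents()].
#' @param tol matching tolerance in seconds.
#' @return data.frame with one row per event type (\code{SO}, \code{delta},
#'   \code{spindle}): \code{n_truth}, \code{n_detected}, \code{n_matched},
#'   \code{recall}, \code{precision}.
#' @export
matchEvents <- function(truth, detection, tol = 0.25) {
  anchorsTruth <- function(type) {
    tt <- truth[truth$type == type, ]
    data.frame(channel = tt$channel,
               t = if (type == "spindle") tt$peak_time else tt$trough_time)
  }
  anchorsDet <- function(type) {
    if (type == "spindle")
      data.frame(channel = detection$spindles$channel,
                 t = detection$spindles$peak_time)
    else {
      sl <- detection$slow[detection$slow$kind == type, ]
      data.frame(channel = sl$channel, t = sl$trough_time)
    }
  }
  rows <- lapply(c("SO", "delta", "spindle"), function(type) {
    tr <- anchorsTruth(type); de <- anchorsDet(type)
    matched <- 0L
    for (ch in unique(tr$channel)) {
      a <- tr$t[tr$channel == ch]; b <- de$t[de$channel == ch]
      if (!length(a) || !length(b)) next
      dmat <- abs(outer(a, b, "-"))
      cand <- which(dmat <= tol, arr.ind = TRUE)
      if (!nrow(cand)) next
      ord <- order(dmat[cand])
      usedA <- logical(length(a)); usedB <- logical(length(b))
      for (j in ord) {
        ia <- cand[j, 1]; ib <- cand[j, 2]
        if (usedA[ia] || usedB[ib]) next
        usedA[ia] <- TRUE; usedB[ib] <- TRUE
        matched <- matched + 1L
      }
    }
    data.frame(type = type, n_truth = nrow(tr), n_detected = nrow(de),
               n_matched = matched,
               recall = if (nrow(tr)) matched / nrow(tr) else NA_real_,
               precision = if (nrow(de)) matched / nrow(de) else NA_real_)
  })
  do.call(rbind, rows)
}
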