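#' Nest spindles to slow oscillations and delta waves
#'
#' A spindle nests to a slow event of a given kind when its envelope-peak
#' time falls within the coupling window relative to the slow event's UP
#' state (positive peak): lag = spindle peak - UP state in
#' [window[1], window[2]], default -0.5 to +1.0 s. SO nesting and delta
#' nesting are computed independently with the same window, so one spindle
#' may appear in both tallies, but within a kind the pairing is one-to-one:
#' candidate pairs are accepted greedily by increasing |lag| (ties toward the
#' earlier slow event), and a spindle or slow event already paired is not
#' reused. This keeps nested counts bounded by both parent counts.
#'
#' @param slow slow-wave events of one subject (data.frame from
#'   [detectEvents()]\code{$slow}, or any frame with \code{channel},
#'   \code{kind}, \code{up_state_time}).
#' @param spindles spindle events (\code{channel}, \code{peak_time}).
#' @param window length-2 lag window in seconds.
#' @return data.frame with \code{channel}, \code{slow_kind},
#'   \code{up_state_time}, \code{spindle_peak_time}, \code{lag}, ordered by
#'   channel then UP-state time.
#' @export
nestSpindles <- function(slow, spindles, window = c(-0.5, 1.0)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  empty <- data.frame(channel = character(0), slow_kind = character(0),
                      up_state_time = numeric(0),
                      spindle_peak_time = numeric(0), lag = numeric(0))
  if (!nrow(slow) || !nrow(spindles)) return(empty)
  out <- list()
  for (ch in intersect(unique(slow$channel), unique(spindles$channel))) {
    spT <- sort(spindles$peak_time[spindles$channel == ch])
    for (kind in c("SO", "delta")) {
      up <- sort(slow$up_state_time[slow$channel == ch & slow$kind == kind])
      if (!length(up)) next
      pairIdx <- which(outer(spT, up, "-") >= window[1] &
                       outer(spT, up, "-") <= window[2], arr.ind = TRUE)
      if (!nrow(pairIdx)) next
      lag <- spT[pairIdx[, 1]] - up[pairIdx[, 2]]
      ord <- order(abs(lag), up[pairIdx[, 2]])
      usedSp <- logical(length(spT)); usedUp <- logical(length(up))
      acc <- list()
      for (j in ord) {
        si <- pairIdx[j, 1]; ui <- pairIdx[j, 2]
        if (usedSp[si] || usedUp[ui]) next
        usedSp[si] <- TRUE; usedUp[ui] <- TRUE
        acc[[length(acc) + 1L]] <- data.frame(
          channel = ch, slow_kind = kind, up_state_time = up[ui],
          spindle_peak_time = spT[si], lag = lag[j])
      }
      if (length(acc)) out[[paste(ch, kind)]] <- do.call(rbind, acc)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res <- res[order(res$channel, res$up_state_time), ]
  rownames(res) <- NULL
  res
}

#' Count nested events per channel and slow-wave kind
#'
#' @param nested data.frame from [nestSpindles()].
#' @return data.frame with \code{channel}, \code{slow_kind}, \code{count};
#'   zero rows when nothing is nested.
#' @export
nestingCounts <- function(nested) {
  if (!nrow(nested))
    return(data.frame(channel = character(0), slow_kind = character(0),
                      count = integer(0)))
  agg <- stats::aggregate(list(count = nested$lag),
                          by = list(channel = nested$channel,
                                    slow_kind = nested$slow_kind),
                          FUN = length)
  agg[order(agg$channel, agg$slow_kind), ]
}
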