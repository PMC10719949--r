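#' Per-channel event densities (counts per retained NREM minute)
#'
#' Counts events of each type per channel and divides by that channel's
#' retained NREM minutes from the analysis mask. The table carries a full
#' channel-by-type grid (zero counts included) for the five event types
#' \code{SO}, \code{delta}, \code{spindle}, \code{SO_spindle},
#' \code{delta_spindle}. Channels with zero retained minutes are excluded
#' with a warning (their density is undefined).
#'
#' @param detection list from [detectEvents()].
#' @param nested data.frame from [nestSpindles()].
#' @param minutes named numeric of retained NREM minutes per channel, e.g.
#'   \code{nremMinutes(mask)}.
#' @param subject subject identifier stamped on every row.
#' @return data.frame (a \emph{density table}) with columns \code{subject},
#'   \code{channel}, \code{event_type}, \code{count}, \code{minutes},
#'   \code{density}.
#' @export
computeDensity <- function(detection, nested, minutes, subject = "s1") {
  types <- c("SO", "delta", "spindle", "SO_spindle", "delta_spindle")
  zero <- names(minutes)[minutes <= 0]
  if (length(zero)) {
    warning("channel(s) with no retained NREM minutes excluded: ",
            paste(zero, collapse = ", "))
    minutes <- minutes[minutes > 0]
  }
  chans <- names(minutes)
  grid <- expand.grid(channel = chans, event_type = types,
                      stringsAsFactors = FALSE)
  countOf <- function(ch, type) {
    switch(type,
      SO = sum(detection$slow$channel == ch & detection$slow$kind == "SO"),
      delta = sum(detection$slow$channel == ch & detection$slow$kind == "delta"),
      spindle = sum(detection$spindles$channel == ch),
      SO_spindle = sum(nested$channel == ch & nested$slow_kind == "SO"),
      delta_spindle = sum(nested$channel == ch & nested$slow_kind == "delta"))
  }
  grid$count <- mapply(countOf, grid$channel, grid$event_type)
  grid$minutes <- minutes[grid$channel]
  grid$density <- grid$count / grid$minutes
  data.frame(subject = subject, grid, row.names = NULL)
}
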