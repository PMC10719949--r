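#' Detect all NREM oscillation events on every channel
#'
#' Runs the full per-channel detection chain: slow-band filtering, candidate
#' extraction, data-derived percentile thresholds, SO/delta classification,
#' spindle-band envelope, envelope thresholds and spindle runs. All
#' thresholds are derived from the channel's own masked NREM data, so
#' detection is invariant to per-channel gain.
#'
#' @param rec an \linkS4class{EEGRecording} (already referenced).
#' @param mask an \linkS4class{AnalysisMask} from [buildMask()]; NULL uses
#'   the whole recording.
#' @param channels channels to analyze (default all in \code{rec}).
#' @param soDuration,deltaMaxDuration,deltaMinDuration see
#'   [classifySlowWaves()].
#' @param negativePercentile,positivePercentile see
#'   [computeSlowThresholds()].
#' @param minSpindleDuration see [detectSpindles()].
#' @return list with elements \code{slow} (data.frame: \code{channel},
#'   candidate columns, \code{kind}, \code{up_state_time}), \code{spindles}
#'   (data.frame: \code{channel}, \code{onset}, \code{offset},
#'   \code{peak_time}, \code{peak_env}) and \code{thresholds} (per-channel
#'   list of the slow and spindle thresholds used).
#' @export
detectEvents <- function(rec, mask = NULL, channels = channelNames(rec),
                         soDuration = c(0.150, 0.500),
                         deltaMaxDuration = 0.500, deltaMinDuration = 0,
                         negativePercentile = 0.40, positivePercentile = 0.85,
                         minSpindleDuration = 0.5) {
  fs <- samplingRate(rec)
  slowAll <- list(); spAll <- list(); thAll <- list()
  for (ch in channels) {
    x <- samples(rec)[, match(ch, channelNames(rec))]
    m <- if (is.null(mask)) NULL else maskChannel(mask, ch)
    filt <- bandpassSlow(x, fs)
    cands <- extractCandidates(filt, fs, m)
    slowTh <- withCallingHandlers(
      computeSlowThresholds(cands, negativePercentile, positivePercentile),
      warning = function(w) {
        warning("channel ", ch, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    slow <- classifySlowWaves(cands, slowTh, soDuration,
                              deltaMaxDuration, deltaMinDuration)
    env <- spindleEnvelope(x, fs)
    spTh <- computeSpindleThresholds(env, m)
    sp <- detectSpindles(env, spTh, fs, m, minSpindleDuration)
    if (nrow(slow)) slowAll[[ch]] <- cbind(channel = ch, slow)
    if (nrow(sp)) spAll[[ch]] <- cbind(channel = ch, sp)
    thAll[[ch]] <- list(slow = slowTh, spindle = spTh)
  }
  emptySlow <- data.frame(channel = character(0), peak_time = numeric(0),
                          peak_amp = numeric(0), trough_time = numeric(0),
                          trough_amp = numeric(0), kind = character(0),
                          up_state_time = numeric(0))
  emptySp <- data.frame(channel = character(0), onset = numeric(0),
                        offset = numeric(0), peak_time = numeric(0),
                        peak_env = numeric(0))
  slow <- if (length(slowAll)) do.call(rbind, c(slowAll, make.row.names = FALSE))
          else emptySlow
  sp <- if (length(spAll)) do.call(rbind, c(spAll, make.row.names = FALSE))
        else emptySp
  list(slow = slow, spindles = sp, thresholds = thAll)
}

#' Write / read detected events as a BED-like annotation
#'
#' Tab-delimited with columns \code{channel}, \code{start_ms}, \code{end_ms}
#' (0-based half-open, milliseconds), \code{type}
#' (\code{SO}, \code{DELTA}, \code{SPINDLE}, \code{SO_SPINDLE},
#' \code{DELTA_SPINDLE}) and \code{amplitude}. Slow waves use peak and trough
#' times as start/end; nested events use the slow UP state and spindle peak.
#'
#' @param detection list from [detectEvents()].
#' @param nested optional data.frame from [nestSpindles()].
#' @param path output file.
#' @return the path, invisibly (\code{writeEvents}); a data.frame
#'   (\code{readEvents}).
#' @export
writeEvents <- function(detection, path, nested = NULL) {
  ms <- function(x) as.integer(round(x * 1000))
  slow <- detection$slow; sp <- detection$spindles
  rows <- rbind(
    if (nrow(slow)) data.frame(channel = slow$channel,
                               start_ms = ms(slow$peak_time),
                               end_ms = ms(slow$trough_time),
                               type = ifelse(slow$kind == "SO", "SO", "DELTA"),
                               amplitude = slow$trough_amp),
    if (nrow(sp)) data.frame(channel = sp$channel, start_ms = ms(sp$onset),
                             end_ms = ms(sp$offset), type = "SPINDLE",
                             amplitude = sp$peak_env),
    if (!is.null(nested) && nrow(nested))
      data.frame(channel = nested$channel,
                 start_ms = ms(nested$up_state_time),
                 end_ms = ms(nested$spindle_peak_time),
                 type = ifelse(nested$slow_kind == "SO",
                               "SO_SPINDLE", "DELTA_SPINDLE"),
                 amplitude = NA_real_))
  if (is.null(rows))
    rows <- data.frame(channel = character(0), start_ms = integer(0),
                       end_ms = integer(0), type = character(0),
                       amplitude = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric"))
}
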