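#' Read a multichannel EEG recording
#'
#' Reads either an EDF file (continuous recordings, 16-bit) or the package's
#' plain-text delimited matrix format: an optional first line
#' \code{#fs<TAB><rate>}, a header row of channel labels, then one row of
#' microvolt amplitudes per sample. Channel labels are normalized to
#' upper-case 10-20 names (a leading \code{"EEG "} prefix is dropped).
#'
#' @param path file to read.
#' @param format \code{"edf"} or \code{"delimited_matrix"}; by default guessed
#'   from the file extension.
#' @param fs sampling rate override for delimited files lacking a
#'   \code{#fs} line.
#' @return an \linkS4class{EEGRecording} with \code{reference = "raw"}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#fs\t4", "C3\tC4", "1\t2", "3\t4"), tf)
#' rec <- loadRecording(tf)
#' channelNames(rec)
#' @export
loadRecording <- function(path, format = c("auto", "edf", "delimited_matrix"),
                          fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited_matrix"
  }
  if (format == "edf") return(readEDF(path))

  lines1 <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#fs", lines1[1])) {
    fs <- as.numeric(strsplit(lines1[1], "\t")[[1]][2])
    skip <- 1L
  }
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    stop("delimited recording needs a sampling rate (#fs line or fs=)")
  dat <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           check.names = FALSE)
  mat <- as.matrix(dat)
  storage.mode(mat) <- "double"
  labels <- normalizeChannelLabels(colnames(dat))
  colnames(mat) <- labels
  new("EEGRecording", samples = mat, fs = fs, channels = labels,
      reference = "raw")
}

normalizeChannelLabels <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^EEG +", "", x)
  trimws(x)
}

edfAscii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

edfField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read a continuous EDF file
#'
#' Minimal EDF reader for continuous recordings. All signals must share one
#' sampling rate; otherwise a format error names the offending channels.
#'
#' @param path EDF file.
#' @return an \linkS4class{EEGRecording}.
#' @keywords internal
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edfAscii(con, 8)                     # version
  edfAscii(con, 80); edfAscii(con, 80) # patient / recording id
  edfAscii(con, 8); edfAscii(con, 8)   # start date / time
  edfAscii(con, 8)                     # header bytes
  edfAscii(con, 44)                    # reserved
  nRec <- as.integer(edfAscii(con, 8))
  recDur <- as.numeric(edfAscii(con, 8))
  ns <- as.integer(edfAscii(con, 4))
  rd <- function(w) vapply(seq_len(ns), function(i) edfAscii(con, w), "")
  labels <- normalizeChannelLabels(rd(16))
  rd(80); rd(8)                                 # transducer, physical dim
  physMin <- as.numeric(rd(8)); physMax <- as.numeric(rd(8))
  digMin  <- as.numeric(rd(8)); digMax  <- as.numeric(rd(8))
  rd(80)                                        # prefilter
  spr <- as.integer(rd(8))                      # samples per record
  rd(32)                                        # reserved
  if (length(unique(spr)) != 1L) {
    fsPerCh <- spr / recDur
    bad <- labels[spr != spr[1]]
    stop("mixed sampling rates in EDF (",
         paste(labels, fsPerCh, sep = "=", collapse = ", "),
         "); offending channels: ", paste(bad, collapse = ", "))
  }
  fs <- spr[1] / recDur
  out <- matrix(0, nrow = nRec * spr[1], ncol = ns)
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      out[idx, s] <- physMin[s] + gain[s] * (dig - digMin[s])
    }
  }
  colnames(out) <- labels
  new("EEGRecording", samples = out, fs = fs, channels = labels,
      reference = "raw")
}

#' Write a recording to disk
#'
#' \code{writeEDF} writes a minimal continuous EDF (1-s data records, 16-bit;
#' requires an integer sampling rate; the tail is truncated to whole records).
#' \code{writeRecordingDelimited} writes the plain-text matrix format that
#' [loadRecording()] reads back.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- samplingRate(rec)
  if (fs != round(fs)) stop("writeEDF requires an integer sampling rate")
  x <- samples(rec)
  nRec <- floor(nrow(x) / fs)
  if (nRec < 1) stop("recording shorter than one EDF data record")
  x <- x[seq_len(nRec * fs), , drop = FALSE]
  ns <- ncol(x)
  physMin <- floor(apply(x, 2, min)); physMax <- ceiling(apply(x, 2, max))
  same <- physMax <= physMin
  physMax[same] <- physMin[same] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(edfField(x, w), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(nRec, 8); wr("1", 8); wr(ns, 4)
  for (lab in channelNames(rec)) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(physMin[i], 8)
  for (i in seq_len(ns)) wr(physMax[i], 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[idx, s] - physMin[s]) / gain[s] + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname writeEDF
#' @export
writeRecordingDelimited <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fs\t", samplingRate(rec)), con)
  writeLines(paste(channelNames(rec), collapse = "\t"), con)
  utils::write.table(format(samples(rec), trim = TRUE, digits = 8),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
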