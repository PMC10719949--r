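# Shared fixtures: everything is generated in code, nothing on disk.

# A tiny recording from a samples-by-channels matrix.
makeRecording <- function(mat, fs, channels = colnames(mat),
                          reference = "raw") {
  colnames(mat) <- channels
  new("EEGRecording", samples = mat, fs = fs, channels = channels,
      reference = reference)
}

# All-true mask matching a recording.
fullMask <- function(rec) {
  new("AnalysisMask",
      keep = matrix(TRUE, nrow(samples(rec)), ncol(samples(rec))),
      fs = samplingRate(rec), channels = channelNames(rec))
}

allNremHypnogram <- function(rec) {
  nEp <- ceiling(nrow(samples(rec)) / samplingRate(rec) / 30)
  new("Hypnogram", epochLength = 30, stages = rep("NREM", nEp))
}

# Independent brute-force slow-wave candidate scan (the oracle): explicit
# sample-by-sample sign-change bookkeeping, no vectorized tricks shared with
# the implementation.
bruteCandidates <- function(x, fs) {
  n <- length(x)
  p2n <- integer(0); n2p <- integer(0)
  for (i in seq_len(n - 1)) {
    if (x[i] > 0 && x[i + 1] <= 0) p2n <- c(p2n, i)
    if (x[i] <= 0 && x[i + 1] > 0) n2p <- c(n2p, i)
  }
  rows <- list()
  for (c0 in p2n) {
    prev <- n2p[n2p < c0]; nxt <- n2p[n2p > c0]
    if (!length(prev) || !length(nxt)) next
    prev <- max(prev); nxt <- min(nxt)
    posSpan <- (prev + 1):c0
    negSpan <- (c0 + 1):nxt
    pk <- posSpan[1]; for (j in posSpan) if (x[j] > x[pk]) pk <- j
    tr <- negSpan[1]; for (j in negSpan) if (x[j] < x[tr]) tr <- j
    rows[[length(rows) + 1]] <- data.frame(
      peak_time = (pk - 1) / fs, peak_amp = x[pk],
      trough_time = (tr - 1) / fs, trough_amp = x[tr])
  }
  if (!length(rows))
    return(data.frame(peak_time = numeric(0), peak_amp = numeric(0),
                      trough_time = numeric(0), trough_amp = numeric(0)))
  do.call(rbind, rows)
}

# Small synthetic subject used by several suites.
smallSpec <- function(seed = 42, durationMin = 6, asymmetry = 1, ...) {
  simulationSpec(durationMin = durationMin,
                 channels = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
                 asymmetry = asymmetry, seed = seed, ...)
}

# LI computed from ground-truth event counts (left / right hemisphere).
truthLI <- function(truth, type) {
  hemi <- hemisphereOf(truth$channel)
  isNested <- !is.na(truth$nested_kind)
  sel <- switch(type,
    SO = truth$type == "SO",
    delta = truth$type == "delta",
    spindle = truth$type == "spindle",
    SO_spindle = truth$type == "spindle" & isNested &
      truth$nested_kind == "SO",
    delta_spindle = truth$type == "spindle" & isNested &
      truth$nested_kind == "delta")
  sum(sel & hemi == "left") / sum(sel & hemi == "right")
}
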