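#' Construct a synthetic NREM-EEG simulation specification
#'
#' Defaults emulate clean referential NREM sleep EEG in which genuine slow
#' waves dominate the slow band (the regime the percentile-threshold
#' detection rules presume): 19-channel 10-20 montage, 1/f^2.5 background at
#' 6 uV RMS, slow-oscillation / delta-wave / isolated-spindle rates of
#' 2.8 / 4.8 / 4 events per minute, deep-sleep amplitudes (SO peaks 45-70 uV
#' over -100..-70 uV troughs, delta peaks 8-14 uV over the same trough
#' range, 20 uV spindles), a 0.3 probability that a slow event hosts a
#' spindle inside the -0.5..+1.0 s coupling window, and no hemispheric
#' asymmetry. Slow-wave templates are half-sine pairs (positive peak then
#' negative trough, peak-to-trough lag 150-400 ms) so injected amplitudes
#' and timings are exactly known; spindles are Hann-windowed 12 Hz tones of
#' 0.8-1.2 s. Injected slow-event peaks keep at least 2 s spacing on a
#' quasi-rhythmic (jittered-grid) timeline with rate-exact counts.
#'
#' @param fs sampling rate (Hz), >= 64.
#' @param durationMin duration in minutes.
#' @param channels 10-20 labels (odd digit left, even right).
#' @param alpha background spectral exponent.
#' @param backgroundRms background RMS (microvolts).
#' @param soRate,deltaRate,spindleRate events/min/channel (spindleRate is the
#'   isolated, non-nested spindle rate).
#' @param soPeakAmp,soTroughAmp,deltaPeakAmp,deltaTroughAmp length-2
#'   amplitude ranges (microvolts).
#' @param spindleFreq,spindleDuration,spindleAmp spindle morphology.
#' @param nestingProb probability a slow event hosts a spindle; single number
#'   or named \code{c(so=, delta=)}.
#' @param nestingAsymmetry per-kind multiplier of the nesting probability on
#'   the affected hemisphere, named \code{c(so=, delta=)}.
#' @param couplingWindow nesting lag window (s).
#' @param asymmetry event-rate multiplier on \code{asymmetryHemisphere}.
#' @param asymmetryHemisphere \code{"left"} or \code{"right"}.
#' @param seed integer controlling the whole dataset.
#' @return a \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(fs = 200, durationMin = 10,
                           channels = c("FP1", "FP2", "F7", "F3", "FZ", "F4",
                                        "F8", "T3", "C3", "CZ", "C4", "T4",
                                        "T5", "P3", "PZ", "P4", "T6",
                                        "O1", "O2"),
                           alpha = 2.5, backgroundRms = 6,
                           soRate = 2.8, deltaRate = 4.8, spindleRate = 4,
                           soPeakAmp = c(45, 70), soTroughAmp = c(-100, -70),
                           deltaPeakAmp = c(8, 14),
                           deltaTroughAmp = c(-100, -70),
                           spindleFreq = 12, spindleDuration = c(0.8, 1.2),
                           spindleAmp = 20,
                           nestingProb = c(so = 0.3, delta = 0.3),
                           nestingAsymmetry = c(so = 1, delta = 1),
                           couplingWindow = c(-0.5, 1.0),
                           asymmetry = 1, asymmetryHemisphere = "left",
                           seed = 1) {
  if (length(nestingProb) == 1) nestingProb <- c(so = unname(nestingProb),
                                                 delta = unname(nestingProb))
  if (length(nestingAsymmetry) == 1)
    nestingAsymmetry <- c(so = unname(nestingAsymmetry),
                          delta = unname(nestingAsymmetry))
  new("SimulationSpec", fs = fs, durationMin = durationMin,
      channels = normalizeChannelLabels(channels), alpha = alpha,
      backgroundRms = backgroundRms, soRate = soRate, deltaRate = deltaRate,
      spindleRate = spindleRate, soPeakAmp = soPeakAmp,
      soTroughAmp = soTroughAmp, deltaPeakAmp = deltaPeakAmp,
      deltaTroughAmp = deltaTroughAmp, spindleFreq = spindleFreq,
      spindleDuration = spindleDuration, spindleAmp = spindleAmp,
      nestingProb = nestingProb, nestingAsymmetry = nestingAsymmetry,
      couplingWindow = couplingWindow, asymmetry = asymmetry,
      asymmetryHemisphere = asymmetryHemisphere, seed = seed)
}

# One channel of 1/f^alpha noise via spectral shaping, scaled to exact RMS.
pinkNoise <- function(n, alpha, rms) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  coef <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- coef
  spec[n:(n - nf + 1)] <- Conj(coef)
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = stats::rnorm(1) * amp[nf])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

#' Generate the 1/f background recording
#'
#' Independent 1/f^alpha noise per channel at the target RMS, reproducible
#' under the spec's seed.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return an \linkS4class{EEGRecording} with \code{reference = "raw"}.
#' @export
generateBackground <- function(spec) {
  set.seed(spec@seed)
  n <- round(spec@durationMin * 60 * spec@fs)
  mat <- vapply(seq_along(spec@channels),
                function(i) pinkNoise(n, spec@alpha, spec@backgroundRms),
                numeric(n))
  colnames(mat) <- spec@channels
  new("EEGRecording", samples = mat, fs = spec@fs, channels = spec@channels,
      reference = "raw")
}

# Additive waveform templates ---------------------------------------------

# Biphasic slow wave: positive half-sine then negative half-sine, each of
# duration `lag` seconds; peak at the anchor, trough `lag` later.
slowTemplate <- function(fs, lag, peakAmp, troughAmp) {
  d <- round(lag * fs)
  u <- seq_len(d) / d
  c(peakAmp * sin(pi * u), troughAmp * sin(pi * u))
}

# Hann-windowed tone, envelope peak at the center.
spindleTemplate <- function(fs, duration, freq, amp) {
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  amp * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))) *
    sin(2 * pi * freq * t)
}

addAt <- function(x, start, w) {
  idx <- start:(start + length(w) - 1L)
  ok <- idx >= 1L & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + w[ok]
  x
}

# Round to an integer, carrying the fractional part as a Bernoulli draw so
# expected counts match non-integer rate x duration products.
roundStochastic <- function(x) {
  n <- floor(x)
  n + as.integer(stats::runif(1) < (x - n))
}

# n event times on [lo, hi]: a regular grid with uniform jitter, spacing
# clamped to >= minGap (events beyond capacity are dropped with a warning).
jitteredGrid <- function(n, lo, hi, minGap) {
  if (n <= 0) return(numeric(0))
  p <- (hi - lo) / n
  if (p < minGap) {
    warning("event count ", n, " cannot respect ", minGap,
            " s spacing on ", round(hi - lo), " s; truncating")
    n <- floor((hi - lo) / minGap)
    p <- (hi - lo) / n
  }
  jit <- max(0, (p - minGap) / 2) * 0.95
  sort(lo + (seq_len(n) - 0.5) * p + stats::runif(n, -jit, jit))
}

# Hard-core renewal process on [lo, hi]: exponential gaps plus a dead time,
# with the exponential mean chosen so the marginal intensity equals `rate`
# exactly (a thinned Poisson process would lose proportionally more events
# at higher rates and bias any rate ratio toward 1). `rate` in events/s.
renewalTimes <- function(rate, lo, hi, minGap) {
  if (rate <= 0) return(numeric(0))
  mu <- 1 / rate - minGap
  if (mu <= 0) {
    warning("rate ", signif(rate * 60, 3),
            "/min cannot respect ", minGap, " s spacing; saturating")
    mu <- 1e-6
  }
  t <- numeric(0)
  cur <- lo + stats::rexp(1, 1 / mu)
  while (cur <= hi) {
    t <- c(t, cur)
    cur <- cur + minGap + stats::rexp(1, 1 / mu)
  }
  t
}

# Renewal times drawn on the complement of exclusion intervals: the renewal
# process runs on the concatenated allowed axis and is mapped back, so the
# realized rate per unit of total time stays `rate` and gaps can only widen.
renewalTimesAvoiding <- function(rate, lo, hi, minGap, exclude) {
  if (is.null(exclude) || !nrow(exclude))
    return(renewalTimes(rate, lo, hi, minGap))
  ex <- exclude[order(exclude[, 1]), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(ex[i, 1], lo); b <- min(ex[i, 2], hi)
    if (a >= b) next
    if (length(merged) && a <= merged[[length(merged)]][2])
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], b)
    else merged[[length(merged) + 1L]] <- c(a, b)
  }
  starts <- lo; ends <- numeric(0)
  for (m in merged) { ends <- c(ends, m[1]); starts <- c(starts, m[2]) }
  ends <- c(ends, hi)
  len <- pmax(ends - starts, 0)
  # rescale so the realized intensity per unit of *total* time stays `rate`
  # even though placement is squeezed into the allowed intervals
  rateAllowed <- rate * (hi - lo) / max(sum(len), 1e-9)
  tAllowed <- renewalTimes(rateAllowed, 0, sum(len), minGap)
  cum <- cumsum(c(0, len))
  vapply(tAllowed, function(ta) {
    k <- findInterval(ta, cum)
    starts[k] + (ta - cum[k])
  }, numeric(1))
}

#' Inject ground-truth events into a background recording
#'
#' Adds slow-wave and spindle waveforms at the times of a hard-core renewal
#' process (exponential gaps plus a 2 s dead time between slow-event peaks,
#' with the gap mean chosen so the realized intensity equals the configured
#' rate exactly at any asymmetry factor), draws amplitudes from the spec's
#' ranges, nests spindles at uniform lags inside the coupling window with the
#' spec's probability, scales per-hemisphere rates by the asymmetry factor,
#' and returns the modified recording together with a ground-truth event
#' list. Isolated spindles are kept clear of every slow event's coupling
#' window (margin 0.2 s) so the realized coupling fraction tracks
#' \code{nestingProb}; spindle peaks keep 1.5 s spacing so envelope runs do
#' not merge; events are kept 3 s clear of the recording edges.
#'
#' @param rec background from [generateBackground()].
#' @param spec the same \linkS4class{SimulationSpec}.
#' @return list with \code{recording} (an \linkS4class{EEGRecording}) and
#'   \code{truth}: data.frame with \code{channel}, \code{type} (SO, delta,
#'   spindle), \code{peak_time}, \code{trough_time}, \code{peak_amp},
#'   \code{trough_amp}, \code{onset}, \code{offset}, \code{nested_kind},
#'   \code{host_up_time} (spindles nested to a slow event reference its
#'   UP-state time).
#' @export
injectEvents <- function(rec, spec) {
  set.seed(spec@seed + 1L)
  fs <- samplingRate(rec)
  n <- nrow(samples(rec))
  totalS <- n / fs
  edge <- 3
  mat <- samples(rec)
  truth <- list()
  hemi <- hemisphereOf(spec@channels)

  for (ci in seq_along(spec@channels)) {
    ch <- spec@channels[ci]
    scale <- if (hemi[ci] == spec@asymmetryHemisphere) spec@asymmetry else 1
    x <- mat[, ci]

    # slow events of both kinds on one quasi-rhythmic timeline: fixed counts
    # at the target rates, placed on a jittered grid with >= 2 s peak
    # spacing. NREM slow waves come in trains more regular than Poisson;
    # keeping per-channel counts tight also keeps the data-derived
    # percentile thresholds stable on short recordings.
    nSO <- roundStochastic(spec@soRate * scale * spec@durationMin)
    nDe <- roundStochastic(spec@deltaRate * scale * spec@durationMin)
    tAll <- jitteredGrid(nSO + nDe, edge, totalS - edge - 1.5, 2)
    kinds <- sample(c(rep("SO", nSO), rep("delta", nDe)))[seq_along(tAll)]

    spPeaks <- numeric(0)   # all spindle peaks on this channel
    chTruth <- list()
    for (i in seq_along(tAll)) {
      kind <- kinds[i]
      lag <- stats::runif(1, 0.15, 0.40)
      if (kind == "SO") {
        pk <- stats::runif(1, spec@soPeakAmp[1], spec@soPeakAmp[2])
        tr <- stats::runif(1, spec@soTroughAmp[1], spec@soTroughAmp[2])
      } else {
        pk <- stats::runif(1, spec@deltaPeakAmp[1], spec@deltaPeakAmp[2])
        tr <- stats::runif(1, spec@deltaTroughAmp[1], spec@deltaTroughAmp[2])
      }
      w <- slowTemplate(fs, lag, pk, tr)
      start <- round((tAll[i] - lag / 2) * fs) + 1L
      x <- addAt(x, start, w)
      peakT <- (start - 1 + round(lag * fs) / 2) / fs
      troughT <- peakT + lag
      chTruth[[length(chTruth) + 1L]] <- data.frame(
        channel = ch, type = kind, peak_time = peakT, trough_time = troughT,
        peak_amp = pk, trough_amp = tr, onset = NA_real_, offset = NA_real_,
        nested_kind = NA_character_, host_up_time = NA_real_)

      pNest <- unname(spec@nestingProb[tolower(kind)]) *
        (if (hemi[ci] == spec@asymmetryHemisphere)
           unname(spec@nestingAsymmetry[tolower(kind)]) else 1)
      pNest <- min(pNest, 1)
      if (stats::runif(1) < pNest) {
        placed <- FALSE
        for (try in 1:10) {
          lagSp <- stats::runif(1, spec@couplingWindow[1],
                                spec@couplingWindow[2])
          center <- peakT + lagSp
          if (center > edge && center < totalS - edge &&
              (!length(spPeaks) || min(abs(spPeaks - center)) >= 1.5)) {
            placed <- TRUE
            break
          }
        }
        if (placed) {
          dur <- stats::runif(1, spec@spindleDuration[1],
                              spec@spindleDuration[2])
          w <- spindleTemplate(fs, dur, spec@spindleFreq, spec@spindleAmp)
          start <- round((center - dur / 2) * fs) + 1L
          x <- addAt(x, start, w)
          spPeaks <- c(spPeaks, center)
          chTruth[[length(chTruth) + 1L]] <- data.frame(
            channel = ch, type = "spindle", peak_time = center,
            trough_time = NA_real_, peak_amp = spec@spindleAmp,
            trough_amp = NA_real_, onset = center - dur / 2,
            offset = center + dur / 2, nested_kind = kind,
            host_up_time = peakT)
        }
      }
    }

    # isolated spindles, clear of every slow event's coupling window and of
    # already-placed nested spindles (exclusion zones, not rejection, so the
    # realized rate is unbiased on both hemispheres)
    exclude <- rbind(
      if (length(tAll)) cbind(tAll + spec@couplingWindow[1] - 0.2,
                              tAll + spec@couplingWindow[2] + 0.2),
      if (length(spPeaks)) cbind(spPeaks - 1.5, spPeaks + 1.5))
    tSp <- renewalTimesAvoiding(spec@spindleRate * scale / 60,
                                edge, totalS - edge, 1.5, exclude)
    for (tc in tSp) {
      if (length(spPeaks) && min(abs(spPeaks - tc)) < 1.5) next
      dur <- stats::runif(1, spec@spindleDuration[1], spec@spindleDuration[2])
      w <- spindleTemplate(fs, dur, spec@spindleFreq, spec@spindleAmp)
      start <- round((tc - dur / 2) * fs) + 1L
      x <- addAt(x, start, w)
      spPeaks <- c(spPeaks, tc)
      chTruth[[length(chTruth) + 1L]] <- data.frame(
        channel = ch, type = "spindle", peak_time = tc,
        trough_time = NA_real_, peak_amp = spec@spindleAmp,
        trough_amp = NA_real_, onset = tc - dur / 2, offset = tc + dur / 2,
        nested_kind = NA_character_, host_up_time = NA_real_)
    }
    mat[, ci] <- x
    if (length(chTruth)) truth[[ch]] <- do.call(rbind, chTruth)
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
    else data.frame(channel = character(0), type = character(0),
                    peak_time = numeric(0), trough_time = numeric(0),
                    peak_amp = numeric(0), trough_amp = numeric(0),
                    onset = numeric(0), offset = numeric(0),
                    nested_kind = character(0), host_up_time = numeric(0))
  truth <- truth[order(truth$channel, truth$peak_time), ]
  rownames(truth) <- NULL
  out <- rec
  out@samples <- mat
  list(recording = out, truth = truth)
}

#' Simulate a complete synthetic subject
#'
#' Background plus injected events in one call.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return list with \code{recording} and \code{truth} (see
#'   [injectEvents()]).
#' @export
simulateSubject <- function(spec) {
  injectEvents(generateBackground(spec), spec)
}

#' Write a synthetic dataset to disk
#'
#' Emits the recording (EDF, or the delimited text format), an all-NREM
#' hypnogram covering it, a groups/run YAML config and the ground-truth
#' annotations (tab-delimited).
#'
#' @param rec recording to write.
#' @param truth ground-truth data.frame from [injectEvents()].
#' @param outdir output directory (created if needed).
#' @param format \code{"edf"} or \code{"delimited"}.
#' @return named character vector of the files written.
#' @export
emitDataset <- function(rec, truth, outdir, format = c("edf", "delimited")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  recPath <- file.path(outdir,
                       if (format == "edf") "recording.edf" else "recording.tsv")
  if (format == "edf") writeEDF(rec, recPath)
  else writeRecordingDelimited(rec, recPath)
  nEp <- ceiling(nrow(samples(rec)) / samplingRate(rec) / 30)
  hyp <- new("Hypnogram", epochLength = 30, stages = rep("NREM", nEp))
  hypPath <- file.path(outdir, "hypnogram.tsv")
  writeHypnogram(hyp, hypPath)
  cfgPath <- file.path(outdir, "groups.yaml")
  writeGroupsConfig(list(
    reference = "none",
    left = as.list(channelNames(rec)[hemisphereOf(channelNames(rec)) == "left"]),
    right = as.list(channelNames(rec)[hemisphereOf(channelNames(rec)) == "right"]),
    medication_group = "healthy"), cfgPath)
  gtPath <- file.path(outdir, "ground_truth.tsv")
  utils::write.table(truth, gtPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(recording = recPath, hypnogram = hypPath, config = cfgPath,
    ground_truth = gtPath)
}
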