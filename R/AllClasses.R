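#' @import methods
NULL

#' Multichannel scalp EEG recording
#'
#' Container for a continuous multichannel EEG recording: a samples-by-channels
#' amplitude matrix (microvolts), the common sampling rate, ordered 10-20
#' channel labels and the referencing state.
#'
#' @slot samples numeric matrix, one column per channel, one row per sample
#'   (microvolts).
#' @slot fs sampling rate in Hz, identical for all channels.
#' @slot channels character vector of upper-case 10-20 labels, one per column.
#' @slot reference one of \code{"raw"}, \code{"auricle_average"},
#'   \code{"linked_mastoids"}.
#'
#' @seealso [loadRecording()], [applyReference()]
#' @export
setClass("EEGRecording",
  representation(
    samples   = "matrix",
    fs        = "numeric",
    channels  = "character",
    reference = "character"
  ),
  prototype(reference = "raw")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@samples) != length(object@channels))
    msg <- c(msg, "one channel label per sample column required")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (!object@reference %in% c("raw", "auricle_average", "linked_mastoids"))
    msg <- c(msg, "unknown reference scheme")
  if (length(msg)) msg else TRUE
})

#' Sleep-stage hypnogram in 30-s epochs
#'
#' Per-epoch sleep-stage labels. Stages come from the closed vocabulary
#' \code{W, N1, N2, N3, R, NREM}; by convention N1/N2/N3 collapse to NREM
#' when the mask is built (configurable there).
#'
#' @slot epochLength epoch duration in seconds (30 by convention).
#' @slot stages character vector of per-epoch stage codes.
#' @export
setClass("Hypnogram",
  representation(epochLength = "numeric", stages = "character"),
  prototype(epochLength = 30)
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  bad <- setdiff(unique(object@stages), c("W", "N1", "N2", "N3", "R", "NREM"))
  if (length(bad))
    msg <- c(msg, paste0("unknown stage codes: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-sample analysis mask
#'
#' Logical samples-by-channels matrix: TRUE where a sample is both inside an
#' NREM epoch and artifact-free on that channel. Houses the denominator of
#' every density (retained NREM minutes per channel).
#'
#' @slot keep logical matrix, same dimensions as the recording's samples.
#' @slot fs sampling rate in Hz.
#' @slot channels channel labels matching the mask columns.
#' @export
setClass("AnalysisMask",
  representation(keep = "matrix", fs = "numeric", channels = "character")
)

setValidity("AnalysisMask", function(object) {
  msg <- character()
  if (!is.logical(object@keep)) msg <- c(msg, "keep must be logical")
  if (ncol(object@keep) != length(object@channels))
    msg <- c(msg, "one channel label per mask column required")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Electrode group assignment
#'
#' For stroke subjects: perilesional (stroke) electrodes, their mirrored
#' contralateral counterparts (CM) and the remaining contralateral electrodes
#' (CNM). For healthy subjects: left/right hemisphere sets. The medication
#' group tags the subject for cohort statistics.
#'
#' @slot stroke labels of electrodes over the perilesional region.
#' @slot contralateralMirror mirrored contralateral (CM) labels.
#' @slot contralateralNonMirror remaining contralateral (CNM) labels.
#' @slot left,right hemisphere label sets (healthy subjects).
#' @slot medicationGroup one of \code{"group1_propofol"},
#'   \code{"group2_levetiracetam"}, \code{"group3_other"}, \code{"healthy"}.
#' @export
setClass("ElectrodeGroups",
  representation(
    stroke                 = "character",
    contralateralMirror    = "character",
    contralateralNonMirror = "character",
    left                   = "character",
    right                  = "character",
    medicationGroup        = "character"
  ),
  prototype(medicationGroup = "healthy")
)

setValidity("ElectrodeGroups", function(object) {
  msg <- character()
  if (length(intersect(object@stroke,
                       c(object@contralateralMirror, object@contralateralNonMirror))))
    msg <- c(msg, "stroke electrodes overlap contralateral sets")
  if (length(intersect(object@contralateralMirror, object@contralateralNonMirror)))
    msg <- c(msg, "CM and CNM electrode sets overlap")
  if (length(intersect(object@left, object@right)))
    msg <- c(msg, "left and right electrode sets overlap")
  if (!object@medicationGroup %in%
      c("group1_propofol", "group2_levetiracetam", "group3_other", "healthy"))
    msg <- c(msg, "unknown medication group")
  if (length(msg)) msg else TRUE
})

#' Synthetic NREM-EEG simulation parameters
#'
#' Everything the generator needs: 1/f background, per-channel event rates,
#' waveform amplitude ranges, spindle morphology, nesting probability within
#' the coupling window, and a hemispheric asymmetry factor. A single integer
#' seed controls the entire dataset.
#'
#' Rates are events per minute per channel before the asymmetry factor is
#' applied; \code{asymmetry} multiplies all event rates on
#' \code{asymmetryHemisphere}. \code{nestingProb} is the probability that a
#' slow event receives a spindle whose envelope peak lag is uniform in the
#' coupling window; \code{nestingAsymmetry} additionally scales that
#' probability per slow-wave kind on the affected hemisphere.
#'
#' @slot fs sampling rate (Hz).
#' @slot durationMin recording duration (minutes).
#' @slot channels 10-20 channel labels (odd digit = left, even = right).
#' @slot alpha background spectral exponent (power ~ 1/f^alpha).
#' @slot backgroundRms background RMS amplitude (microvolts).
#' @slot soRate,deltaRate,spindleRate events/min/channel (spindleRate counts
#'   isolated, non-nested spindles).
#' @slot soPeakAmp,soTroughAmp,deltaPeakAmp,deltaTroughAmp amplitude ranges
#'   (microvolts, length-2 min/max; troughs negative).
#' @slot spindleFreq spindle frequency (Hz).
#' @slot spindleDuration spindle duration range (seconds).
#' @slot spindleAmp spindle peak amplitude (microvolts).
#' @slot nestingProb probability a slow event hosts a spindle (named
#'   \code{c(so=, delta=)} or a single number for both).
#' @slot nestingAsymmetry per-kind multiplier of nesting probability on the
#'   affected hemisphere, named \code{c(so=, delta=)}.
#' @slot couplingWindow nesting lag window (seconds, relative to UP state).
#' @slot asymmetry multiplicative rate factor on the affected hemisphere.
#' @slot asymmetryHemisphere \code{"left"} or \code{"right"}.
#' @slot seed integer seed for the whole dataset.
#' @seealso [simulationSpec()], [simulateSubject()]
#' @export
setClass("SimulationSpec",
  representation(
    fs                  = "numeric",
    durationMin         = "numeric",
    channels            = "character",
    alpha               = "numeric",
    backgroundRms       = "numeric",
    soRate              = "numeric",
    deltaRate           = "numeric",
    spindleRate         = "numeric",
    soPeakAmp           = "numeric",
    soTroughAmp         = "numeric",
    deltaPeakAmp        = "numeric",
    deltaTroughAmp      = "numeric",
    spindleFreq         = "numeric",
    spindleDuration     = "numeric",
    spindleAmp          = "numeric",
    nestingProb         = "numeric",
    nestingAsymmetry    = "numeric",
    couplingWindow      = "numeric",
    asymmetry           = "numeric",
    asymmetryHemisphere = "character",
    seed                = "numeric"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@fs < 64) msg <- c(msg, "fs must be >= 64 Hz (spindle band)")
  if (object@durationMin <= 0) msg <- c(msg, "durationMin must be positive")
  if (any(c(object@soRate, object@deltaRate, object@spindleRate) < 0))
    msg <- c(msg, "event rates must be >= 0")
  if (any(object@nestingProb < 0 | object@nestingProb > 1))
    msg <- c(msg, "nestingProb must lie in [0, 1]")
  if (any(object@asymmetry <= 0)) msg <- c(msg, "asymmetry must be > 0")
  if (!object@asymmetryHemisphere %in% c("left", "right"))
    msg <- c(msg, "asymmetryHemisphere must be 'left' or 'right'")
  if (min(object@soPeakAmp) <= max(object@deltaPeakAmp))
    msg <- c(msg, "soPeakAmp range must lie above deltaPeakAmp range")
  if (length(object@couplingWindow) != 2L ||
      object@couplingWindow[1] >= object@couplingWindow[2])
    msg <- c(msg, "couplingWindow must be an increasing length-2 vector")
  if (length(msg)) msg else TRUE
})
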