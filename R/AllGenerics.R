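#' Accessors for sleeposc S4 classes
#'
#' @param object an \linkS4class{EEGRecording}, \linkS4class{AnalysisMask} or
#'   \linkS4class{Hypnogram}.
#' @return \code{samples}: the numeric sample matrix; \code{samplingRate}: Hz;
#'   \code{channelNames}: character labels; \code{referenceScheme}: the
#'   referencing state; \code{nremMinutes}: named numeric, retained NREM
#'   minutes per channel; \code{nEpochs}: number of hypnogram epochs.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("referenceScheme", function(object) standardGeneric("referenceScheme"))

#' @rdname accessors
#' @export
setGeneric("nremMinutes", function(object) standardGeneric("nremMinutes"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setMethod("samples", "EEGRecording", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("referenceScheme", "EEGRecording", function(object) object@reference)

#' @rdname accessors
#' @export
setMethod("samplingRate", "AnalysisMask", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("channelNames", "AnalysisMask", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("nremMinutes", "AnalysisMask", function(object) {
  mins <- colSums(object@keep) / (object@fs * 60)
  names(mins) <- object@channels
  mins
})

#' @rdname accessors
#' @export
setMethod("nEpochs", "Hypnogram", function(object) length(object@stages))

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", ncol(object@samples), "channels x",
      nrow(object@samples), "samples @", object@fs, "Hz\n")
  cat("  duration :", sprintf("%.1f min", nrow(object@samples) / object@fs / 60), "\n")
  cat("  reference:", object@reference, "\n")
  cat("  channels :", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(object@stages)
  cat("Hypnogram:", length(object@stages), "epochs of", object@epochLength, "s (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "AnalysisMask", function(object) {
  mins <- nremMinutes(object)
  cat("AnalysisMask:", ncol(object@keep), "channels,",
      sprintf("retained NREM %.2f-%.2f min", min(mins), max(mins)), "\n")
})

setMethod("show", "ElectrodeGroups", function(object) {
  cat("ElectrodeGroups (medication:", object@medicationGroup, ")\n")
  if (length(object@stroke)) {
    cat("  stroke:", paste(object@stroke, collapse = " "), "\n")
    cat("  CM    :", paste(object@contralateralMirror, collapse = " "), "\n")
    cat("  CNM   :", paste(object@contralateralNonMirror, collapse = " "), "\n")
  }
  if (length(object@left)) {
    cat("  left  :", paste(object@left, collapse = " "), "\n")
    cat("  right :", paste(object@right, collapse = " "), "\n")
  }
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", length(object@channels), "channels,",
      object@durationMin, "min @", object@fs, "Hz, seed", object@seed, "\n")
  cat(sprintf("  rates/min: SO %.2g, delta %.2g, spindle %.2g; nestingProb %s\n",
              object@soRate, object@deltaRate, object@spindleRate,
              paste(signif(object@nestingProb, 3), collapse = "/")))
  cat(sprintf("  background 1/f^%.2g @ %.3g uV RMS; asymmetry %.2g on %s\n",
              object@alpha, object@backgroundRms, object@asymmetry,
              object@asymmetryHemisphere))
})
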