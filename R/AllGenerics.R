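#' @rdname Recording-class
#' @param object,x a \code{Recording} (or other package object).
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname Recording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname Recording-class
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @describeIn Recording-class number of channels (rows).
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' @describeIn Recording-class number of samples (columns).
setMethod("nSamples", "Recording", function(x) ncol(x@data))

#' @describeIn Recording-class sampling rate in Hz.
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @describeIn Recording-class channel labels in file order.
setMethod("channelLabels", "Recording", function(x) x@labels)

#' @describeIn Recording-class the channels x samples matrix (microvolts).
setMethod("signalData", "Recording", function(x) {
  d <- x@data
  rownames(d) <- x@labels
  d
})

#' @describeIn Recording-class compact display.
setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat("  channels:", paste(utils::head(object@labels, 8L), collapse = ", "),
      if (length(object@labels) > 8L) "..." else "", "\n")
})

#' @rdname ICADecomposition-class
#' @param x an \code{ICADecomposition}.
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' @rdname ICADecomposition-class
#' @export
setGeneric("unmixingMatrix", function(x) standardGeneric("unmixingMatrix"))

#' @rdname ICADecomposition-class
#' @export
setGeneric("sourceMatrix", function(x) standardGeneric("sourceMatrix"))

#' @describeIn ICADecomposition-class channels x components mixing matrix.
setMethod("mixingMatrix", "ICADecomposition", function(x) x@A)

#' @describeIn ICADecomposition-class components x channels unmixing matrix.
setMethod("unmixingMatrix", "ICADecomposition", function(x) x@W)

#' @describeIn ICADecomposition-class components x samples source matrix.
setMethod("sourceMatrix", "ICADecomposition", function(x) x@S)

#' @describeIn ICADecomposition-class compact display.
#' @param object an \code{ICADecomposition}.
setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf(
    "ICADecomposition: %d components over %d channels, %d samples\n",
    nrow(object@S), nrow(object@A), ncol(object@S)))
  cat(sprintf("  converged: %s after %d passes (seed %d)\n",
              object@converged, object@nIter, object@seed))
})

#' @rdname EOGReport-class
#' @param x an \code{EOGReport}.
#' @export
setGeneric("flaggedComponents", function(x) standardGeneric("flaggedComponents"))

#' @describeIn EOGReport-class indices of components flagged as ocular.
setMethod("flaggedComponents", "EOGReport", function(x) x@flagged)

#' @describeIn EOGReport-class compact display.
#' @param object an \code{EOGReport}.
setMethod("show", "EOGReport", function(object) {
  cat(sprintf("EOGReport: %d components, weight fence %.4g\n",
              length(object@wbar), object@threshold))
  if (length(object@flagged))
    cat("  flagged:", paste(object@flagged, collapse = ", "), "\n")
  else cat("  flagged: none\n")
})

#' @rdname ArtifactWindows-class
#' @param x an \code{ArtifactWindows}.
#' @export
setGeneric("windowIntervals", function(x) standardGeneric("windowIntervals"))

#' @rdname ArtifactWindows-class
#' @export
setGeneric("windowCoverage", function(x) standardGeneric("windowCoverage"))

#' @describeIn ArtifactWindows-class two-column (start, end) matrix of
#'   half-open 1-based sample intervals.
setMethod("windowIntervals", "ArtifactWindows", function(x) x@intervals)

#' @describeIn ArtifactWindows-class fraction of samples covered.
setMethod("windowCoverage", "ArtifactWindows", function(x) x@coverage)

#' @describeIn ArtifactWindows-class compact display.
#' @param object an \code{ArtifactWindows}.
setMethod("show", "ArtifactWindows", function(object) {
  cat(sprintf("ArtifactWindows: %d interval(s), coverage %.1f%% of %d samples\n",
              nrow(object@intervals), 100 * object@coverage,
              object@nSamples))
})

#' @describeIn PeakSet-class compact display.
#' @param object a \code{PeakSet}.
setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: component %d, %d peak(s) @ %g Hz\n",
              object@component, length(object@samples), object@fs))
})

#' @rdname CleaningResult-class
#' @param x a \code{CleaningResult}.
#' @export
setGeneric("cleanedRecording", function(x) standardGeneric("cleanedRecording"))

#' @rdname CleaningResult-class
#' @export
setGeneric("componentActions", function(x) standardGeneric("componentActions"))

#' @describeIn CleaningResult-class the cleaned Recording.
setMethod("cleanedRecording", "CleaningResult", function(x) x@cleaned)

#' @describeIn CleaningResult-class per-component action labels.
setMethod("componentActions", "CleaningResult", function(x) x@actions)

#' @describeIn CleaningResult-class compact display.
#' @param object a \code{CleaningResult}.
setMethod("show", "CleaningResult", function(object) {
  cat(sprintf("CleaningResult (method %s, seed %d)\n",
              object@method, object@seed))
  tab <- table(object@actions)
  cat("  actions:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

#' @describeIn MetricsReport-class compact display.
#' @param object a \code{MetricsReport}.
setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (channel means):\n")
  m <- object@means
  cat(sprintf("  lambda %.2f%%, deltaSNR %.2f dB, RMSE %.3f uV, band MSC %.3f\n",
              m[["lambda"]], m[["deltaSNR"]], m[["rmse"]], m[["bandMSC"]]))
})
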