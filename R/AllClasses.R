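#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a channels-by-samples signal matrix in microvolts, together
#' with its sampling rate and channel labels. Sample indices are 1-based and
#' the time of sample \code{i} is \code{(i - 1) / fs} seconds.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz, strictly positive.
#' @slot labels character vector of channel names, one per row of
#'   \code{data}.
#' @slot meta free-form list of provenance notes.
#'
#' @seealso [Recording()], [readRecording()], [writeRecording()]
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", labels = "character",
                 meta = "list"),
  prototype(meta = list()))

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (nrow(object@data) < 2L)
    msg <- c(msg, "a Recording needs at least 2 channels")
  if (ncol(object@data) < 2L)
    msg <- c(msg, "a Recording needs at least 2 samples")
  if (length(object@labels) != nrow(object@data))
    msg <- c(msg, "length(labels) must equal nrow(data)")
  if (anyDuplicated(tolower(trimws(object@labels))))
    msg <- c(msg, "channel labels must be unique (case-insensitive)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single strictly positive number")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels channel labels; defaults to \code{"ch1"}, \code{"ch2"}, ...
#' @param meta optional list of provenance notes.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(400), 2, 200), fs = 100)
#' nChannels(rec)
#' @export
Recording <- function(data, fs, labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(labels))
    labels <- paste0("ch", seq_len(nrow(data)))
  new("Recording", data = unname(data), fs = as.numeric(fs),
      labels = as.character(labels), meta = meta)
}

#' Infomax ICA decomposition of a Recording
#'
#' Linear decomposition \code{x = A S + mean} with unmixing
#' \code{S = W (x - mean)}. Sources are scaled to unit variance and each
#' column of \code{A} is signed so its largest-magnitude channel weight is
#' positive. For a square (full-rank) decomposition \code{A W = I}; when the
#' decomposition is computed in a PCA-reduced subspace (the default for
#' average-referenced data, which is rank-deficient by one), \code{A} is the
#' Moore-Penrose right inverse of \code{W}, so \code{W A = I} and \code{A W}
#' is the orthogonal projector onto the retained subspace.
#'
#' @slot A mixing matrix, channels x components.
#' @slot W unmixing matrix, components x channels.
#' @slot S source matrix, components x samples.
#' @slot center per-channel mean removed before unmixing.
#' @slot whitener sphering matrix used internally.
#' @slot converged logical; FALSE if the iteration hit maxIter first.
#' @slot nIter number of passes over the data used.
#' @slot seed integer seed the fit was run under.
#' @slot fs,labels sampling rate and channel labels of the fitted
#'   recording, carried along so reconstruction returns a full Recording.
#' @seealso [fitInfomax()], [icaSources()], [reconstructRecording()]
#' @export
setClass("ICADecomposition",
  representation(A = "matrix", W = "matrix", S = "matrix",
                 center = "numeric", whitener = "matrix",
                 converged = "logical", nIter = "integer", seed = "integer",
                 fs = "numeric", labels = "character"))

setValidity("ICADecomposition", function(object) {
  msg <- character()
  k <- nrow(object@W)
  if (ncol(object@A) != k) msg <- c(msg, "ncol(A) must equal nrow(W)")
  if (nrow(object@A) != ncol(object@W))
    msg <- c(msg, "nrow(A) must equal ncol(W)")
  if (nrow(object@S) != k) msg <- c(msg, "nrow(S) must equal nrow(W)")
  if (length(object@center) != nrow(object@A))
    msg <- c(msg, "center must have one entry per channel")
  if (length(msg)) msg else TRUE
})

#' Report of automatic EOG-component identification
#'
#' @slot corr correlation matrix, frontal channels x components (Pearson).
#' @slot wbar mean absolute frontal mixing weight per component.
#' @slot threshold Tukey fence value Q3 + 1.5 IQR over \code{wbar}.
#' @slot flagged integer indices of components identified as ocular.
#' @slot ranks components ordered by decreasing max |corr|.
#' @slot minAbsCorr correlation gate used.
#' @seealso [identifyEOGComponents()]
#' @export
setClass("EOGReport",
  representation(corr = "matrix", wbar = "numeric", threshold = "numeric",
                 flagged = "integer", ranks = "integer",
                 minAbsCorr = "numeric"))

setValidity("EOGReport", function(object) {
  msg <- character()
  if (length(object@wbar) && any(object@wbar < 0))
    msg <- c(msg, "wbar entries must be nonnegative")
  if (length(object@corr) && any(abs(object@corr) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (any(object@flagged < 1L) ||
      any(object@flagged > length(object@wbar)))
    msg <- c(msg, "flagged indices out of range")
  if (length(msg)) msg else TRUE
})

#' Detected EOG peaks within one independent component
#'
#' Peaks are local maxima of |y| exceeding 3 E{|y|}, thinned so that
#' consecutive kept peaks are at least 0.5 s apart.
#'
#' @slot component index of the component the peaks belong to.
#' @slot samples 1-based sample indices of kept peaks, ascending.
#' @slot amplitudes |y| at the kept peaks.
#' @slot fs sampling rate in Hz.
#' @seealso [detectEOGPeaks()]
#' @export
setClass("PeakSet",
  representation(component = "integer", samples = "integer",
                 amplitudes = "numeric", fs = "numeric"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (is.unsorted(object@samples, strictly = TRUE))
    msg <- c(msg, "peak samples must be strictly ascending")
  if (length(object@amplitudes) != length(object@samples))
    msg <- c(msg, "amplitudes and samples must have equal length")
  if (length(msg)) msg else TRUE
})

#' Merged correction windows around EOG peaks
#'
#' Half-open intervals [start, end) in 1-based samples: an interval covers
#' samples \code{start .. end - 1}. Intervals are disjoint, sorted and lie
#' within the recording.
#'
#' @slot intervals two-column integer matrix (start, end).
#' @slot nSamples length of the underlying component.
#' @slot coverage fraction of samples covered, in [0, 1].
#' @seealso [buildWindows()], [decideAction()]
#' @export
setClass("ArtifactWindows",
  representation(intervals = "matrix", nSamples = "integer",
                 coverage = "numeric"))

setValidity("ArtifactWindows", function(object) {
  iv <- object@intervals
  msg <- character()
  if (ncol(iv) != 2L) msg <- c(msg, "intervals must have two columns")
  if (nrow(iv)) {
    if (any(iv[, 1L] >= iv[, 2L]))
      msg <- c(msg, "intervals must be non-empty half-open [start, end)")
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > object@nSamples + 1L))
      msg <- c(msg, "intervals must lie within [1, nSamples + 1)")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L] - 1L + 0))
      if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
        msg <- c(msg, "intervals must be disjoint and sorted")
  }
  if (object@coverage < 0 || object@coverage > 1)
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of an artifact-removal run
#'
#' @slot cleaned cleaned [Recording-class] (same shape, fs and labels as
#'   the preprocessed input).
#' @slot preprocessed the band-passed, re-referenced input the cleaning
#'   operated on (the reference for selectivity checks and metrics).
#' @slot method one of \code{"pm"}, \code{"wica"}, \code{"icarej"}.
#' @slot actions per-component action: \code{"untouched"},
#'   \code{"corrected_in_windows"} or \code{"rejected"}.
#' @slot report the [EOGReport-class] of the identification step.
#' @slot windows named list of [ArtifactWindows-class], one per flagged
#'   component.
#' @slot decomposition the [ICADecomposition-class] used.
#' @slot config config snapshot (list).
#' @slot seed integer seed.
#' @seealso [removeEOG()]
#' @export
setClass("CleaningResult",
  representation(cleaned = "Recording", preprocessed = "Recording",
                 method = "character", actions = "character",
                 report = "EOGReport", windows = "list",
                 decomposition = "ICADecomposition",
                 config = "list", seed = "integer"))

setValidity("CleaningResult", function(object) {
  msg <- character()
  if (!identical(dim(object@cleaned@data), dim(object@preprocessed@data)))
    msg <- c(msg, "cleaned and preprocessed recordings must share shape")
  if (length(object@actions) != nrow(object@decomposition@S))
    msg <- c(msg, "one action must be recorded per component")
  if (length(msg)) msg else TRUE
})

#' Artifact-removal quality metrics
#'
#' Per-channel and channel-averaged artifact removal percentage (lambda),
#' delta-SNR, RMSE, band-mean magnitude-squared coherence, plus the
#' channel-averaged MSC curve.
#'
#' @slot perChannel data.frame with one row per channel: \code{lambda},
#'   \code{deltaSNR}, \code{rmse}, \code{bandMSC}.
#' @slot means named numeric vector of channel means of the above.
#' @slot mscFreqs frequency grid (Hz) of the averaged MSC curve.
#' @slot mscCurve channel-averaged MSC at \code{mscFreqs}.
#' @seealso [evaluateCleaning()]
#' @export
setClass("MetricsReport",
  representation(perChannel = "data.frame", means = "numeric",
                 mscFreqs = "numeric", mscCurve = "numeric"))
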