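# Step 1 of the pipeline: band-pass filtering and average re-referencing.
# The zero-phase pass is a forward-backward application of a 4th-order
# Butterworth design, so the effective magnitude response is the design's
# squared magnitude and the phase response is identically zero.

# Forward-backward IIR filtering with odd-symmetric edge extension and
# steady-state initial conditions, the standard transient-suppression
# scheme: the signal is extended at both ends by its point-reflection,
# the filter state is initialized as if the first extended sample had
# been applied forever, then the extended signal is filtered forward,
# reversed, filtered again, reversed, and the extensions dropped.
filtfiltOdd <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad)
    stop("signal too short for stable zero-phase filtering: need more than ",
         npad, " samples, got ", n)
  ord <- max(length(a), length(b)) - 1L
  hdc <- sum(b) / sum(a)               # DC gain fixes the resting state
  onePass <- function(v) {
    signal::filter(b, a, v, init.x = rep(v[1L], ord),
                   init.y = rep(v[1L] * hdc, ord))
  }
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  ext <- c(pre, x, post)
  y <- onePass(ext)
  y <- rev(onePass(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel. \code{order} is the one-way design order; the two-way pass has
#' the squared magnitude response of that design and no phase shift.
#'
#' @param rec a [Recording-class].
#' @param low,high band edges in Hz; defaults 1 and 47.
#' @param order one-way Butterworth order (default 4).
#' @return A filtered [Recording-class] of the same shape.
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 2000), 2, 2000), fs = 200)
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(rec, low = 1, high = 47, order = 4L) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (!(low > 0 && low < high))
    stop("need 0 < low < high")
  if (high >= fs / 2)
    stop("upper band edge ", high, " Hz must be below the Nyquist rate ",
         fs / 2, " Hz (fs = ", fs, " Hz)")
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(rec@data, 1L, function(ch) filtfiltOdd(bt$b, bt$a, ch)))
  new("Recording", data = out, fs = fs, labels = rec@labels,
      meta = c(rec@meta, list(filter = list(low = low, high = high,
                                            order = order))))
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' each column of the result sums to zero. Idempotent. Note the result is
#' rank-deficient by one, which [fitInfomax()] handles by reducing to
#' \code{nChannels - 1} principal dimensions.
#'
#' @param rec a [Recording-class] with at least 2 channels.
#' @return The re-referenced [Recording-class].
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "Recording"))
  out <- sweep(rec@data, 2L, colMeans(rec@data))
  new("Recording", data = out, fs = rec@fs, labels = rec@labels,
      meta = c(rec@meta, list(reference = "average")))
}

#' Band-pass and average-reference a Recording
#'
#' Convenience composition of [bandpassFilter()] and [averageReference()],
#' the preprocessing applied before ICA and also to any "pure" reference
#' recording used for evaluation (so removal error is isolated from the
#' filter response).
#'
#' @inheritParams bandpassFilter
#' @param reference \code{"average"} or \code{"none"}.
#' @return The preprocessed [Recording-class].
#' @export
preprocessRecording <- function(rec, low = 1, high = 47, order = 4L,
                                reference = c("average", "none")) {
  reference <- match.arg(reference)
  out <- bandpassFilter(rec, low = low, high = high, order = order)
  if (reference == "average") out <- averageReference(out)
  out
}
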