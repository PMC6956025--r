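# Steps 4-5: EOG peak detection within a flagged component, one-second
# correction windows around the peaks, and the full-rejection fallback
# when the windows cover most of the component.

#' Detect EOG peaks in a component series
#'
#' Local maxima of |y| are kept iff
#' \code{|y| > ampFactor * mean(|y|)}; a greedy time-ordered scan then
#' drops any peak closer than \code{minSeparation} seconds to the last
#' kept peak. By default conflicts are resolved in favour of the
#' larger amplitude (\code{tieBreak = "largest"}): when a background
#' fluctuation and an EOG peak contend within the spacing window, the
#' EOG peak -- the large one -- must win, or the detector keeps noise
#' and drops the event. \code{tieBreak = "earliest"} keeps the first
#' peak in time instead. A local
#' maximum must dominate a 25 ms neighbourhood on each side, not just
#' its immediate neighbours: with one-sample neighbourhoods, noise
#' riding on the rising flank of a large peak produces spurious maxima
#' that the spacing rule then keeps in place of the true peak,
#' systematically shifting detections early.
#'
#' @param y numeric component series.
#' @param fs sampling rate in Hz.
#' @param component component index recorded in the result (default 1).
#' @param ampFactor amplitude factor over mean |y| (default 3).
#' @param minSeparation minimum between-peak distance in seconds
#'   (default 0.5).
#' @param tieBreak \code{"largest"} (default) or \code{"earliest"}.
#' @return A [PeakSet-class]; empty if no sample qualifies.
#' @examples
#' y <- rnorm(2000, sd = 0.01); y[500] <- 10
#' detectEOGPeaks(y, fs = 200)
#' @export
detectEOGPeaks <- function(y, fs, component = 1L, ampFactor = 3,
                           minSeparation = 0.5,
                           tieBreak = c("largest", "earliest")) {
  tieBreak <- match.arg(tieBreak)
  stopifnot(all(is.finite(y)), fs > 0)
  a <- abs(y)
  n <- length(a)
  thr <- ampFactor * mean(a)
  cand <- which(a > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[a[cand] > a[cand - 1L] & a[cand] > a[cand + 1L]]
  w <- max(1L, round(0.025 * fs))            # 25 ms dominance window
  cand <- cand[vapply(cand, function(m) {
    lo <- max(1L, m - w); hi <- min(n, m + w)
    a[m] >= max(a[lo:hi])
  }, logical(1))]
  minGap <- minSeparation * fs
  keep <- integer(0)
  if (tieBreak == "earliest") {
    last <- -Inf
    for (m in cand) {
      if (m - last >= minGap) { keep <- c(keep, m); last <- m }
    }
  } else {
    for (m in cand[order(a[cand], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - m) >= minGap))
        keep <- c(keep, m)
    }
    keep <- sort(keep)
  }
  new("PeakSet", component = as.integer(component),
      samples = as.integer(keep), amplitudes = a[keep], fs = fs)
}

#' Build merged correction windows around peaks
#'
#' Each peak at sample \code{m} yields the half-open interval
#' \code{[m - width/2, m + width/2)} in samples, clipped to the recording;
#' overlapping or adjacent windows are merged. Coverage is the fraction of
#' the component's samples inside the merged intervals.
#'
#' @param peaks a [PeakSet-class] (or integer vector of peak samples).
#' @param fs sampling rate in Hz.
#' @param nSamples length of the component.
#' @param width window width in seconds (default 1).
#' @return An [ArtifactWindows-class].
#' @export
buildWindows <- function(peaks, fs, nSamples, width = 1.0) {
  stopifnot(width > 0)
  samples <- if (is(peaks, "PeakSet")) peaks@samples else as.integer(peaks)
  half <- round(width * fs / 2)
  nSamples <- as.integer(nSamples)
  if (!length(samples)) {
    return(new("ArtifactWindows",
               intervals = matrix(integer(0), 0L, 2L,
                                  dimnames = list(NULL, c("start", "end"))),
               nSamples = nSamples, coverage = 0))
  }
  start <- pmax(samples - half, 1L)
  end <- pmin(samples + half, nSamples + 1L)   # half-open
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  ms <- start[1L]; me <- end[1L]
  outS <- integer(0); outE <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outS <- c(outS, ms); outE <- c(outE, me)
           ms <- start[i]; me <- end[i] }
  }
  outS <- c(outS, ms); outE <- c(outE, me)
  iv <- cbind(start = as.integer(outS), end = as.integer(outE))
  new("ArtifactWindows", intervals = iv, nSamples = nSamples,
      coverage = sum(outE - outS) / nSamples)
}

#' Decide between in-window correction and full rejection
#'
#' The whole component is rejected iff the windows cover strictly more
#' than \code{rejectFraction} of its samples (default 0.60); otherwise
#' correction is restricted to the windows.
#'
#' @param windows an [ArtifactWindows-class].
#' @param rejectFraction coverage threshold, strict (default 0.60).
#' @return \code{"reject_component"} or \code{"correct_in_windows"}.
#' @export
decideAction <- function(windows, rejectFraction = 0.60) {
  cov <- if (is(windows, "ArtifactWindows")) windows@coverage
         else as.numeric(windows)
  if (cov > rejectFraction) "reject_component" else "correct_in_windows"
}

# logical mask of samples inside the windows
windowMask <- function(windows, nSamples = windows@nSamples) {
  mask <- logical(nSamples)
  iv <- windows@intervals
  for (i in seq_len(nrow(iv)))
    mask[iv[i, 1L]:(iv[i, 2L] - 1L)] <- TRUE
  mask
}
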