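# Artifact-removal quality metrics: removal efficacy (lambda, deltaSNR),
# residual distortion (RMSE, magnitude-squared coherence) and the
# sensitivity of the peak detector against ground-truth event times.

#' Artifact removal percentage (lambda)
#'
#' \code{lambda = 100 (1 - (Rref - Rcleaned) / (Rref - Rcontam))} where
#' \code{Rref} is the lag-1 autocorrelation of the pure signal,
#' \code{Rcleaned = cor(pure, cleaned)} and
#' \code{Rcontam = cor(pure, contam)}. Note the reference deliberately
#' mixes an autocorrelation with cross-correlations; it is implemented
#' literally as defined. 100 means the cleaned signal correlates with the
#' truth as strongly as the truth's own lag-1 autocorrelation; 0 means no
#' improvement over the contaminated signal.
#'
#' The score is only meaningful where the artifact measurably degrades
#' the correlation: when \code{Rref - Rcontam} falls below
#' \code{minDenom} (essentially uncontaminated channel, or one where
#' the artifact happens to mimic the reference autocorrelation) the
#' ratio is numerically unstable and lambda is reported as \code{NA}
#' with a warning. Channel averages skip such channels.
#'
#' @param pure,contam,cleaned equal-length numeric series (one channel).
#' @param minDenom smallest \code{Rref - Rcontam} for which the score
#'   is considered defined (default 0.05).
#' @return Lambda in percent, or \code{NA} (with a warning) when the
#'   denominator makes the ratio undefined.
#' @export
lambdaRemoval <- function(pure, contam, cleaned, minDenom = 0.05) {
  stopifnot(length(pure) == length(contam),
            length(pure) == length(cleaned))
  n <- length(pure)
  Rref <- stats::cor(pure[-n], pure[-1L])
  Rcontam <- stats::cor(pure, contam)
  Rcleaned <- stats::cor(pure, cleaned)
  if (Rref - Rcontam < minDenom) {
    warning("Rref - Rcontam = ", signif(Rref - Rcontam, 3),
            " < ", minDenom, ": lambda is undefined on this channel")
    return(NA_real_)
  }
  100 * (1 - (Rref - Rcleaned) / (Rref - Rcontam))
}

#' Signal-to-noise ratio improvement (dB)
#'
#' \code{10 log10(var(pure) / var(cleaned - pure)) -
#'   10 log10(var(pure) / var(contam - pure))}: the SNR gained by
#' cleaning, relative to the contaminated signal. Exact recovery would be
#' +Inf and is capped at +-120 dB.
#'
#' @inheritParams lambdaRemoval
#' @param cap absolute cap in dB for degenerate exact-recovery cases.
#' @return Delta-SNR in dB.
#' @export
deltaSNR <- function(pure, contam, cleaned, cap = 120) {
  stopifnot(length(pure) == length(contam),
            length(pure) == length(cleaned))
  snr <- function(err) 10 * log10(stats::var(pure) / stats::var(err))
  val <- snr(cleaned - pure) - snr(contam - pure)
  if (!is.finite(val)) val <- sign(val) * cap
  max(min(val, cap), -cap)
}

#' Root mean square error between two series
#'
#' @param pure,cleaned equal-length numeric series (microvolts).
#' @return RMSE in microvolts.
#' @export
rmse <- function(pure, cleaned) {
  stopifnot(length(pure) == length(cleaned))
  sqrt(mean((cleaned - pure)^2))
}

# Welch-averaged auto/cross spectra of one or two series
welchSpectra <- function(x, y, fs, segLength, overlap) {
  n <- length(x)
  step <- max(1L, round(segLength * (1 - overlap)))
  starts <- if (n >= segLength) seq.int(1L, n - segLength + 1L, by = step)
            else integer(0)
  if (length(starts) < 2L)
    stop("fewer than 2 Welch segments (series length ", n,
         ", segment ", segLength, "); coherence of one segment is ",
         "identically 1 -- use a longer series or shorter segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, segLength - 1) / (segLength - 1))
  Pxx <- Pyy <- numeric(segLength)
  Pxy <- complex(segLength)
  for (s in starts) {
    idx <- s:(s + segLength - 1L)
    X <- stats::fft(w * (x[idx] - mean(x[idx])))
    Y <- stats::fft(w * (y[idx] - mean(y[idx])))
    Pxx <- Pxx + Mod(X)^2
    Pyy <- Pyy + Mod(Y)^2
    Pxy <- Pxy + Conj(X) * Y
  }
  nf <- floor(segLength / 2) + 1L
  list(freqs = (seq_len(nf) - 1L) * fs / segLength,
       Pxx = Pxx[seq_len(nf)], Pyy = Pyy[seq_len(nf)],
       Pxy = Pxy[seq_len(nf)], nseg = length(starts))
}

#' Magnitude-squared coherence via Welch averaging
#'
#' \code{C(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))} with Hann-windowed,
#' mean-detrended, overlapping segments. Values are clipped to [0, 1]
#' against rounding. At least two segments are required (the coherence of
#' a single segment is identically one).
#'
#' @param pure,cleaned equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @param segSeconds Welch segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return List with \code{freqs} (Hz) and \code{coherence} in [0, 1].
#' @export
msc <- function(pure, cleaned, fs, segSeconds = 2, overlap = 0.5) {
  stopifnot(length(pure) == length(cleaned))
  segLength <- round(segSeconds * fs)
  sp <- welchSpectra(pure, cleaned, fs, segLength, overlap)
  coh <- Mod(sp$Pxy)^2 / (sp$Pxx * sp$Pyy)
  coh[!is.finite(coh)] <- 0
  list(freqs = sp$freqs, coherence = pmin(pmax(coh, 0), 1))
}

#' Peak-detection sensitivity against ground truth
#'
#' Greedy one-to-one matching of detected to true event times within
#' \code{tol} seconds; \code{Se = 100 TP / (TP + FN)}.
#'
#' @param detected,truth sorted numeric vectors of event times (seconds).
#' @param tol matching tolerance in seconds (default 0.1).
#' @return List with \code{Se} (percent), \code{TP}, \code{FN}.
#' @examples
#' peakSensitivity(c(1, 2, 3), c(1.02, 2.5, 3.01))
#' @export
peakSensitivity <- function(detected, truth, tol = 0.1) {
  if (!length(truth)) {
    warning("empty truth set; sensitivity is undefined")
    return(list(Se = NA_real_, TP = 0L, FN = 0L))
  }
  used <- logical(length(detected))
  TP <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      TP <- TP + 1L
    }
  }
  FN <- length(truth) - TP
  list(Se = 100 * TP / (TP + FN), TP = TP, FN = FN)
}

#' Evaluate a cleaned recording against its pure reference
#'
#' Computes lambda, delta-SNR, RMSE and band-mean magnitude-squared
#' coherence per channel, plus their channel means and the
#' channel-averaged MSC curve. Channels where lambda is undefined
#' (see [lambdaRemoval()]) carry \code{NA} in the per-channel table and
#' are skipped in the lambda mean. The pure reference must have been given
#' the same preprocessing as the contaminated input (see
#' [preprocessRecording()]), so removal error is not confounded with the
#' filter response.
#'
#' @param pure,contam,cleaned [Recording-class] objects of equal shape:
#'   preprocessed pure reference, preprocessed contaminated input, and
#'   cleaned output.
#' @param band frequency band (Hz) over which MSC is averaged
#'   (default c(1, 47), the analysis passband).
#' @param segSeconds,overlap Welch parameters for [msc()].
#' @return A [MetricsReport-class].
#' @export
evaluateCleaning <- function(pure, contam, cleaned, band = c(1, 47),
                             segSeconds = 2, overlap = 0.5) {
  stopifnot(identical(dim(pure@data), dim(contam@data)),
            identical(dim(pure@data), dim(cleaned@data)))
  nch <- nrow(pure@data)
  lam <- dsnr <- rm <- bm <- numeric(nch)
  curve <- NULL
  for (i in seq_len(nch)) {
    p <- pure@data[i, ]; co <- contam@data[i, ]; cl <- cleaned@data[i, ]
    lam[i] <- suppressWarnings(lambdaRemoval(p, co, cl))
    dsnr[i] <- deltaSNR(p, co, cl)
    rm[i] <- rmse(p, cl)
    m <- msc(p, cl, pure@fs, segSeconds, overlap)
    inBand <- m$freqs >= band[1L] & m$freqs <= band[2L]
    bm[i] <- mean(m$coherence[inBand])
    curve <- if (is.null(curve)) m$coherence else curve + m$coherence
  }
  per <- data.frame(channel = pure@labels, lambda = lam, deltaSNR = dsnr,
                    rmse = rm, bandMSC = bm)
  m1 <- msc(pure@data[1L, ], cleaned@data[1L, ], pure@fs, segSeconds,
            overlap)
  new("MetricsReport", perChannel = per,
      means = c(lambda = mean(lam, na.rm = TRUE),
                deltaSNR = mean(dsnr), rmse = mean(rm),
                bandMSC = mean(bm)),
      mscFreqs = m1$freqs, mscCurve = curve / nch)
}
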