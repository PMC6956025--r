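# Step 6: multilevel orthogonal DWT of windowed component segments, with
# only the high-frequency detail bands retained, plus the two baselines
# (full-component wavelet thresholding, and whole-component rejection).
#
# The transform is the decimated quadrature-mirror cascade on a circular
# (periodized) signal. Segments are zero-padded to the next multiple of
# 2^levels: zero padding adds no energy, so perfect reconstruction,
# linearity and exact coefficient-energy conservation hold for arbitrary
# segment lengths.

# orthonormal scaling filters (sum g = sqrt(2), sum g^2 = 1)
.waveletFilters <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  sym3 = c(0.035226291882100656, -0.085441273882241486, -0.13501102001039084,
           0.45987750211933132, 0.80689150931333875, 0.33267055295095688),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  sym6 = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
           -0.048311742585632998, 0.49105594192674662, 0.787641141030194,
           0.3379294217276218, -0.072637522786462516, -0.021060292512300564,
           0.044724901770665779, 0.0017677118642428036,
           -0.007800708325034148))

waveletFilter <- function(basis) {
  g <- .waveletFilters[[basis]]
  if (is.null(g))
    stop("unknown wavelet basis '", basis, "'; available: ",
         paste(names(.waveletFilters), collapse = ", "))
  g
}

# single-level periodized analysis: x (even length) -> list(a, d)
dwtStep <- function(x, g) {
  N <- length(x)
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)   # quadrature-mirror highpass
  e <- seq.int(0L, N - 2L, by = 2L)
  a <- numeric(N / 2L); d <- numeric(N / 2L)
  for (m in seq_len(L)) {
    xv <- x[((e + m - 1L) %% N) + 1L]
    a <- a + g[m] * xv
    d <- d + h[m] * xv
  }
  list(a = a, d = d)
}

# single-level periodized synthesis (transpose of the analysis operator)
idwtStep <- function(a, d, g) {
  N <- 2L * length(a)
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  e <- seq.int(0L, N - 2L, by = 2L)
  x <- numeric(N)
  for (m in seq_len(L)) {
    pos <- ((e + m - 1L) %% N) + 1L
    x[pos] <- x[pos] + g[m] * a + h[m] * d
  }
  x
}

#' Multilevel wavelet decomposition of a segment
#'
#' Detail bands split the (two-sided) spectrum dyadically: at sampling
#' rate fs, D1 spans fs/4..fs/2, D2 fs/8..fs/4, ..., and the level-L
#' approximation spans 0..fs/2^(L+1). At fs = 200 Hz with 5 levels, D1:D3
#' together cover roughly 12.5-100 Hz while D4, D5 and A5 cover 0-12.5 Hz
#' -- the band that carries ocular artifact energy (concentrated below
#' about 7 Hz).
#'
#' @param segment numeric series (length at least \code{2^levels}).
#' @param basis wavelet name; one of \code{haar}, \code{db2}, \code{db4},
#'   \code{sym3}, \code{sym4} (default), \code{sym5}, \code{sym6}.
#' @param levels decomposition depth (default 5).
#' @return A \code{WaveletDecomposition} with detail arrays \code{D1} (finest)
#'   through \code{D<levels>}, approximation \code{A}, and the original
#'   length needed to undo the internal zero padding.
#' @examples
#' x <- rnorm(200)
#' w <- dwtMultilevel(x)
#' max(abs(idwtMultilevel(w) - x))
#' @export
dwtMultilevel <- function(segment, basis = "sym4", levels = 5L) {
  g <- waveletFilter(basis)
  n <- length(segment)
  if (n < 2^levels)
    stop("segment of length ", n, " is too short for ", levels,
         " levels; minimum length is ", 2^levels)
  padN <- as.integer(2^levels * ceiling(n / 2^levels))
  x <- c(segment, numeric(padN - n))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwtStep(x, g)
    details[[j]] <- st$d
    x <- st$a
  }
  names(details) <- paste0("D", seq_len(levels))
  new("WaveletDecomposition", basis = basis, levels = as.integer(levels),
      details = details, approx = x, origLength = as.integer(n),
      padLength = padN)
}

#' @rdname dwtMultilevel
#' @param decomp a \code{WaveletDecomposition}.
#' @return \code{idwtMultilevel}: the reconstructed series (original,
#'   unpadded length).
#' @export
idwtMultilevel <- function(decomp) {
  g <- waveletFilter(decomp@basis)
  x <- decomp@approx
  for (j in rev(seq_len(decomp@levels)))
    x <- idwtStep(x, decomp@details[[j]], g)
  x[seq_len(decomp@origLength)]
}

#' Wavelet segment decomposition container
#'
#' @slot basis wavelet basis name.
#' @slot levels decomposition depth.
#' @slot details list of detail coefficient arrays D1 (finest) .. D-levels.
#' @slot approx approximation coefficients at the deepest level.
#' @slot origLength,padLength segment length before/after zero padding.
#' @export
setClass("WaveletDecomposition",
  representation(basis = "character", levels = "integer",
                 details = "list", approx = "numeric",
                 origLength = "integer", padLength = "integer"))

#' Reconstruct keeping only selected wavelet bands
#'
#' Inverse transform with every band not in \code{keep} zeroed. The
#' default retains the three finest detail bands, i.e. the high-frequency
#' content, and discards the low-frequency bands that carry the ocular
#' artifact waveform.
#'
#' @param decomp a \code{WaveletDecomposition}.
#' @param keep character vector of band labels among \code{D1..D<levels>}
#'   and \code{"A"}; must be non-empty.
#' @return Numeric series of the original segment length.
#' @export
highpassReconstruct <- function(decomp, keep = c("D1", "D2", "D3")) {
  if (!length(keep)) stop("keep must name at least one band")
  avail <- c(names(decomp@details), "A")
  bad <- setdiff(keep, avail)
  if (length(bad))
    stop("unknown band(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  d2 <- decomp
  for (nm in names(d2@details))
    if (!(nm %in% keep)) d2@details[[nm]] <- numeric(length(d2@details[[nm]]))
  if (!("A" %in% keep)) d2@approx <- numeric(length(d2@approx))
  idwtMultilevel(d2)
}

#' Selective in-window wavelet correction of a component
#'
#' Inside each artifact window the segment is replaced by its
#' high-frequency wavelet reconstruction ([highpassReconstruct()]);
#' outside the windows the series is returned bit-identically. A short
#' linear crossfade at each window boundary (inside the window) blends
#' the spliced segment into its surroundings to avoid step
#' discontinuities that would ring through the inverse ICA.
#'
#' @param y numeric component series.
#' @param windows an [ArtifactWindows-class] for \code{y}.
#' @param fs sampling rate in Hz.
#' @param basis,levels wavelet parameters (defaults sym4, 5).
#' @param keep bands to retain (default \code{D1:D3}).
#' @param crossfade crossfade length in seconds (default 0.01).
#' @return The corrected series, same length as \code{y}.
#' @export
cleanComponentSelective <- function(y, windows, fs, basis = "sym4",
                                    levels = 5L, keep = c("D1", "D2", "D3"),
                                    crossfade = 0.01) {
  out <- y
  iv <- windows@intervals
  nfade <- round(crossfade * fs)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]          # half-open [s, e)
    seg <- y[s:(e - 1L)]
    lev <- min(levels, floor(log2(length(seg))))
    if (lev < 1L) next                       # degenerate sliver: leave as is
    cleaned <- highpassReconstruct(
      dwtMultilevel(seg, basis = basis, levels = lev),
      keep = intersect(keep, paste0("D", seq_len(lev))))
    nf <- min(nfade, floor(length(seg) / 2))
    if (nf > 0) {
      w <- seq_len(nf) / (nf + 1)
      cleaned[seq_len(nf)] <- (1 - w) * seg[seq_len(nf)] +
        w * cleaned[seq_len(nf)]
      tail <- length(seg) - nf + seq_len(nf)
      cleaned[tail] <- rev(w) * cleaned[tail] + (1 - rev(w)) * seg[tail]
    }
    out[s:(e - 1L)] <- cleaned
  }
  out
}

#' Full-component wavelet thresholding (wICA baseline)
#'
#' The classical wavelet-enhanced ICA baseline: decompose the entire
#' component, zero every coefficient whose magnitude exceeds the
#' universal threshold \code{K sqrt(2 log N) sigma} with the robust noise
#' scale \code{sigma = median(|D1|) / 0.6745}, and invert. This removes
#' large-amplitude artifact coefficients wherever they occur, at the cost
#' of touching the whole component.
#'
#' @param y numeric component series.
#' @param basis,levels wavelet parameters (defaults sym4, 5).
#' @param thresholdScale the factor K (default 1).
#' @return The thresholded series, same length as \code{y}.
#' @export
wicaCleanComponent <- function(y, basis = "sym4", levels = 5L,
                               thresholdScale = 1) {
  if (all(y == 0)) return(y)
  w <- dwtMultilevel(y, basis = basis, levels = levels)
  sigma <- stats::median(abs(w@details[["D1"]])) / 0.6745
  thr <- thresholdScale * sqrt(2 * log(length(y))) * sigma
  for (nm in names(w@details)) {
    d <- w@details[[nm]]
    d[abs(d) > thr] <- 0
    w@details[[nm]] <- d
  }
  a <- w@approx
  a[abs(a) > thr] <- 0
  w@approx <- a
  idwtMultilevel(w)
}

#' Whole-component rejection baseline
#'
#' Reconstructs the recording with the flagged components zeroed before
#' the inverse ICA (classical rejection ICA).
#'
#' @param decomp an [ICADecomposition-class].
#' @param flagged integer component indices to reject.
#' @return A [Recording-class].
#' @export
rejectClean <- function(decomp, flagged) {
  reconstructRecording(decomp, reject = flagged)
}
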