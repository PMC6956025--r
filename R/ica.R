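# Step 2 (and 7) of the pipeline: Infomax ICA and inverse reconstruction.
#
# The decomposition is the classic natural-gradient logistic Infomax:
# maximize the output entropy of y = logistic(W z) over unmixing matrices
# W on centered, whitened data z, via blocked stochastic natural-gradient
# ascent  dW = lrate * (I + (1 - 2 y) u') W,  u = W z.
# Average-referenced data are rank-deficient by one, so the fit runs in
# the nChannels - 1 principal subspace and is embedded back afterwards.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

asSignalMatrix <- function(x) {
  if (is(x, "Recording")) x@data else as.matrix(x)
}

#' Center and whiten a multichannel signal
#'
#' Removes the per-channel mean and applies a PCA whitening transform so
#' the rows of the result have identity sample covariance. Eigendirections
#' with negligible variance are dropped only when expected: by default one
#' deficient dimension is tolerated iff the data are average-referenced
#' (channel sums are zero, putting the all-ones vector in the null space);
#' any other rank deficiency is an error, since it means genuinely
#' redundant channels that call for explicit PCA dimension reduction.
#'
#' @param x a [Recording-class] or channels x samples matrix.
#' @param maxDrop maximum number of negligible eigendirections to drop
#'   silently; \code{NULL} (default) auto-detects average-referenced data.
#' @param tol relative eigenvalue tolerance for "negligible".
#' @return List with \code{z} (whitened matrix, k x samples),
#'   \code{whitener} (k x channels), \code{center} (channel means),
#'   \code{basis} (channels x k back-projection basis \code{E D^{1/2}}).
#' @export
centerWhiten <- function(x, maxDrop = NULL, tol = 1e-9) {
  mat <- asSignalMatrix(x)
  n <- nrow(mat); T <- ncol(mat)
  if (T <= n) stop("need more samples than channels to whiten")
  center <- rowMeans(mat)
  xc <- mat - center
  v <- rowSums(xc^2)
  if (any(v == 0))
    stop("constant channel(s): ",
         paste(which(v == 0), collapse = ", "),
         " have zero variance and cannot be whitened")
  if (is.null(maxDrop)) {
    colsum <- colSums(mat)
    maxDrop <- if (max(abs(colsum)) < 1e-6 * max(abs(mat)) + 1e-12) 1L
               else 0L
  }
  covm <- tcrossprod(xc) / (T - 1)
  eg <- eigen(covm, symmetric = TRUE)
  lam <- eg$values
  small <- lam < tol * lam[1L]
  if (sum(small) > maxDrop)
    stop("covariance is rank-deficient by ", sum(small),
         " (expected at most ", maxDrop,
         "): reduce dimensionality with PCA before fitting")
  keep <- which(!small)
  if (length(keep) < 2L) stop("fewer than 2 non-degenerate dimensions")
  E <- eg$vectors[, keep, drop = FALSE]
  whitener <- diag(1 / sqrt(lam[keep]), length(keep)) %*% t(E)
  list(z = whitener %*% xc, whitener = whitener, center = center,
       basis = E %*% diag(sqrt(lam[keep]), length(keep)))
}

#' Fit an Infomax ICA decomposition
#'
#' Natural-gradient logistic Infomax on centered, whitened data, with
#' learning-rate annealing: the rate is multiplied by 0.9 whenever the
#' angle between successive weight updates exceeds 60 degrees (the
#' standard oscillation heuristic) or, after a 100-pass burn-in, when
#' the per-pass weight change stops decreasing (stochastic plateau).
#' The run is deterministic given \code{seed},
#' which drives both the data permutation of each pass and nothing else.
#' Sources are returned with unit variance and signed so that each
#' component's largest-magnitude mixing weight is positive.
#'
#' @param x a [Recording-class] or channels x samples matrix.
#' @param seed integer seed.
#' @param maxIter maximum passes over the data (default 512). If \code{tol}
#'   is not reached the fit returns with \code{converged = FALSE} and a
#'   warning, not an error.
#' @param tol relative Frobenius change in W that counts as converged.
#' @param lrate initial learning rate; default 0.01.
#' @param nDim optional explicit number of principal dimensions to keep
#'   before the rotation (passed through PCA); default keeps all
#'   non-degenerate dimensions as decided by [centerWhiten()].
#' @return An [ICADecomposition-class].
#' @examples
#' toy <- genICAToy(3, 5000, seed = 7)
#' dec <- fitInfomax(Recording(toy$mixture, fs = 100), seed = 7)
#' @export
fitInfomax <- function(x, seed = 1L, maxIter = 512L, tol = 1e-7,
                       lrate = 0.01, nDim = NULL) {
  mat <- asSignalMatrix(x)
  fs <- if (is(x, "Recording")) x@fs else 1
  labels <- if (is(x, "Recording")) x@labels
            else paste0("ch", seq_len(nrow(mat)))
  cw <- centerWhiten(mat)
  z <- cw$z
  if (!is.null(nDim)) {
    if (nDim > nrow(z)) stop("nDim exceeds available dimensions")
    z <- z[seq_len(nDim), , drop = FALSE]
    cw$whitener <- cw$whitener[seq_len(nDim), , drop = FALSE]
    cw$basis <- cw$basis[, seq_len(nDim), drop = FALSE]
  }
  k <- nrow(z); nT <- ncol(z)
  B <- min(nT, 8L * ceiling(sqrt(nT)))
  W <- diag(k)
  I <- diag(k)
  oldDelta <- NULL
  lastChange <- Inf
  burnin <- 100L                 # full-rate passes before annealing starts
  converged <- FALSE
  iter <- 0L
  withSeed(seed, {
    for (iter in seq_len(maxIter)) {
      Wold <- W
      perm <- sample.int(nT)
      starts <- seq.int(1L, nT, by = B)
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + B - 1L, nT)]
        u <- W %*% z[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        W <- W + lrate * (I + ((1 - 2 * y) %*% t(u)) / length(idx)) %*% W
        if (!all(is.finite(W)))
          stop("Infomax diverged to non-finite weights at pass ", iter,
               "; lower lrate")
      }
      delta <- W - Wold
      change <- sqrt(sum(delta^2)) / sqrt(sum(Wold^2))
      anneal <- FALSE
      if (!is.null(oldDelta)) {            # oscillation: > 60 degrees
        denom <- sqrt(sum(delta^2)) * sqrt(sum(oldDelta^2))
        if (denom > 0 && sum(delta * oldDelta) / denom < 0.5)
          anneal <- TRUE
      }
      if (iter > burnin && change > lastChange)
        anneal <- TRUE                     # plateau: change stopped falling
      if (anneal) lrate <- lrate * 0.9
      oldDelta <- delta
      lastChange <- change
      if (change < tol) { converged <- TRUE; break }
    }
  })
  if (!converged)
    warning("Infomax did not reach tol = ", tol, " within ", maxIter,
            " passes (treating last iterate as the fit)")
  Wt <- W %*% cw$whitener                    # k x n total unmixing
  S <- Wt %*% (mat - cw$center)
  sds <- apply(S, 1L, stats::sd)
  Wt <- Wt / sds
  S <- S / sds
  A <- if (k == nrow(mat)) solve(Wt)
       else t(Wt) %*% solve(Wt %*% t(Wt))    # Moore-Penrose right inverse
  for (j in seq_len(k)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) {
      A[, j] <- -A[, j]; Wt[j, ] <- -Wt[j, ]; S[j, ] <- -S[j, ]
    }
  }
  new("ICADecomposition", A = A, W = Wt, S = S, center = cw$center,
      whitener = cw$whitener, converged = converged, nIter = iter,
      seed = as.integer(seed), fs = fs, labels = labels)
}

#' Unmix a recording with a fitted decomposition
#'
#' @param decomp an [ICADecomposition-class].
#' @param x a [Recording-class] or matrix with the channel count the
#'   decomposition was fitted on.
#' @return Components x samples source matrix \code{W (x - center)}.
#' @export
icaSources <- function(decomp, x) {
  mat <- asSignalMatrix(x)
  if (nrow(mat) != ncol(decomp@W))
    stop("recording has ", nrow(mat), " channels but the decomposition ",
         "was fitted on ", ncol(decomp@W))
  decomp@W %*% (mat - decomp@center)
}

#' Reconstruct channel data from (possibly modified) sources
#'
#' Computes \code{A S + center} with the columns of \code{A} belonging to
#' rejected components zeroed. With unmodified sources and nothing
#' rejected this inverts the decomposition.
#'
#' @param decomp an [ICADecomposition-class].
#' @param S source matrix (components x samples); defaults to the stored
#'   sources.
#' @param reject integer indices of components to zero out entirely.
#' @return A [Recording-class].
#' @export
reconstructRecording <- function(decomp, S = decomp@S,
                                 reject = integer(0)) {
  if (!identical(dim(S), dim(decomp@S)))
    stop("S must have the decomposition's source dimensions")
  reject <- as.integer(reject)
  if (length(reject) &&
      (min(reject) < 1L || max(reject) > nrow(decomp@S)))
    stop("reject index out of range 1..", nrow(decomp@S))
  A <- decomp@A
  if (length(reject)) A[, reject] <- 0
  Recording(A %*% S + decomp@center, fs = decomp@fs,
            labels = decomp@labels)
}
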