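# Step 3: automatic identification of ocular components. Ocular activity
# projects dominantly onto the forehead, so an EOG component has (i)
# outlying mean absolute mixing weight over the frontal channels (Tukey
# fence Q3 + 1.5 IQR over all components' weights) and (ii) strong Pearson
# correlation with at least one frontal channel.

safeCor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    warning("zero-variance series in correlation; defining r = 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Correlations between frontal channels and independent components
#'
#' @param decomp an [ICADecomposition-class].
#' @param rec the (preprocessed) [Recording-class] the decomposition was
#'   fitted on.
#' @param frontal frontal channel labels (or a montage list with a
#'   \code{frontal} entry).
#' @return Matrix of Pearson correlations, frontal channels x components.
#' @export
frontalCorrelations <- function(decomp, rec, frontal) {
  if (is.list(frontal)) frontal <- frontal$frontal
  idx <- resolveMontage(rec, frontal)
  S <- decomp@S
  R <- matrix(0, length(idx), nrow(S),
              dimnames = list(names(idx), NULL))
  for (i in seq_along(idx))
    for (j in seq_len(nrow(S)))
      R[i, j] <- safeCor(rec@data[idx[i], ], S[j, ])
  R
}

#' Mean absolute frontal mixing weight per component
#'
#' \code{wbar[j] = mean_i |A[i, j]|} over the frontal channels \code{i}.
#'
#' @param A mixing matrix, channels x components.
#' @param frontalIdx integer indices of the frontal channels.
#' @return Nonnegative numeric vector, one entry per component.
#' @export
meanAbsFrontalWeights <- function(A, frontalIdx) {
  if (!length(frontalIdx)) stop("frontalIdx must be non-empty")
  colMeans(abs(A[frontalIdx, , drop = FALSE]))
}

#' Tukey-fence outlier flagging of component weights
#'
#' Threshold is \code{Q3 + 1.5 IQR} over the weight vector (quantiles by
#' linear interpolation between order statistics, \code{type = 7}); a
#' component is flagged iff its weight is strictly above the fence.
#'
#' @param wbar numeric vector of component weights (length >= 4 so the
#'   quartiles are meaningful).
#' @return List with \code{threshold} and integer \code{flagged}.
#' @examples
#' tukeyFlag(c(1, 2, 3, 4, 100))
#' @export
tukeyFlag <- function(wbar) {
  if (length(wbar) < 4L)
    stop("need at least 4 components for a meaningful fence; ",
         "select artifact components manually instead")
  q <- stats::quantile(wbar, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2L] + 1.5 * (q[2L] - q[1L])
  list(threshold = threshold, flagged = which(wbar > threshold))
}

#' Automatic identification of EOG components
#'
#' Combines the weight fence with a confirmatory correlation gate: a
#' component is flagged iff its mean absolute frontal weight exceeds the
#' Tukey fence and its best absolute frontal correlation reaches
#' \code{minAbsCorr}. An empty flagged set is a legal outcome (recording
#' free of ocular artifacts).
#'
#' @inheritParams frontalCorrelations
#' @param minAbsCorr minimum max-|r| over frontal channels (default 0.75).
#' @return An [EOGReport-class].
#' @export
identifyEOGComponents <- function(decomp, rec, frontal, minAbsCorr = 0.75) {
  if (is.list(frontal)) frontal <- frontal$frontal
  idx <- resolveMontage(rec, frontal)
  R <- frontalCorrelations(decomp, rec, frontal)
  wbar <- meanAbsFrontalWeights(decomp@A, idx)
  fence <- tukeyFlag(wbar)
  maxAbsR <- apply(abs(R), 2L, max)
  flagged <- fence$flagged[maxAbsR[fence$flagged] >= minAbsCorr]
  new("EOGReport", corr = R, wbar = unname(wbar),
      threshold = fence$threshold,
      flagged = as.integer(flagged),
      ranks = as.integer(order(maxAbsR, decreasing = TRUE)),
      minAbsCorr = minAbsCorr)
}
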