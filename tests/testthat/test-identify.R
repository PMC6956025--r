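# brute-force type-7 quantile oracle, independent of stats::quantile
quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("the Tukey fence matches a brute-force quantile oracle", {
  wbar <- c(1, 2, 3, 4, 100)
  thrOracle <- quantile7(wbar, 0.75) +
    1.5 * (quantile7(wbar, 0.75) - quantile7(wbar, 0.25))
  expect_equal(thrOracle, 7)
  res <- tukeyFlag(wbar)
  expect_equal(res$threshold, thrOracle)
  expect_equal(res$flagged, 5L)

  wbar2 <- c(rep(0.1, 7), 1.0)
  res2 <- tukeyFlag(wbar2)
  thr2 <- quantile7(wbar2, 0.75) +
    1.5 * (quantile7(wbar2, 0.75) - quantile7(wbar2, 0.25))
  expect_equal(res2$threshold, thr2)
  expect_equal(res2$flagged, 8L)

  set.seed(1)
  for (rep in 1:20) {                       # property: oracle agreement
    w <- rexp(sample(4:30, 1))
    r <- tukeyFlag(w)
    expect_equal(r$threshold,
                 quantile7(w, 0.75) +
                   1.5 * (quantile7(w, 0.75) - quantile7(w, 0.25)))
    expect_setequal(r$flagged, which(w > r$threshold))
  }
})

test_that("equal weights flag nothing (strict inequality) and short input errors", {
  res <- tukeyFlag(rep(2.5, 6))
  expect_equal(res$threshold, 2.5)
  expect_length(res$flagged, 0L)
  expect_error(tukeyFlag(c(1, 2, 3)), "manual")
})

test_that("mean absolute frontal weights follow |.|-then-mean", {
  A <- cbind(c(1, -3, 0), c(0, 0, 5), c(-2, 2, 1))
  expect_equal(unname(meanAbsFrontalWeights(A, 1:2)), c(2, 0, 2))
  expect_equal(unname(meanAbsFrontalWeights(A, 2L)), c(3, 0, 2))
  A0 <- cbind(c(0, 0), c(1, 1))
  expect_equal(unname(meanAbsFrontalWeights(A0, 1:2)), c(0, 1))
  expect_error(meanAbsFrontalWeights(A, integer(0)), "non-empty")
})

test_that("frontal correlations behave like Pearson correlation", {
  fs <- 100
  t <- (0:999) / fs
  comp <- sin(2 * pi * 5 * t)
  rec <- Recording(rbind(3 * comp, cos(2 * pi * 5 * t)), fs = fs,
                   labels = c("Fp1", "Fp2"))
  dec <- new("ICADecomposition", A = diag(2), W = diag(2),
             S = rbind(comp, rnorm(1000)), center = c(0, 0),
             whitener = diag(2), converged = TRUE, nIter = 1L,
             seed = 1L, fs = fs, labels = c("Fp1", "Fp2"))
  R <- frontalCorrelations(dec, rec, c("Fp1", "Fp2"))
  expect_equal(unname(R["Fp1", 1]), 1)      # scaling-invariant
  expect_lt(abs(R["Fp2", 1]), 1e-6)         # sin vs cos orthogonal
  # zero-variance series defines r = 0 with a warning
  dec@S[2, ] <- 0
  expect_warning(eogica:::safeCor(rec@data[1, ], dec@S[2, ]),
                 "zero-variance")
  R2 <- suppressWarnings(frontalCorrelations(dec, rec, c("Fp1", "Fp2")))
  expect_equal(unname(R2[, 2]), c(0, 0))
})

test_that("flagging is stable under component permutation and rescaling", {
  ds <- simulateDataset(duration = 30, saccadeRate = 0, seed = 41)
  pre <- preprocessRecording(ds$contaminated)
  dec <- suppressWarnings(fitInfomax(pre, seed = 41))
  rep1 <- identifyEOGComponents(dec, pre, c("Fp1", "Fp2", "F7", "F8"))
  k <- nrow(dec@S)
  perm <- rev(seq_len(k))
  dp <- dec
  dp@A <- dec@A[, perm]; dp@W <- dec@W[perm, ]; dp@S <- dec@S[perm, ]
  rep2 <- identifyEOGComponents(dp, pre, c("Fp1", "Fp2", "F7", "F8"))
  expect_setequal(match(rep1@flagged, perm), rep2@flagged)
  # global rescaling of the recording rescales A and S inversely
  sc <- Recording(pre@data * 7, fs = pre@fs, labels = pre@labels)
  ds2 <- dec
  ds2@A <- dec@A * 7; ds2@center <- dec@center * 7
  rep3 <- identifyEOGComponents(ds2, sc, c("Fp1", "Fp2", "F7", "F8"))
  expect_equal(rep3@flagged, rep1@flagged)
})

test_that("simultaneous blink and gaze sources yield two flagged components", {
  # a heavy eye-mover: dense, strong gaze shifts on top of blinking.
  # With two strong sources sharing the forehead, neither component
  # dominates a frontal channel the way a lone blink does, so the
  # confirmatory correlation gate is relaxed below its single-artifact
  # default -- the situation the exposed parameter exists for.
  ds <- simulateDataset(duration = 90, blinkRate = 12, saccadeRate = 30,
                        bMax = 2, seed = 77)
  res <- suppressWarnings(removeEOG(
    ds$contaminated, method = "pm", seed = 77,
    config = list(identify = list(min_abs_corr = 0.65))))
  S <- sourceMatrix(res@decomposition)
  vf <- bandpassFilter(Recording(rbind(ds$veog, ds$veog),
                                 fs = 200))@data[1, ]
  hf <- bandpassFilter(Recording(rbind(ds$heog, ds$heog),
                                 fs = 200))@data[1, ]
  bc <- which.max(abs(cor(vf, t(S))))
  hc <- which.max(abs(cor(hf, t(S))))
  expect_false(bc == hc)                    # sources separated
  expect_gt(abs(cor(vf, S[bc, ])), 0.85)
  expect_gt(abs(cor(hf, S[hc, ])), 0.85)
  fl <- flaggedComponents(res@report)
  expect_true(bc %in% fl)
  expect_true(hc %in% fl)
})
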