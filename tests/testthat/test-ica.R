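test_that("whitening produces identity covariance and zero means", {
  set.seed(11)
  x <- matrix(rnorm(4 * 3000), 4, 3000) + 1:4
  cw <- centerWhiten(x)
  expect_lt(max(abs(rowMeans(cw$z))), 1e-10)
  covz <- tcrossprod(cw$z) / (ncol(cw$z) - 1)
  expect_lt(max(abs(covz - diag(nrow(covz)))), 1e-8)
})

test_that("whitening an exactly-white input yields an orthogonal map", {
  set.seed(12)
  raw <- matrix(rnorm(4 * 3000), 4, 3000)
  z0 <- centerWhiten(raw)$z                 # exactly white by construction
  W <- centerWhiten(z0)$whitener
  expect_lt(max(abs(t(W) %*% W - diag(4))), 1e-6)
})

test_that("degenerate channels are refused", {
  x <- matrix(rnorm(3 * 500), 3, 500)
  x[2, ] <- 7
  expect_error(centerWhiten(x), "zero variance")
  y <- matrix(rnorm(3 * 500), 3, 500)
  y <- rbind(y, y[1, ])                     # duplicated channel
  expect_error(centerWhiten(y), "rank-deficient")
  expect_error(fitInfomax(y, seed = 1), "rank-deficient")
})

test_that("Infomax recovers Laplacian sources through a known mixing", {
  toy <- genICAToy(3, 20000, seed = 11)
  dec <- fitInfomax(toy$mixture, seed = 11)
  expect_lt(max(abs(dec@A %*% dec@W - diag(3))), 1e-8)
  expect_lt(max(abs(dec@A %*% dec@S + dec@center - toy$mixture)), 1e-6)
  cors <- abs(cor(t(toy$sources), t(dec@S)))
  # greedy permutation matching: each true source to its best component
  perm <- integer(3)
  for (i in order(apply(cors, 1, max), decreasing = TRUE)) {
    j <- which.max(replace(cors[i, ], perm[perm > 0], -1))
    perm[i] <- j
  }
  expect_equal(sort(perm), 1:3)             # a true permutation
  for (i in 1:3) expect_gt(cors[i, perm[i]], 0.95)
})

test_that("separation quality is high in the Amari sense", {
  toy <- genICAToy(3, 20000, seed = 11)
  dec <- fitInfomax(toy$mixture, seed = 11)
  P <- abs(dec@W %*% toy$mixing)
  rowPart <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colPart <- sum(colSums(P / rep(apply(P, 2, max),
                                 each = nrow(P))) - 1)
  amari <- (rowPart + colPart) / (2 * 3 * 2)
  expect_lt(amari, 0.1)
})

test_that("fits are bit-reproducible given the seed", {
  toy <- genICAToy(3, 8000, seed = 5)
  d1 <- fitInfomax(toy$mixture, seed = 99)
  d2 <- fitInfomax(toy$mixture, seed = 99)
  expect_lt(max(abs(d1@S - d2@S)), 1e-12)
  expect_identical(d1@W, d2@W)
})

test_that("sources have unit variance and positive dominant weights", {
  toy <- genICAToy(3, 8000, seed = 6)
  dec <- fitInfomax(toy$mixture, seed = 6)
  expect_equal(apply(dec@S, 1, sd), rep(1, 3), tolerance = 1e-10)
  for (j in 1:3) expect_gt(max(dec@A[, j]), 0)
})

test_that("average-referenced data are fitted in a reduced subspace", {
  set.seed(21)
  rec <- averageReference(noiseRecording(nch = 5, n = 4000))
  dec <- suppressWarnings(fitInfomax(rec, seed = 1))
  expect_equal(nrow(dec@S), 4L)             # one dimension dropped
  expect_lt(max(abs(dec@W %*% dec@A - diag(4))), 1e-8)
  # A W projects onto the data subspace, so reconstruction round-trips
  expect_lt(max(abs(dec@A %*% dec@S + dec@center - rec@data)), 1e-6)
})

test_that("sources/reconstruct honour their linear contracts", {
  toy <- genICAToy(3, 8000, seed = 8)
  dec <- fitInfomax(toy$mixture, seed = 8)
  expect_lt(max(abs(icaSources(dec, toy$mixture) - dec@S)), 1e-10)
  atMean <- matrix(dec@center, 3, 10)
  expect_lt(max(abs(icaSources(dec, atMean))), 1e-10)
  rt <- reconstructRecording(dec)
  expect_lt(max(abs(rt@data - toy$mixture)), 1e-6)
  rj <- reconstructRecording(dec, reject = 2L)
  manual <- toy$mixture - dec@A[, 2] %o% dec@S[2, ]
  expect_lt(max(abs(rj@data - manual)), 1e-6)
  expect_error(reconstructRecording(dec, reject = 9L), "out of range")
  # modifying one component on [a, b) only changes those samples
  S2 <- dec@S
  S2[1, 101:200] <- 0
  out <- reconstructRecording(dec, S = S2)
  expect_equal(out@data[, -(101:200)], rt@data[, -(101:200)])
  expect_error(icaSources(dec, matrix(0, 5, 10)), "channels")
})
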