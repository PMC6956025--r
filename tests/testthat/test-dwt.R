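test_that("the multilevel transform reconstructs perfectly", {
  set.seed(13)
  for (n in c(200, 256, 321, 1000)) {
    x <- rnorm(n)
    w <- dwtMultilevel(x)
    expect_lt(max(abs(idwtMultilevel(w) - x)), 1e-8)
  }
  # other bases too
  for (b in c("haar", "db4", "sym6")) {
    x <- rnorm(300)
    w <- dwtMultilevel(x, basis = b, levels = 4)
    expect_lt(max(abs(idwtMultilevel(w) - x)), 1e-8)
  }
})

test_that("the transform is linear coefficient-wise", {
  set.seed(14)
  x <- rnorm(200); y <- rnorm(200)
  wx <- dwtMultilevel(x); wy <- dwtMultilevel(y)
  wxy <- dwtMultilevel(2 * x + 3 * y)
  for (nm in names(wx@details))
    expect_lt(max(abs(wxy@details[[nm]] -
                        2 * wx@details[[nm]] - 3 * wy@details[[nm]])),
              1e-8)
  expect_lt(max(abs(wxy@approx - 2 * wx@approx - 3 * wy@approx)), 1e-8)
})

test_that("coefficient energy equals signal energy", {
  set.seed(15)
  for (n in c(200, 256, 500)) {
    x <- rnorm(n)
    w <- dwtMultilevel(x)
    coefEnergy <- sum(unlist(w@details)^2) + sum(w@approx^2)
    expect_equal(coefEnergy, sum(x^2), tolerance = 1e-6)
  }
})

test_that("too-short segments and unknown bases are refused", {
  expect_error(dwtMultilevel(rnorm(20), levels = 5), "32")
  expect_error(dwtMultilevel(rnorm(100), basis = "nope"), "unknown")
  expect_error(highpassReconstruct(dwtMultilevel(rnorm(200)),
                                   keep = character(0)), "at least one")
  expect_error(highpassReconstruct(dwtMultilevel(rnorm(200)),
                                   keep = "D9"), "unknown band")
})

test_that("retaining D1:D3 passes 30 Hz and blocks 2 Hz at fs 200", {
  fs <- 200
  t <- (0:199) / fs
  s2 <- sin(2 * pi * 2 * t)
  s30 <- sin(2 * pi * 30 * t)
  r2 <- highpassReconstruct(dwtMultilevel(s2))
  r30 <- highpassReconstruct(dwtMultilevel(s30))
  expect_lt(sqrt(mean(r2^2) / mean(s2^2)), 0.15)
  expect_gt(sqrt(mean(r30^2) / mean(s30^2)), 0.85)
  expect_equal(highpassReconstruct(dwtMultilevel(numeric(200))),
               numeric(200))
})

test_that("selective cleaning touches only the windows", {
  set.seed(16)
  y <- rnorm(2000)
  w0 <- buildWindows(integer(0), 200, 2000)
  expect_identical(cleanComponentSelective(y, w0, 200), y)
  w1 <- buildWindows(1000L, 200, 2000)      # one 1-s window
  out <- cleanComponentSelective(y, w1, 200)
  mask <- eogica:::windowMask(w1)
  expect_identical(out[!mask], y[!mask])    # bit-equal outside
  expect_false(identical(out[mask], y[mask]))
  # max |value| outside windows never grows
  expect_lte(max(abs(out[!mask])), max(abs(y[!mask])))
})

test_that("a window spanning everything equals plain high-pass retention", {
  set.seed(17)
  y <- rnorm(1600)
  wAll <- new("ArtifactWindows",
              intervals = cbind(start = 1L, end = 1601L),
              nSamples = 1600L, coverage = 1)
  out <- cleanComponentSelective(y, wAll, 200, crossfade = 0)
  ref <- highpassReconstruct(dwtMultilevel(y))
  expect_lt(max(abs(out - ref)), 1e-10)
})

test_that("wavelet thresholding removes large spikes and passes small signals", {
  set.seed(18)
  y <- rnorm(2000, sd = 10)
  y[700:720] <- y[700:720] + 500            # one big artifact
  out <- wicaCleanComponent(y)
  expect_lt(max(abs(out[700:720])), 0.2 * 500)
  # with every coefficient below threshold the series is unchanged
  z <- rnorm(512)
  w <- dwtMultilevel(z)
  sigma <- median(abs(w@details$D1)) / 0.6745
  maxc <- max(abs(c(unlist(w@details), w@approx)))
  K <- 1.5 * maxc / (sqrt(2 * log(512)) * sigma)   # guarantees no zeroing
  expect_lt(max(abs(wicaCleanComponent(z, thresholdScale = K) - z)), 1e-8)
  expect_equal(wicaCleanComponent(numeric(300)), numeric(300))
})

test_that("whole-component rejection obeys the linear identity", {
  toy <- genICAToy(4, 6000, seed = 19)
  dec <- fitInfomax(toy$mixture, seed = 19)
  expect_lt(max(abs(rejectClean(dec, integer(0))@data - toy$mixture)),
            1e-6)
  rj <- rejectClean(dec, 3L)
  manual <- toy$mixture - dec@A[, 3] %o% dec@S[3, ]
  expect_lt(max(abs(rj@data - manual)), 1e-6)
  all4 <- rejectClean(dec, 1:4)
  expect_lt(max(abs(all4@data - dec@center)), 1e-6)
})
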