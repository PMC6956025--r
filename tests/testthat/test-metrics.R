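test_that("lambda has its fixed points at 0 and 100", {
  set.seed(20)
  pure <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  contam <- pure + rnorm(2000, sd = 3)
  expect_equal(lambdaRemoval(pure, contam, contam), 0)
  # a cleaned series whose correlation with pure equals pure's lag-1
  # autocorrelation: mix pure with independent noise to hit that r exactly
  n <- length(pure)
  Rref <- cor(pure[-n], pure[-1])
  noise <- rnorm(n)
  noise <- residuals(lm(noise ~ pure))      # orthogonal to pure
  alpha <- sqrt(1 / Rref^2 - 1) * sd(pure) / sd(noise)
  cleaned <- pure + alpha * noise
  expect_equal(cor(pure, cleaned), Rref, tolerance = 1e-10)
  expect_equal(lambdaRemoval(pure, contam, cleaned), 100,
               tolerance = 1e-6)
  # invariant to positive rescaling of the cleaned series
  expect_equal(lambdaRemoval(pure, contam, 3.7 * contam),
               lambdaRemoval(pure, contam, contam))
  expect_warning(lambdaRemoval(pure, pure, contam), "undefined")
})

test_that("delta-SNR reflects error-variance ratios in dB", {
  set.seed(21)
  pure <- rnorm(5000, sd = 10)
  err <- rnorm(5000)
  contam <- pure + err
  expect_equal(deltaSNR(pure, contam, contam), 0)
  expect_equal(deltaSNR(pure, contam, pure + err / sqrt(10)), 10,
               tolerance = 1e-10)
  expect_equal(deltaSNR(pure, contam, pure + err * sqrt(10)), -10,
               tolerance = 1e-10)
  expect_equal(deltaSNR(pure, contam, pure), 120)   # capped
})

test_that("rmse is a symmetric metric with exact simple cases", {
  x <- rnorm(100)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 2.5), 2.5)
  y <- rnorm(100)
  expect_equal(rmse(x, y), rmse(y, x))
})

test_that("coherence is 1 for identical series and low for independent noise", {
  set.seed(22)
  fs <- 200
  x <- rnorm(60 * fs)
  m <- msc(x, x, fs)
  expect_true(all(abs(m$coherence - 1) < 1e-8))
  y <- rnorm(60 * fs)
  m2 <- msc(x, y, fs)
  expect_lt(mean(m2$coherence), 0.2)        # expectation ~ 1/nsegments
  expect_true(all(m2$coherence >= 0 & m2$coherence <= 1))
  expect_error(msc(rnorm(300), rnorm(300), fs), "2 Welch segments")
})

test_that("sensitivity reproduces the worked annotation counts", {
  # 218 true peaks, one missed
  truth <- seq(1, by = 2, length.out = 218)
  detected <- truth[-50]
  r <- peakSensitivity(detected, truth)
  expect_equal(r$TP, 217L)
  expect_equal(r$FN, 1L)
  expect_equal(round(r$Se, 2), 99.54)
  # 78 true peaks, all found
  truth2 <- seq(1, by = 2, length.out = 78)
  r2 <- peakSensitivity(truth2 + 0.05, truth2)
  expect_equal(r2$Se, 100)
  expect_equal(r2$TP, 78L)
  # no detections at all
  r3 <- peakSensitivity(numeric(0), c(1, 2, 3, 4, 5))
  expect_equal(r3$Se, 0)
  expect_warning(r4 <- peakSensitivity(c(1, 2), numeric(0)), "undefined")
  expect_true(is.na(r4$Se))
  # matching is one-to-one: two detections cannot claim one truth
  r5 <- peakSensitivity(c(1.0, 1.01), c(1.0, 5.0))
  expect_equal(r5$TP, 1L)
})

test_that("evaluateCleaning aggregates per-channel metrics", {
  set.seed(23)
  fs <- 200
  pure <- Recording(matrix(rnorm(2 * 20 * fs, sd = 10), 2, 20 * fs),
                    fs = fs)
  noise <- matrix(rnorm(2 * 20 * fs, sd = 5), 2, 20 * fs)
  contam <- Recording(pure@data + noise, fs = fs)
  cleaned <- Recording(pure@data + noise / 4, fs = fs)
  met <- evaluateCleaning(pure, contam, cleaned)
  expect_equal(nrow(met@perChannel), 2L)
  expect_equal(met@means[["rmse"]], mean(met@perChannel$rmse))
  expect_gt(met@means[["deltaSNR"]], 10)    # error var down 16x ~ 12 dB
  expect_true(all(met@mscCurve >= 0 & met@mscCurve <= 1))
})
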