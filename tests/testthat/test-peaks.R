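test_that("an isolated spike is detected by direct evaluation of the rule", {
  set.seed(9)
  y <- rnorm(2000, sd = 0.01)
  y[500] <- 10
  thr <- 3 * mean(abs(y))                   # explicit rule evaluation
  expect_lt(thr, 0.1)
  pk <- detectEOGPeaks(y, fs = 200)
  expect_equal(pk@samples, 500L)
  expect_equal(pk@amplitudes, 10)
})

test_that("peaks closer than 0.5 s are thinned to one survivor", {
  y <- rnorm(2000, sd = 0.01)
  y[500] <- 10
  y[560] <- 10                              # 0.3 s later at fs = 200
  pk <- detectEOGPeaks(y, fs = 200)
  expect_equal(pk@samples, 500L)            # equal heights: first wins
  y2 <- y; y2[560] <- 12
  # default keeps the larger contender; earliest mode keeps the first
  expect_equal(detectEOGPeaks(y2, fs = 200)@samples, 560L)
  expect_equal(detectEOGPeaks(y2, fs = 200, tieBreak = "earliest")@samples,
               500L)
  y3 <- y; y3[700] <- 10                    # 1 s apart: both kept
  expect_equal(detectEOGPeaks(y3, fs = 200)@samples, c(500L, 700L))
})

test_that("a unit sinusoid has no peaks above 3 E{|y|}", {
  t <- (0:1999) / 200
  y <- sin(2 * pi * 1 * t)
  expect_equal(mean(abs(y)), 2 / pi, tolerance = 1e-3)   # analytic mean
  expect_length(detectEOGPeaks(y, fs = 200)@samples, 0L)
})

test_that("peak detection is invariant to positive rescaling", {
  set.seed(10)
  y <- rnorm(4000, sd = 1)
  y[c(400, 1400, 2400)] <- c(20, 25, 30)
  p1 <- detectEOGPeaks(y, fs = 200)
  p2 <- detectEOGPeaks(y * 137.5, fs = 200)
  expect_equal(p1@samples, p2@samples)
})

test_that("windows are half-open, clipped and merged", {
  # peak at 2.0 s (sample 401), fs = 200: window [301, 501)
  w <- buildWindows(401L, fs = 200, nSamples = 2000)
  expect_equal(unname(windowIntervals(w)[1, ]), c(301L, 501L))
  expect_equal(windowCoverage(w), 200 / 2000)
  # peak at 0.1 s clips at the start: [1, 121)
  w2 <- buildWindows(21L, fs = 200, nSamples = 2000)
  expect_equal(unname(windowIntervals(w2)[1, ]), c(1L, 121L))
  # peaks at 2.0 and 2.6 s merge into [301, 621)
  w3 <- buildWindows(c(401L, 521L), fs = 200, nSamples = 2000)
  expect_equal(nrow(windowIntervals(w3)), 1L)
  expect_equal(unname(windowIntervals(w3)[1, ]), c(301L, 621L))
  expect_equal(windowCoverage(w3), 320 / 2000)
})

test_that("windows always contain their generating peaks", {
  set.seed(11)
  for (rep in 1:10) {
    y <- rnorm(3000)
    y[sample(100:2900, 5)] <- 50
    pk <- detectEOGPeaks(y, fs = 200)
    w <- buildWindows(pk, fs = 200, nSamples = 3000)
    mask <- eogica:::windowMask(w)
    expect_true(all(mask[pk@samples]))
  }
})

test_that("the rejection decision is strict at the 60% boundary", {
  mk <- function(cov) new("ArtifactWindows",
                          intervals = cbind(start = 1L,
                                            end = as.integer(1 + cov * 1000)),
                          nSamples = 1000L, coverage = cov)
  expect_equal(decideAction(mk(0.61)), "reject_component")
  expect_equal(decideAction(mk(0.60)), "correct_in_windows")
  expect_equal(decideAction(buildWindows(integer(0), 200, 1000)),
               "correct_in_windows")
})
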