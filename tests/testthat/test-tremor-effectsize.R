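test_that("Cliff's delta matches its definition on separated, identical and random samples", {
  expect_equal(cliffsDelta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cliffsDelta(numeric(0), 1), "empty")

  # brute-force double loop agreement, antisymmetry, and the large-n rank
  # path agreeing with the double loop
  withSeed(99, {
    for (i in 1:20) {
      a <- sample(0:10, sample(3:50, 1), replace = TRUE)
      b <- sample(0:10, sample(3:50, 1), replace = TRUE)
      brute <- (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) /
        (length(a) * length(b))
      expect_equal(cliffsDelta(a, b), brute)
      expect_equal(cliffsDelta(b, a), -brute)
    }
    a <- rnorm(700); b <- rnorm(800, 0.3)   # forces the rank path
    brute <- (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) /
      (length(a) * length(b))
    expect_equal(cliffsDelta(a, b), brute)
  })
})

test_that("bootstrap CI brackets the point estimate and degenerates correctly", {
  withSeed(7, {
    ci <- bootstrapCI(rep(2, 10), rep(2, 10), nBoot = 200)
    expect_equal(ci$delta, 0)
    expect_equal(c(ci$ciLow, ci$ciHigh), c(0, 0))
    ci <- bootstrapCI(11:20, 1:10, nBoot = 200)
    expect_equal(ci$delta, 1)
    expect_equal(ci$ciHigh, 1)
    a <- rnorm(30, 1); b <- rnorm(30)
    ci <- bootstrapCI(a, b, nBoot = 500)
    expect_true(ci$ciLow <= ci$delta && ci$delta <= ci$ciHigh)
    expect_true(ci$ciLow >= -1 && ci$ciHigh <= 1)
    expect_warning(bootstrapCI(1, c(1, 2), nBoot = 50), "degenerate")
  })
})

test_that("interval to frequency conversion is the reciprocal in Hz", {
  expect_equal(intervalToFrequency(20), 50)
  expect_equal(intervalToFrequency(30), 1000 / 30)
  expect_equal(intervalToFrequency(100), 10)
  expect_error(intervalToFrequency(0), "positive")
})

test_that("shake detection finds alternating extrema above the amplitude cut", {
  fps <- 1000
  # smooth monotone trace: no extrema
  expect_equal(nrow(detectShakeEvents(seq(0, 50, length.out = 500), fps)), 0L)
  # 20-Hz wave, peak-to-valley 5 px, 8 cycles -> 16 alternating events
  tt <- (0:399) / 1000
  sq <- c(rep(0, 100), 2.5 * sin(2 * pi * 20 * tt), rep(0, 150))
  ev <- detectShakeEvents(sq, fps, minAmp = 3)
  expect_equal(nrow(ev), 16L)
  expect_true(all(ev$amplitude >= 3))
  expect_true(all(ev$polarity[-1] != ev$polarity[-nrow(ev)]))
  # same wave at peak-to-valley 2 px: below the cut
  sq2 <- c(rep(0, 100), 1 * sin(2 * pi * 20 * tt), rep(0, 150))
  expect_equal(nrow(detectShakeEvents(sq2, fps, minAmp = 3)), 0L)
})

test_that("tremor events are runs of >= 3 shakes with < 100 ms gaps", {
  fps <- 1000
  mk <- function(frames) data.frame(frame = frames, axis = "x",
                                    polarity = rep_len(c("peak", "valley"),
                                                       length(frames)),
                                    amplitude = 5, value = 0)
  expect_equal(nrow(detectTremorEvents(mk(c(100, 120)), fps)), 0L)
  tr <- detectTremorEvents(mk(seq(100, by = 25, length.out = 5)), fps)
  expect_equal(nrow(tr), 5L)          # every member of the run counts
  expect_equal(unique(tr$run), 1L)
  expect_equal(nrow(detectTremorEvents(mk(seq(100, by = 150, length.out = 6)),
                                       fps)), 0L)
})

test_that("interval spectrum recovers an injected oscillation and the permutation test calibrates", {
  fps <- 1000
  syn <- synthTrace(40, 5, fps = fps, nFrames = 2000, noiseSD = 0)
  sh <- detectShakeEvents(syn$trace, fps, minAmp = 3)
  tr <- detectTremorEvents(sh, fps)
  expect_gt(nrow(tr), 10)
  spec <- intervalSpectrum(tr, fps)
  expect_equal(unname(spec$dominantBin), c(20, 30))   # 25-ms period
  withSeed(31, {
    p <- intervalPermutationTest(spec$intervals, spec$dominantBin,
                                 nIter = 10000L)
    expect_lt(p, 0.01)
  })
  # no false tremor on a smooth noise-free trace (the stride flicks sit
  # below the 3-px cut)
  smooth <- synthTrace(40, 0, fps = fps, nFrames = 2000)
  sh0 <- detectShakeEvents(smooth$trace, fps, minAmp = 3)
  expect_equal(nrow(detectTremorEvents(sh0, fps)), 0L)

  # calibration: under the null the test holds its level (the statistic is
  # discrete, so the p distribution is sub-uniform rather than exactly
  # uniform)
  withSeed(5, {
    ps <- as.numeric(replicate(300, {
      iv <- runif(20, 10, 110)
      intervalPermutationTest(iv, c(20, 30), nIter = 200L)
    }))
    for (alpha in c(0.05, 0.1, 0.25))
      expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha / 300))
  })
  expect_error(intervalPermutationTest(c(1, 2), c(0, 10)), "insufficient")
})

test_that("permutation p-value is reproducible under a fixed seed and bounded below", {
  iv <- c(21, 22, 24, 26, 28, 25, 23)
  p1 <- withSeed(3, intervalPermutationTest(iv, c(20, 30), nIter = 10L))
  p2 <- withSeed(3, intervalPermutationTest(iv, c(20, 30), nIter = 10L))
  expect_identical(as.numeric(p1), as.numeric(p2))
  # nearly all intervals in the bin with a wide observed range: the null
  # can essentially never match, so p approaches 1/(1+nIter)
  withSeed(4, {
    iv2 <- c(runif(28, 20, 29.9), 5, 200)
    p <- intervalPermutationTest(iv2, c(20, 30), nIter = 1000L)
    expect_lte(as.numeric(p), 2 / 1001)
  })
})
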