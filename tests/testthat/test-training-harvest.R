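test_that("training frames are sampled every 20th frame with degenerate fallback", {
  expect_length(sampleTrainingFrames(1000L), 50L)
  expect_equal(sampleTrainingFrames(19L), 1:19)
  expect_equal(sampleTrainingFrames(40L), c(1L, 21L))   # 0-based {0, 20}
  expect_equal(sampleTrainingFrames(smallWalker()$stack, 20L),
               seq(1L, 80L, by = 20L))
})

test_that("skeleton/edge harvest keeps thin structures and excludes the body interior", {
  # a 1-px line: every pixel is skeleton and edge, so all are positives
  m <- matrix(FALSE, 40, 40); m[20, 5:35] <- TRUE
  pool <- harvestConfidentPixels(m, 1L)
  expect_equal(sort(pool$positives$x), 4:34)
  expect_true(all(pool$positives$y == 19))

  # a filled disk: the skeleton is central, edges peripheral, and the
  # deep-interior thinness filter leaves no positives inside
  d <- 41
  xg <- matrix(rep(1:d, each = d), d); yg <- matrix(rep(1:d, d), d)
  disk <- (xg - 21)^2 + (yg - 21)^2 <= 10.5^2
  poolD <- harvestConfidentPixels(disk, 1L)
  # brute-force: any reported positive must lie within legWidth/2 of the
  # boundary (thin-structure requirement)
  if (nrow(poolD$positives)) {
    dst <- HexGait:::distanceToBackground(disk)
    expect_true(all(dst[cbind(poolD$positives$y + 1,
                              poolD$positives$x + 1)] <= 2.5))
  }
  # the negative body pool avoids the grey zone around harvested legs
  expect_gt(nrow(poolD$negCore), 0)
  if (nrow(poolD$positives)) {
    posMask <- matrix(FALSE, d, d)
    posMask[cbind(poolD$positives$y + 1, poolD$positives$x + 1)] <- TRUE
    grey <- HexGait:::dilateMask(posMask, 5)
    expect_false(any(grey[cbind(poolD$negCore$y + 1,
                                poolD$negCore$x + 1)]))
  }

  # walker frame: harvested positives hit true leg midlines
  v <- smallWalker()
  mask <- extractSilhouette(v$stack@frames[[40]], v$bg)
  hp <- harvestConfidentPixels(mask, 40L)
  legs2 <- HexGait:::dilateMask(v$truth$masks[["40"]]$legs, 2)
  hitRate <- mean(legs2[cbind(hp$positives$y + 1, hp$positives$x + 1)])
  expect_gte(hitRate, 0.9)
  expect_error(harvestConfidentPixels(matrix(FALSE, 5, 5)), "empty")
})

test_that("patch extraction balances classes, pads borders and is seed-reproducible", {
  v <- smallWalker()
  st <- v$stack
  mask <- extractSilhouette(st@frames[[1]], v$bg)
  pool <- harvestConfidentPixels(mask, 1L)
  withSeed(77, ps <- extractPatches(pool, st, nPos = 300L, nNeg = 300L))
  expect_equal(nrow(ps@patches), 600L)
  expect_equal(sum(ps@labels > 0), 300L)
  expect_equal(sum(ps@labels < 0), 300L)
  expect_true(all(ps@weights == 1))
  expect_identical(ps@residuals, ps@labels)
  withSeed(77, ps2 <- extractPatches(pool, st, nPos = 300L, nNeg = 300L))
  expect_identical(ps@patches, ps2@patches)

  # a tiny pool is sampled with replacement to the requested size
  tiny <- pool; tiny$positives <- pool$positives[1:10, ]
  withSeed(1, psT <- extractPatches(tiny, st, nPos = 100L, nNeg = 50L))
  expect_equal(sum(psT@labels > 0), 100L)

  # corner pixel: the out-of-image patch region is zero-padded
  cornerPool <- structure(list(
    positives = data.frame(frame = 1L, x = 0L, y = 0L),
    negCore = data.frame(frame = 1L, x = 5L, y = 5L),
    negBand = data.frame(frame = 1L, x = 6L, y = 6L)),
    class = "LabeledPixelPool")
  withSeed(1, pc <- extractPatches(cornerPool, st, nPos = 1L, nNeg = 1L))
  pm <- matrix(pc@patches[1, ], 41, 41)
  expect_true(all(pm[1:20, ] == 0))     # rows above the image
  expect_true(all(pm[, 1:20] == 0))     # columns left of the image
  expect_gt(sum(pm[21:41, 21:41]), 0)

  # one empty class is a harvest error
  noPos <- pool; noPos$positives <- pool$positives[0, ]
  expect_error(extractPatches(noPos, st, 10L, 10L), "harvest error")
})

test_that("self-training grows pools and never shrinks recall on the walker", {
  v <- smallWalker()
  st <- v$stack
  withSeed(15, {
    res <- selfTrain(st, rounds = 2L, background = v$bg,
                     nPos = 700L, nNeg = 700L, M = 6L,
                     control = kbControl(nCandidates = 12L,
                                         kernelFitMax = 250L),
                     frameStride = 20L)
  })
  expect_s4_class(res$classifier, "KernelBoostClassifier")
  expect_gte(nrow(res$poolSizes), 1L)
  # pool sizes non-decreasing across rounds
  expect_true(all(diff(res$poolSizes$positives) >= 0))
  expect_true(all(diff(res$poolSizes$negatives) >= 0))

  # rounds = 1 is exactly a fit on the initial harvest
  withSeed(15, {
    res1 <- selfTrain(st, rounds = 1L, background = v$bg,
                      nPos = 700L, nNeg = 700L, M = 6L,
                      control = kbControl(nCandidates = 12L,
                                          kernelFitMax = 250L))
  })
  expect_equal(res1$poolSizes$round, 1L)
  f <- 40L
  mask <- extractSilhouette(st@frames[[f]], v$bg)
  c1 <- predictConfidence(res1$classifier, st@frames[[f]], mask)
  c2 <- predictConfidence(res$classifier, st@frames[[f]], mask)
  truth <- v$truth$masks[["40"]]$legs
  rec1 <- sum(c1 >= 0.65 & truth) / sum(truth)
  rec2 <- sum(c2 >= 0.65 & truth) / sum(truth)
  expect_gte(rec2, rec1 - 0.01)
})
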