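test_that("learned kernels satisfy the regularized normal equations and known limits", {
  train <- toyPatchSet(n = 160L, seed = 8)
  P <- train@patches
  w <- runif(nrow(P), 0.5, 2); r <- train@residuals
  for (spec in list(list(s = 5L, anchor = c(18L, 18L), lambda = 100),
                    list(s = 9L, anchor = c(0L, 30L), lambda = 1000))) {
    kn <- learnKernel(P, w, r, spec$s, spec$anchor, spec$lambda)
    X <- P[, HexGait:::patchCols(spec$s, spec$anchor[1], spec$anchor[2])]
    A <- crossprod(X * sqrt(w)) + spec$lambda * HexGait:::gridLaplacian(spec$s)
    b <- crossprod(X, w * r)
    res <- A %*% as.vector(kn$weights) - b
    expect_lt(sqrt(sum(res^2)), 1e-6 * sqrt(sum(b^2)) + 1e-10)
  }

  # lambda = 0 equals the generic weighted least-squares solution
  kn0 <- learnKernel(P, w, r, 4L, c(10L, 10L), 0)
  X <- P[, HexGait:::patchCols(4L, 10L, 10L)]
  oracle <- qr.solve(crossprod(X * sqrt(w)), crossprod(X, w * r))
  expect_equal(as.vector(kn0$weights), as.vector(oracle), tolerance = 1e-6)

  # huge lambda forces a (near-)constant kernel
  knC <- learnKernel(P, w, r, 6L, c(15L, 15L), 1e9)
  kv <- as.vector(knC$weights)
  expect_lt(diff(range(kv)), 1e-4 * max(abs(kv)))

  # zero residuals give the zero kernel
  knZ <- learnKernel(P, w, rep(0, nrow(P)), 5L, c(5L, 5L), 500)
  expect_equal(max(abs(knZ$weights)), 0, tolerance = 1e-12)
})

test_that("split search equals exhaustive scoring and has the stated invariances", {
  # separable responses: threshold between the groups, zero cost
  P <- toyPatchSet(n = 60L, seed = 3)@patches
  kn <- learnKernel(P, rep(1, 60), rep(c(1, -1), each = 30), 7L,
                    c(17L, 17L), 100)
  # direct check of the threshold scan on fabricated responses
  resp <- c(1, 2, 9, 10); w <- rep(1, 4); r <- c(-1, -1, 1, 1)
  th <- HexGait:::.bestThreshold(resp, w, r)
  expect_true(th$tau > 2 && th$tau < 9)
  expect_equal(c(th$etaL, th$etaR, th$cost), c(-1, 1, 0))
  # doubling the weights doubles the cost, same split
  th2 <- HexGait:::.bestThreshold(resp, 2 * w, r)
  expect_equal(th2$tau, th$tau)
  expect_equal(th2$cost, 2 * th$cost)

  # random nodes: findBestSplit equals brute force over every
  # (candidate, threshold) pair
  withSeed(19, {
    for (rep in 1:5) {
      n <- 50L
      idx <- sample(nrow(P), n, replace = TRUE)
      Pn <- P[idx, ]; wn <- runif(n, 0.5, 2); rn <- sample(c(-1, 1), n, TRUE)
      cands <- lapply(HexGait:::genCandidates(8L), function(cn)
        learnKernel(Pn, wn, rn, cn$s, cn$anchor, cn$lambda))
      best <- findBestSplit(Pn, wn, rn, cands)
      # oracle
      oracleCost <- Inf
      for (kn in cands) {
        X <- Pn[, HexGait:::patchCols(kn$s, kn$anchor[1], kn$anchor[2])]
        resp <- drop(X %*% as.vector(kn$weights))
        for (tau in sort(unique(resp))) {
          L <- resp < tau
          if (!any(L) || all(L)) next
          eL <- weighted.mean(rn[L], wn[L]); eR <- weighted.mean(rn[!L], wn[!L])
          cost <- sum(wn[L] * (eL - rn[L])^2) + sum(wn[!L] * (eR - rn[!L])^2)
          if (cost < oracleCost) oracleCost <- cost
        }
      }
      expect_equal(best$cost, oracleCost, tolerance = 1e-9)
    }
  })
})

test_that("trees honour the depth cap and beat stumps on separable textures", {
  train <- toyPatchSet(n = 300L, seed = 12)
  P <- train@patches; y <- train@labels
  w <- rep(1, 300); r <- y
  withSeed(4, {
    idx1 <- 1:100; idx2 <- 101:300
    deep <- growTree(P, w, r, idx1, idx2,
                     kbControl(nCandidates = 15L, depth = 5L))
    stump <- growTree(P, w, r, idx1, idx2,
                      kbControl(nCandidates = 15L, depth = 1L))
    expect_lte(HexGait:::treeDepth(deep), 5L)
    expect_equal(HexGait:::treeDepth(stump), 1L)
    errDeep <- mean(sign(HexGait:::treeApply(deep, P)) != y)
    errStump <- mean(sign(HexGait:::treeApply(stump, P)) != y)
    expect_lte(errDeep, errStump)
  })
})

test_that("boosting drives training error to zero with non-increasing loss; gamma = 0 scores zero", {
  train <- toyPatchSet(n = 240L, seed = 23)
  withSeed(6, {
    clf <- fitClassifier(train, M = 20L, gamma = 0.1,
                         control = kbControl(nCandidates = 10L,
                                             kernelFitMax = 200L))
    expect_equal(mean(sign(predictPatchScores(clf, train@patches)) !=
                        train@labels), 0)
    expect_true(all(diff(clf@trainingLog$loss) <= 1e-9))
    expect_lte(length(clf@learners), 20L)

    clf0 <- fitClassifier(train, M = 3L, gamma = 0,
                          control = kbControl(nCandidates = 5L))
    expect_equal(max(abs(predictPatchScores(clf0, train@patches))), 0)
  })
})

test_that("compiled confidence maps agree with the R tree evaluator and stay in [0,1]", {
  v <- smallWalker()
  st <- v$stack
  withSeed(9, {
    tf <- sampleTrainingFrames(st, 20L)
    masks <- lapply(tf, function(i) extractSilhouette(st@frames[[i]], v$bg))
    pool <- HexGait:::mergePixelPools(
      Map(function(m, i) harvestConfidentPixels(m, i), masks, tf))
    train <- extractPatches(pool, st, 800L, 800L)
    clf <- fitClassifier(train, M = 5L,
                         control = kbControl(nCandidates = 15L,
                                             kernelFitMax = 300L))
  })
  f <- 40L
  mask <- extractSilhouette(st@frames[[f]], v$bg)
  conf <- predictConfidence(clf, st@frames[[f]], mask)
  expect_true(all(conf >= 0 & conf <= 1))
  expect_true(all(conf[!mask] == 0))
  # dual route: compiled scorer vs the R patch evaluator on sampled pixels
  xy <- HexGait:::maskCoords(mask)
  sel <- xy[seq(1, nrow(xy), length.out = 25), , drop = FALSE]
  Psel <- HexGait:::.gatherPatches(st@frames[[f]], sel, 41L)
  confR <- 1 / (1 + exp(-2 * predictPatchScores(clf, Psel)))
  expect_equal(conf[cbind(sel[, 2] + 1, sel[, 1] + 1)], confR,
               tolerance = 1e-10)

  # empty mask gives an all-zero map
  conf0 <- predictConfidence(clf, st@frames[[f]],
                             matrix(FALSE, 512, 512))
  expect_equal(sum(conf0), 0)
})

test_that("classifier serialization round-trips scores exactly", {
  train <- toyPatchSet(n = 120L, seed = 31)
  withSeed(14, {
    clf <- fitClassifier(train, M = 3L,
                         control = kbControl(nCandidates = 6L))
  })
  path <- tempfile(fileext = ".json")
  saveKernelBoost(clf, path)
  clf2 <- readKernelBoost(path)
  expect_equal(predictPatchScores(clf2, train@patches),
               predictPatchScores(clf, train@patches))
  expect_equal(clf2@gamma, clf@gamma)
  unlink(path)
})
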