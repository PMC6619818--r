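# Shared fixtures, built once per test run and memoized. Small walker videos
# keep the unit tests fast; the full-scale study videos live in
# test-acceptance.R with their own cache.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A short walker with a clean loaded background (too short for the auto
# background, which needs 1.5 body lengths of travel).
smallWalker <- function() fixture("smallWalker", function() {
  p <- walkerParams(nFrames = 80L, seed = 5, occlusions = NULL, noiseSD = 1)
  v <- renderWalkerVideo(p, keepMasks = c(10L, 40L))
  v$bg <- estimateBackground(v$stack, mode = "loaded",
                             image = matrix(200, 512, 512))
  v
})

# Toy texture patches: class +1 has a bright 7x7 centre block, class -1 a
# dark one, on a noisy mid-grey background. Linearly separable by a centre
# kernel, so small forests must reach zero training error.
toyPatchSet <- function(n = 400L, seed = 42L, noise = 0.05) {
  withSeed(seed, {
    half <- n %/% 2L
    P <- matrix(runif(n * 1681, 0.45, 0.55), n, 1681)
    ctr <- as.vector(outer(18:24, (17:23) * 41L, `+`))
    P[seq_len(half), ctr] <- P[seq_len(half), ctr] + 0.35
    P[(half + 1L):n, ctr] <- P[(half + 1L):n, ctr] - 0.35
    P <- P + matrix(rnorm(n * 1681, 0, noise), n, 1681)
    labels <- rep(c(1, -1), c(half, n - half))
    new("TrainingPatchSet", patches = P, labels = labels,
        weights = rep(1, n), residuals = labels, patchSize = 41L,
        roundIndex = 1L)
  })
}

withSeed <- HexGait:::withSeed

# Brute-force assignment oracle: minimum total squared cost over all
# injective mappings of rows to columns (Inf = forbidden), maximizing the
# number of finite matches first (mirrors the gated tracker semantics).
bruteAssign <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  cols <- seq_len(nc)
  best <- NULL; bestCost <- Inf; bestMatched <- -1L
  rec <- function(r, used, acc, asn) {
    if (r > nr) {
      matched <- sum(!is.na(asn))
      if (matched > bestMatched ||
          (matched == bestMatched && acc < bestCost - 1e-12)) {
        bestMatched <<- matched; bestCost <<- acc; best <<- asn
      }
      return()
    }
    for (j in cols[!used]) {
      if (is.finite(cost[r, j]))
        rec(r + 1L, `[<-`(used, j, TRUE), acc + cost[r, j],
            `[<-`(asn, r, j))
    }
    rec(r + 1L, used, acc, asn)   # leave row r unmatched
  }
  rec(1L, rep(FALSE, nc), 0, rep(NA_integer_, nr))
  list(assign = best, cost = bestCost, matched = bestMatched)
}
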