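# Gradient boosting with quadratic approximation over decision trees whose
# split features are convolution kernels learned by regularized least
# squares. The boosting loss is the exponential loss L(y, phi) = exp(-y*phi),
# for which the Newton weights are w = exp(-y*phi) and the pseudo-residuals
# reduce to the labels themselves.

.kbCache <- new.env(parent = emptyenv())

# 4-neighbour graph Laplacian of an s x s pixel grid (column-major order),
# the smoothness penalty matrix for kernel learning. Cached per size.
gridLaplacian <- function(s) {
  key <- as.character(s)
  if (!is.null(.kbCache[[key]])) return(.kbCache[[key]])
  p <- s * s
  L <- matrix(0, p, p)
  id <- function(row, col) (col - 1L) * s + row
  for (col in seq_len(s)) for (row in seq_len(s)) {
    i <- id(row, col)
    if (row < s) { j <- id(row + 1L, col); L[i, j] <- L[j, i] <- -1 }
    if (col < s) { j <- id(row, col + 1L); L[i, j] <- L[j, i] <- -1 }
  }
  diag(L) <- -rowSums(L) + diag(L) * 0
  .kbCache[[key]] <- L
  L
}

# Column indices (into the flattened patchSize^2 patch vector) of the s x s
# window anchored at 0-based (ar, ac) = (row, col) offsets.
patchCols <- function(s, ar, ac, patchSize = 41L) {
  rows <- (ar + 1L):(ar + s)           # 1-based patch rows
  cols <- (ac):(ac + s - 1L)           # 0-based patch cols
  as.vector(outer(rows, cols * patchSize, `+`))
}

# Random candidate kernel specs: size uniform in sizeRange, anchor uniform
# among placements keeping the window inside the patch, lambda drawn from the
# configured set. Weights are filled in by learnKernel at the node.
genCandidates <- function(n, patchSize = 41L, sizeRange = c(4L, 19L),
                          lambdas = c(100, 500, 1000)) {
  lapply(seq_len(n), function(i) {
    s <- sample(sizeRange[1L]:sizeRange[2L], 1L)
    list(s = s,
         anchor = c(sample.int(patchSize - s + 1L, 1L) - 1L,
                    sample.int(patchSize - s + 1L, 1L) - 1L),
         lambda = lambdas[sample.int(length(lambdas), 1L)])
  })
}

#' Learn a convolution kernel by regularized weighted least squares
#'
#' Finds the s x s kernel K minimizing
#' \deqn{\sum_i w_i (K * x_i - r_i)^2 +
#'       \lambda \sum_{m,n \ \mathrm{neighbours}} (K^{(m)} - K^{(n)})^2}
#' where \code{K * x} is the response of the kernel on its fixed window
#' inside patch x and the second term is a 4-neighbour smoothness penalty
#' (a graph-Laplacian quadratic form). The minimizer solves the normal
#' equations \code{(X'WX + lambda L) k = X'W r}; a singular system gets a
#' small ridge jitter (1e-8 on the diagonal) and a message.
#'
#' @param patches n x patchSize^2 patch matrix (rows = samples).
#' @param weights positive sample weights.
#' @param residuals regression targets.
#' @param size kernel side length s (4--19).
#' @param anchor 0-based (row, col) offset of the window inside the patch.
#' @param lambda smoothness factor, one of 100 / 500 / 1000 in training.
#' @param patchSize patch side length, default 41.
#' @return list with the kernel \code{weights} (s x s matrix), \code{s},
#'   \code{anchor}, \code{lambda}.
#' @export
learnKernel <- function(patches, weights, residuals, size, anchor, lambda,
                        patchSize = 41L) {
  X <- patches[, patchCols(size, anchor[1L], anchor[2L], patchSize),
               drop = FALSE]
  sw <- sqrt(weights)
  Xs <- X * sw
  A <- crossprod(Xs) + lambda * gridLaplacian(size)
  b <- crossprod(X, weights * residuals)
  k <- tryCatch(solve(A, b), error = function(e) {
    message("singular kernel system; adding 1e-8 ridge jitter")
    solve(A + diag(1e-8, nrow(A)), b)
  })
  list(weights = matrix(k, size, size), s = as.integer(size),
       anchor = as.integer(anchor), lambda = lambda)
}

# Exhaustive threshold search on sorted responses. Returns NULL when no
# split point separates two distinct response values, else tau / leaf values
# (weighted residual means per side) / weighted SSE cost.
.bestThreshold <- function(resp, w, r) {
  ord <- order(resp)
  rs <- resp[ord]; ws <- w[ord]; rr <- r[ord]
  n <- length(rs)
  if (n < 2L) return(NULL)
  cw <- cumsum(ws); cwr <- cumsum(ws * rr); cwr2 <- cumsum(ws * rr * rr)
  W <- cw[n]; WR <- cwr[n]; WR2 <- cwr2[n]
  k <- which(rs[-n] < rs[-1L])            # split between distinct values
  if (!length(k)) return(NULL)
  sseL <- cwr2[k] - cwr[k]^2 / cw[k]
  wR <- W - cw[k]
  sseR <- (WR2 - cwr2[k]) - (WR - cwr[k])^2 / wR
  cost <- sseL + sseR
  b <- k[which.min(cost)]
  list(tau = (rs[b] + rs[b + 1L]) / 2,
       etaL = cwr[b] / cw[b],
       etaR = (WR - cwr[b]) / (W - cw[b]),
       cost = min(cost))
}

#' Choose the best (kernel, threshold) split for a node
#'
#' Every candidate kernel's responses on the node samples are scanned over
#' all sorted-midpoint thresholds; leaf values are the weighted means of the
#' residuals on each side and the split cost is the total weighted SSE. The
#' candidate with the smallest cost wins; ties break toward the lowest
#' candidate index. Returns \code{NULL} when no candidate produces two
#' distinct response values (the node then becomes a leaf).
#'
#' @param patches node sample patch matrix (n x patchSize^2).
#' @param weights,residuals boosting weights and pseudo-residuals of the
#'   node samples.
#' @param kernels list of fitted kernels (as from \code{\link{learnKernel}}).
#' @param patchSize patch side length.
#' @return list: \code{kernelIndex}, \code{kernel}, \code{tau}, \code{etaL},
#'   \code{etaR}, \code{cost}; or \code{NULL}.
#' @export
findBestSplit <- function(patches, weights, residuals, kernels,
                          patchSize = 41L) {
  best <- NULL
  for (p in seq_along(kernels)) {
    kn <- kernels[[p]]
    X <- patches[, patchCols(kn$s, kn$anchor[1L], kn$anchor[2L], patchSize),
                 drop = FALSE]
    resp <- drop(X %*% as.vector(kn$weights))
    th <- .bestThreshold(resp, weights, residuals)
    if (is.null(th)) next
    if (is.null(best) || th$cost < best$cost - 1e-12) {
      best <- c(th, list(kernelIndex = p, kernel = kn))
    }
  }
  best
}

#' Training control parameters for the boosted classifier
#'
#' @param nCandidates candidate kernels generated at every tree node
#'   (default 100).
#' @param depth maximum tree depth (default 5, i.e. at most 32 leaves).
#' @param minNode minimum number of split-search samples a node needs to be
#'   split further (default 20).
#' @param kernelFitMax cap on the number of kernel-learning samples used per
#'   node; nodes holding more are subsampled for the kernel fit (the split
#'   search still scores every node sample).
#' @param t1Size number of samples reserved for kernel learning (T1); the
#'   default keeps the 1:5 ratio of 10000 kernel-learning samples in a
#'   60000-patch training set.
#' @param sizeRange kernel side-length range, default 4--19.
#' @param lambdas smoothness factors candidates draw from.
#' @return list of class \code{"kbControl"}.
#' @export
kbControl <- function(nCandidates = 100L, depth = 5L, minNode = 20L,
                      kernelFitMax = 1000L, t1Size = NULL,
                      sizeRange = c(4L, 19L),
                      lambdas = c(100, 500, 1000)) {
  structure(list(nCandidates = as.integer(nCandidates),
                 depth = as.integer(depth), minNode = as.integer(minNode),
                 kernelFitMax = as.integer(kernelFitMax), t1Size = t1Size,
                 sizeRange = as.integer(sizeRange), lambdas = lambdas),
            class = "kbControl")
}

#' Grow one kernel-split decision tree
#'
#' Recursive split search to the configured depth. At each node a fresh set
#' of candidate kernels (random sizes, anchors and smoothness factors) is fit
#' on the kernel-learning samples (T1) reaching the node, the split is chosen
#' on the split-search samples (T2) reaching the node, and both subsets are
#' routed down by the chosen rule \code{K * x < tau}. A node with too few T2
#' samples, no T1 samples, no valid threshold, or an empty child becomes a
#' leaf holding the weighted mean residual of its T2 samples.
#'
#' @param P full patch matrix.
#' @param w,r boosting weights and pseudo-residuals (length nrow(P)).
#' @param idxT1,idxT2 row indices of the kernel-learning and split-search
#'   subsets.
#' @param control a \code{\link{kbControl}} list.
#' @param patchSize patch side length.
#' @return nested tree: internal nodes carry \code{kernel}, \code{tau},
#'   \code{cost}, \code{left}, \code{right}; leaves carry \code{value}.
#' @export
growTree <- function(P, w, r, idxT1, idxT2, control = kbControl(),
                     patchSize = 41L) {
  leafOf <- function(idx2) {
    v <- if (length(idx2)) weighted.mean(r[idx2], w[idx2]) else 0
    list(leaf = TRUE, value = v)
  }
  grow <- function(idx1, idx2, depth) {
    if (depth >= control$depth || length(idx2) < control$minNode ||
        length(idx1) == 0L)
      return(leafOf(idx2))
    fitIdx <- if (length(idx1) > control$kernelFitMax)
      idx1[sample.int(length(idx1), control$kernelFitMax)] else idx1
    cand <- genCandidates(control$nCandidates, patchSize,
                          control$sizeRange, control$lambdas)
    Pfit <- P[fitIdx, , drop = FALSE]
    wf <- w[fitIdx]; rf <- r[fitIdx]
    fitted <- lapply(cand, function(cn)
      learnKernel(Pfit, wf, rf, cn$s, cn$anchor, cn$lambda, patchSize))
    best <- findBestSplit(P[idx2, , drop = FALSE], w[idx2], r[idx2],
                          fitted, patchSize)
    if (is.null(best)) return(leafOf(idx2))
    kn <- best$kernel
    cols <- patchCols(kn$s, kn$anchor[1L], kn$anchor[2L], patchSize)
    kv <- as.vector(kn$weights)
    resp2 <- drop(P[idx2, cols, drop = FALSE] %*% kv)
    goL2 <- resp2 < best$tau
    if (!any(goL2) || all(goL2)) return(leafOf(idx2))
    resp1 <- drop(P[idx1, cols, drop = FALSE] %*% kv)
    goL1 <- resp1 < best$tau
    list(leaf = FALSE, kernel = kn, tau = best$tau, cost = best$cost,
         left = grow(idx1[goL1], idx2[goL2], depth + 1L),
         right = grow(idx1[!goL1], idx2[!goL2], depth + 1L))
  }
  grow(idxT1, idxT2, 0L)
}

# Evaluate one tree on a patch matrix; returns a numeric vector of leaf
# values. Vectorized by routing index subsets down the tree.
treeApply <- function(tree, P, patchSize = 41L) {
  out <- numeric(nrow(P))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    kn <- node$kernel
    cols <- patchCols(kn$s, kn$anchor[1L], kn$anchor[2L], patchSize)
    resp <- drop(P[idx, cols, drop = FALSE] %*% as.vector(kn$weights))
    goL <- resp < node$tau
    rec(node$left, idx[goL])
    rec(node$right, idx[!goL])
  }
  rec(tree, seq_len(nrow(P)))
  out
}

# Depth of a tree (number of splits on the longest path).
treeDepth <- function(tree) {
  if (tree$leaf) return(0L)
  1L + max(treeDepth(tree$left), treeDepth(tree$right))
}

#' Fit the boosted kernel classifier
#'
#' Gradient boosting with quadratic (Newton) approximation under the
#' exponential loss \code{exp(-y * phi)}. The model starts at \code{phi = 0};
#' each round computes the Newton weights \code{w = exp(-y * phi)} and
#' pseudo-residuals \code{r = y}, fits one kernel-split tree
#' (\code{\link{growTree}}) on the T1/T2 split of the training set, and
#' updates \code{phi <- phi + gamma * h}. Scores are clipped to +/-30 before
#' exponentiation to keep the weights finite.
#'
#' @param train a \code{\link{TrainingPatchSet-class}}.
#' @param M boosting rounds (default 100).
#' @param gamma shrinkage factor (default 0.1).
#' @param control a \code{\link{kbControl}} list.
#' @return a \code{\link{KernelBoostClassifier-class}}; the training log
#'   holds the mean loss after every round.
#' @export
fitClassifier <- function(train, M = 100L, gamma = 0.1,
                          control = kbControl()) {
  P <- train@patches
  y <- train@labels
  n <- nrow(P)
  t1n <- control$t1Size
  if (is.null(t1n)) t1n <- max(1L, round(n / 6))
  t1n <- min(t1n, n - 1L)
  perm <- sample.int(n)
  idxT1 <- perm[seq_len(t1n)]
  idxT2 <- perm[(t1n + 1L):n]

  phi <- numeric(n)
  learners <- vector("list", M)
  lossLog <- numeric(M)
  for (j in seq_len(M)) {
    m <- pmin(pmax(y * phi, -30), 30)
    w <- exp(-m)
    r <- y
    tree <- growTree(P, w, r, idxT1, idxT2, control, train@patchSize)
    learners[[j]] <- tree
    phi <- phi + gamma * treeApply(tree, P, train@patchSize)
    lossLog[j] <- mean(exp(-pmin(pmax(y * phi, -30), 30)))
  }
  new("KernelBoostClassifier", learners = learners, gamma = gamma,
      nRounds = as.integer(M),
      trainingLog = data.frame(round = seq_len(M), loss = lossLog),
      patchSize = train@patchSize,
      config = list(control = unclass(control), nTrain = n, t1Size = t1n))
}

#' Classifier scores for a patch matrix
#'
#' The raw boosted score \code{gamma * sum_j h_j(x)} for each row of
#' \code{patches}.
#'
#' @param clf a \code{KernelBoostClassifier}.
#' @param patches n x patchSize^2 matrix.
#' @return numeric vector of scores.
#' @export
predictPatchScores <- function(clf, patches) {
  s <- numeric(nrow(patches))
  for (tree in clf@learners)
    s <- s + treeApply(tree, patches, clf@patchSize)
  clf@gamma * s
}

# Flatten the forest into parallel arrays for the compiled scorer.
.flattenForest <- function(learners) {
  isLeaf <- integer(0); value <- numeric(0); tau <- numeric(0)
  left <- integer(0); right <- integer(0)
  kSize <- integer(0); anchorR <- integer(0); anchorC <- integer(0)
  kOffset <- integer(0); kWeights <- numeric(0)
  treeRoot <- integer(length(learners))
  add <- function(node) {
    id <- length(isLeaf)                 # 0-based id this node will get
    if (node$leaf) {
      isLeaf <<- c(isLeaf, 1L); value <<- c(value, node$value)
      tau <<- c(tau, 0); left <<- c(left, -1L); right <<- c(right, -1L)
      kSize <<- c(kSize, 0L); anchorR <<- c(anchorR, 0L)
      anchorC <<- c(anchorC, 0L); kOffset <<- c(kOffset, 0L)
    } else {
      isLeaf <<- c(isLeaf, 0L); value <<- c(value, 0)
      tau <<- c(tau, node$tau); left <<- c(left, NA_integer_)
      right <<- c(right, NA_integer_)
      kSize <<- c(kSize, node$kernel$s)
      anchorR <<- c(anchorR, node$kernel$anchor[1L])
      anchorC <<- c(anchorC, node$kernel$anchor[2L])
      kOffset <<- c(kOffset, length(kWeights))
      kWeights <<- c(kWeights, as.vector(node$kernel$weights))
      l <- add(node$left); r <- add(node$right)
      left[id + 1L] <<- l; right[id + 1L] <<- r
    }
    id
  }
  for (t in seq_along(learners)) treeRoot[t] <- add(learners[[t]])
  list(treeRoot = treeRoot, isLeaf = isLeaf, value = value, tau = tau,
       left = left, right = right, kSize = kSize, anchorR = anchorR,
       anchorC = anchorC, kOffset = kOffset, kWeights = kWeights)
}

#' Leg-confidence map of one frame
#'
#' Scores the 41 x 41 patch around every silhouette-foreground pixel with the
#' boosted forest and maps the score to a confidence in [0, 1] with the
#' logistic transform \code{1 / (1 + exp(-2 * score))}. Background pixels
#' are 0.
#'
#' @param clf a trained \code{KernelBoostClassifier}.
#' @param frame grayscale matrix (0--255).
#' @param mask logical silhouette mask.
#' @param thinLimit optional speed restriction: score only foreground pixels
#'   within this distance (px) of the background, leaving the deep body core
#'   at confidence 0. Legs are at most a few px wide, so any distance beyond
#'   the leg width cannot lose a leg pixel; \code{NULL} (default) scores the
#'   whole foreground.
#' @param flat internal: a pre-flattened forest (avoids re-flattening when
#'   scoring many frames).
#' @return numeric matrix of confidences, same shape as \code{frame}.
#' @export
predictConfidence <- function(clf, frame, mask, thinLimit = NULL,
                              flat = NULL) {
  conf <- matrix(0, nrow(frame), ncol(frame))
  scoreMask <- if (is.null(thinLimit)) mask
               else mask & (distanceToBackground(mask) <= thinLimit)
  xy <- maskCoords(scoreMask)
  if (!nrow(xy)) return(conf)
  half <- (clf@patchSize - 1L) %/% 2L
  d <- dim(frame)
  padded <- matrix(0, d[1L] + 2L * half, d[2L] + 2L * half)
  padded[(half + 1L):(half + d[1L]), (half + 1L):(half + d[2L])] <- frame / 255
  if (is.null(flat)) flat <- .flattenForest(clf@learners)
  score <- clf@gamma * cpp_forest_score(
    padded, as.integer(xy[, 2L] + half), as.integer(xy[, 1L] + half), half,
    flat$treeRoot, flat$isLeaf, flat$value, flat$tau, flat$left, flat$right,
    flat$kSize, flat$anchorR, flat$anchorC, flat$kOffset, flat$kWeights)
  conf[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L)] <- 1 / (1 + exp(-2 * score))
  conf
}

#' Self-training: iterative training-set augmentation
#'
#' Round 1 trains on the morphological harvest alone. Every later round
#' applies the current classifier to the sampled training frames, adds
#' foreground pixels predicted with confidence at or above \code{confHi} to
#' the positive pool and at or below \code{confLo} to the negative pool,
#' resamples patches and retrains. Stops early when the pools grow by less
#' than \code{minGrowth}.
#'
#' @param stack a \code{FrameStack}.
#' @param rounds self-training rounds (default 2).
#' @param background optional \code{BackgroundImage}; estimated automatically
#'   when NULL.
#' @param nPos,nNeg patch sample sizes per class.
#' @param M,gamma,control boosting parameters, see
#'   \code{\link{fitClassifier}}.
#' @param legWidth,frameStride harvest parameters, see
#'   \code{\link{harvestConfidentPixels}} and
#'   \code{\link{sampleTrainingFrames}}.
#' @param confHi,confLo confidence gates for pool augmentation.
#' @param minGrowth relative pool growth below which augmentation stops.
#' @return list with \code{classifier} (the final
#'   \code{KernelBoostClassifier}) and \code{poolSizes} (per-round pool
#'   sizes).
#' @export
selfTrain <- function(stack, rounds = 2L, background = NULL,
                      nPos = 30000L, nNeg = 30000L,
                      M = 100L, gamma = 0.1, control = kbControl(),
                      legWidth = 5, frameStride = 20L,
                      confHi = 0.9, confLo = 0.1, minGrowth = 0.01) {
  stopifnot(rounds >= 1L)
  if (is.null(background)) background <- estimateBackground(stack)
  tf <- sampleTrainingFrames(stack, frameStride)
  masks <- lapply(tf, function(i)
    extractSilhouette(stack@frames[[i]], background))
  pool <- mergePixelPools(Map(function(m, i)
    harvestConfidentPixels(m, i, legWidth = legWidth), masks, tf))

  poolSizes <- data.frame(round = integer(0), positives = integer(0),
                          negatives = integer(0))
  clf <- NULL
  for (rd in seq_len(rounds)) {
    if (rd > 1L) {
      before <- nrow(pool$positives) + nrow(pool$negCore) + nrow(pool$negBand)
      addPos <- list(); addNeg <- list()
      flat <- .flattenForest(clf@learners)
      for (k in seq_along(tf)) {
        i <- tf[k]
        conf <- predictConfidence(clf, stack@frames[[i]], masks[[k]],
                                  flat = flat)
        xy <- maskCoords(masks[[k]])
        cv <- conf[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L)]
        # augmentation respects morphology as well as confidence: new
        # positives must lie on thin structures (a confident prediction on
        # a thick body extremity would poison the positive pool), and new
        # negatives must lie on thick ones (a faint, half-missed leg tip
        # must not be taught as non-leg)
        dst <- distanceToBackground(masks[[k]])
        thin <- dst[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L)] <= legWidth / 2
        hi <- cv >= confHi & thin
        lo <- cv <= confLo & !thin
        if (any(hi)) addPos[[length(addPos) + 1L]] <-
          data.frame(frame = i, x = xy[hi, 1L], y = xy[hi, 2L])
        if (any(lo)) addNeg[[length(addNeg) + 1L]] <-
          data.frame(frame = i, x = xy[lo, 1L], y = xy[lo, 2L])
      }
      pool$positives <- unique(rbind(pool$positives, do.call(rbind, addPos)))
      pool$negCore <- unique(rbind(pool$negCore, do.call(rbind, addNeg)))
      after <- nrow(pool$positives) + nrow(pool$negCore) + nrow(pool$negBand)
      if ((after - before) / before < minGrowth) {
        message("pool growth below ", minGrowth * 100,
                "% in round ", rd, "; stopping self-training early")
        break
      }
    }
    train <- extractPatches(pool, stack, nPos, nNeg, roundIndex = rd)
    clf <- fitClassifier(train, M = M, gamma = gamma, control = control)
    poolSizes <- rbind(poolSizes, data.frame(
      round = rd, positives = nrow(pool$positives),
      negatives = nrow(pool$negCore) + nrow(pool$negBand)))
  }
  list(classifier = clf, poolSizes = poolSizes)
}
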