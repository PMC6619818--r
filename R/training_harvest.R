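# Self-supervised training-set harvest: high-confidence leg pixels from the
# intersection of silhouette skeleton and edge morphology, non-leg pixels
# from the deep body core and the background band around the animal.

#' Pick the training frames of a stack
#'
#' One frame in every \code{stride} (default 20) is used for training-set
#' generation; stacks shorter than the stride contribute every frame.
#'
#' @param stack a \code{FrameStack} (or an integer frame count).
#' @param stride sampling stride.
#' @return integer vector of 1-based frame indices (frame 1, 21, 41, ...).
#' @export
sampleTrainingFrames <- function(stack, stride = 20L) {
  n <- if (is(stack, "FrameStack")) nFrames(stack) else as.integer(stack)
  if (n < stride) return(seq_len(n))
  seq(1L, n, by = as.integer(stride))
}

#' Harvest high-confidence leg / non-leg pixels from one silhouette
#'
#' Positive (leg) pixels are the intersection of the silhouette's skeleton
#' with its dilated edge set: on thin structures such as legs the medial axis
#' runs within a pixel of the boundary, while on the body the skeleton stays
#' far from the edge, so the intersection selects leg midlines with high
#' precision (and deliberately low recall). Skeleton-near-edge pixels deeper
#' than half a leg width (narrow body extremities such as the head or a wing
#' tip) are rejected. Negative pixels come from two sources: the non-leg
#' body (all foreground outside a grey exclusion zone of \code{legWidth} px
#' around the harvested leg pixels) and a band of background just outside
#' the silhouette. The grey zone is left out of learning as low-confidence.
#'
#' @param mask logical silhouette mask.
#' @param frameIndex 1-based index of the frame the mask belongs to.
#' @param legWidth upper bound on leg width in px (default 5); the body core
#'   is the foreground deeper than this distance from the boundary.
#' @param edgeDilate dilation radius applied to the edge set before the
#'   intersection (default 1, tolerating 1-px offsets between skeleton and
#'   edge rasters).
#' @param bandWidth width of the background sampling band around the
#'   silhouette, px.
#' @return list with data.frames \code{positives}, \code{negCore},
#'   \code{negBand}, each holding 0-based \code{x}, \code{y} and
#'   \code{frame}; class \code{"LabeledPixelPool"}.
#' @export
harvestConfidentPixels <- function(mask, frameIndex = 1L, legWidth = 5,
                                   edgeDilate = 1L, bandWidth = 10L) {
  if (!any(mask)) stop("empty silhouette mask")
  skel <- skeletonizeMask(mask)
  edges <- maskEdges(mask)
  dist <- distanceToBackground(mask)
  # skeleton-near-edge pixels, restricted to thin structures: skeleton
  # points at narrow body extremities (head, wing tip) also graze the edge
  # but sit deeper than half a leg width
  nearEdge <- skel & dilateMask(edges, edgeDilate)
  pos <- nearEdge & (dist <= legWidth / 2)
  if (!any(pos))
    message("no skeleton/edge overlap in frame ", frameIndex)
  # the non-leg foreground (body, including its boundary and narrow
  # extremities such as the head) is negative except for a grey exclusion
  # zone around the harvested leg pixels, where labels are uncertain
  grey <- dilateMask(pos, legWidth)
  core <- mask & !grey
  band <- dilateMask(mask, bandWidth) & !mask

  asDF <- function(m) {
    xy <- maskCoords(m)
    data.frame(frame = rep(frameIndex, nrow(xy)), x = xy[, 1L], y = xy[, 2L])
  }
  structure(list(positives = asDF(pos), negCore = asDF(core),
                 negBand = asDF(band)),
            class = "LabeledPixelPool")
}

# Merge pool contributions from several frames.
mergePixelPools <- function(pools) {
  structure(list(
    positives = do.call(rbind, lapply(pools, `[[`, "positives")),
    negCore   = do.call(rbind, lapply(pools, `[[`, "negCore")),
    negBand   = do.call(rbind, lapply(pools, `[[`, "negBand"))),
    class = "LabeledPixelPool")
}

#' @export
print.LabeledPixelPool <- function(x, ...) {
  cat(sprintf("LabeledPixelPool: %d positives, %d core negatives, %d band negatives\n",
              nrow(x$positives), nrow(x$negCore), nrow(x$negBand)))
  invisible(x)
}

# Sample n rows from a coordinate pool, without replacement when possible.
.samplePool <- function(df, n) {
  if (nrow(df) == 0L) stop("cannot sample from an empty pixel pool")
  df[sample.int(nrow(df), n, replace = nrow(df) < n), , drop = FALSE]
}

# Gather flattened patchSize x patchSize patches (column-major) centred on
# 0-based (x, y) pixels of one frame, zero-padded at the borders.
.gatherPatches <- function(frame, xy, patchSize) {
  half <- (patchSize - 1L) %/% 2L
  d <- dim(frame)
  padded <- matrix(0, d[1L] + 2L * half, d[2L] + 2L * half)
  padded[(half + 1L):(half + d[1L]), (half + 1L):(half + d[2L])] <- frame / 255
  nrP <- nrow(padded)
  # centre linear index in the padded matrix (1-based)
  base <- (xy[, 1L] + half) * nrP + (xy[, 2L] + half + 1L)
  offs <- as.vector(outer((-half):half, (-half):half * nrP, `+`))
  idx <- outer(base, offs, `+`)
  matrix(padded[idx], nrow = nrow(xy))
}

#' Extract a labeled training patch set from a pixel pool
#'
#' Samples \code{nPos} positive and \code{nNeg} negative pixels (negatives
#' split evenly between body core and background band, falling back to the
#' non-empty source if one is missing) and cuts the surrounding
#' \code{patchSize} x \code{patchSize} grayscale patches out of the raw
#' frames, zero-padded at image borders. Sampling is uniform without
#' replacement, switching to with-replacement when a pool is smaller than the
#' request. Labels are +1 (leg) / -1; initial weights are 1 and initial
#' residuals equal the labels.
#'
#' @param pool a \code{LabeledPixelPool}.
#' @param stack the \code{FrameStack} the pool was harvested from.
#' @param nPos,nNeg class sample sizes (defaults 30000 each).
#' @param patchSize patch side length, default 41.
#' @param roundIndex self-training round tag.
#' @return a \code{\link{TrainingPatchSet-class}}.
#' @export
extractPatches <- function(pool, stack, nPos = 30000L, nNeg = 30000L,
                           patchSize = 41L, roundIndex = 1L) {
  if (nrow(pool$positives) == 0L)
    stop("harvest error: positive pixel pool is empty")
  nCoreAvail <- nrow(pool$negCore); nBandAvail <- nrow(pool$negBand)
  if (nCoreAvail + nBandAvail == 0L)
    stop("harvest error: negative pixel pool is empty")

  posSel <- .samplePool(pool$positives, nPos)
  nCore <- if (nBandAvail == 0L) nNeg else if (nCoreAvail == 0L) 0L
           else nNeg %/% 2L
  nBand <- nNeg - nCore
  negSel <- rbind(
    if (nCore > 0L) .samplePool(pool$negCore, nCore),
    if (nBand > 0L) .samplePool(pool$negBand, nBand))

  sel <- rbind(cbind(posSel, label = 1), cbind(negSel, label = -1))
  patches <- matrix(0, nrow(sel), patchSize^2)
  for (f in unique(sel$frame)) {
    rows <- which(sel$frame == f)
    patches[rows, ] <- .gatherPatches(stack@frames[[f]],
                                      as.matrix(sel[rows, c("x", "y")]),
                                      patchSize)
  }
  new("TrainingPatchSet", patches = patches, labels = sel$label,
      weights = rep(1, nrow(sel)), residuals = sel$label,
      patchSize = as.integer(patchSize), roundIndex = as.integer(roundIndex))
}
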