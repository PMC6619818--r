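# Body-centred claw detection and identity tracking: body pose from
# silhouette moments, skeleton-endpoint claw candidates, geometric identity
# initialization, and frame-to-frame gated Hungarian assignment with
# missing-tip recovery.

.deg2rad <- function(d) d * pi / 180
.foldAxis <- function(deg) {           # fold an axis angle into (-90, 90]
  d <- ((deg + 90) %% 180) - 90
  ifelse(d == -90, 90, d)
}

#' Body pose from a silhouette
#'
#' The centroid is the foreground mean; the axis angle is the orientation of
#' the principal axis of the second central moments, reported in degrees
#' from the arena y-axis, in (-90, 90]. Which end of the axis is anterior is
#' decided later from temporal continuity and motion direction (see
#' \code{\link{trackClaws}}); \code{flip = TRUE} means the anterior points
#' along the negative axis direction. An isotropic (degenerate) silhouette
#' keeps the previous frame's angle.
#'
#' @param mask logical silhouette mask.
#' @param prev optional previous \code{BodyPose} for the degenerate case.
#' @return list of class \code{"BodyPose"}: \code{cx}, \code{cy} (0-based
#'   arena px), \code{theta} (deg), \code{flip}, \code{extentPx} (silhouette
#'   extent along the axis), \code{widthPos}/\code{widthNeg} (mean
#'   perpendicular spread of the two axis halves), \code{degenerate}.
#' @export
bodyPose <- function(mask, prev = NULL) {
  xy <- maskCoords(mask)
  if (!nrow(xy)) stop("empty mask has no pose")
  cx <- mean(xy[, 1L]); cy <- mean(xy[, 2L])
  dx <- xy[, 1L] - cx; dy <- xy[, 2L] - cy
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  degenerate <- abs(mxx - myy) < 1e-9 && abs(mxy) < 1e-9
  if (degenerate) {
    theta <- if (!is.null(prev)) prev$theta else 0
  } else {
    alpha <- 0.5 * atan2(2 * mxy, mxx - myy)   # major axis vs x-axis
    theta <- .foldAxis(90 - alpha * 180 / pi)
  }
  th <- .deg2rad(theta)
  d <- c(sin(th), cos(th))                     # axis direction, +y reference
  t <- dx * d[1L] + dy * d[2L]                 # axial coordinate
  perp <- abs(dx * d[2L] - dy * d[1L])
  structure(list(cx = cx, cy = cy, theta = theta, flip = FALSE,
                 extentPx = diff(range(t)),
                 widthPos = if (any(t > 0)) mean(perp[t > 0]) else 0,
                 widthNeg = if (any(t < 0)) mean(perp[t < 0]) else 0,
                 degenerate = degenerate),
            class = "BodyPose")
}

# Heading angle in degrees (anterior direction measured from +y toward +x).
.headingDeg <- function(pose) pose$theta + if (isTRUE(pose$flip)) 180 else 0

#' Transform arena points into the body-centred frame
#'
#' Translates the centroid to the origin and rotates so the anterior points
#' along +y: \code{p' = R(h) (p - c)} with \code{h} the heading angle.
#' \code{fromBodyFrame} is the exact inverse.
#'
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) arena positions.
#' @param pose a \code{BodyPose} (its \code{flip} must be final).
#' @return n x 2 matrix of body-frame positions.
#' @export
toBodyFrame <- function(pts, pose) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1L)
  h <- .deg2rad(.headingDeg(pose))
  dx <- pts[, 1L] - pose$cx; dy <- pts[, 2L] - pose$cy
  cbind(x = dx * cos(h) - dy * sin(h),
        y = dx * sin(h) + dy * cos(h))
}

#' @rdname toBodyFrame
#' @export
fromBodyFrame <- function(pts, pose) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1L)
  h <- .deg2rad(.headingDeg(pose))
  cbind(x = pose$cx + pts[, 1L] * cos(h) + pts[, 2L] * sin(h),
        y = pose$cy - pts[, 1L] * sin(h) + pts[, 2L] * cos(h))
}

#' Claw candidates of a segmented frame
#'
#' Each leg component is skeletonized to single-pixel width; its endpoints
#' (skeleton pixels with at most one skeleton neighbour) are listed and the
#' endpoint at maximum Euclidean distance from the body centroid is kept as
#' the claw candidate. Closed-loop components without endpoints are skipped.
#' The tip position is then refined to the most distal pixels around the
#' endpoint; when the confidence map is supplied, sub-threshold pixels down
#' to \code{tipThr} take part in the refinement, recovering the faint
#' anti-aliased tail of the tip that the global segmentation threshold
#' clips off.
#'
#' @param seg a \code{LegSegmentation}.
#' @param pose the frame's \code{BodyPose}.
#' @param conf optional confidence map (same shape as \code{seg$labels}).
#' @param tipThr local confidence cut used for tip refinement.
#' @return data.frame of class \code{"TipSet"}: arena and body-frame
#'   coordinates (\code{x}, \code{y}, \code{xb}, \code{yb}), component id
#'   and centroid distance, one row per tip.
#' @export
findClawCandidates <- function(seg, pose, conf = NULL, tipThr = 0.3) {
  lab <- seg$labels
  tips <- NULL
  for (k in seq_along(seg$sizes)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (!nrow(idx)) next
    r0 <- max(1L, min(idx[, 1L]) - 1L); r1 <- min(nrow(lab), max(idx[, 1L]) + 1L)
    c0 <- max(1L, min(idx[, 2L]) - 1L); c1 <- min(ncol(lab), max(idx[, 2L]) + 1L)
    comp <- lab[r0:r1, c0:c1, drop = FALSE] == k
    skel <- skeletonizeMask(comp)
    nb <- neighbourCount8(skel)
    endp <- maskCoords(skel & nb <= 1L)
    if (!nrow(endp)) next                       # ring artifact, no endpoint
    endp[, 1L] <- endp[, 1L] + (c0 - 1L)        # back to full-image coords
    endp[, 2L] <- endp[, 2L] + (r0 - 1L)
    d2 <- (endp[, 1L] - pose$cx)^2 + (endp[, 2L] - pose$cy)^2
    w <- which.max(d2)
    # thinning retracts the skeleton a pixel or two from the physical tip;
    # refine to the most distal pixels around the endpoint (sub-threshold
    # confidence included when available)
    tipZone <- if (is.null(conf)) comp else {
      comp | (conf[r0:r1, c0:c1, drop = FALSE] >= tipThr)
    }
    cxy <- maskCoords(tipZone)
    cxy[, 1L] <- cxy[, 1L] + (c0 - 1L); cxy[, 2L] <- cxy[, 2L] + (r0 - 1L)
    near <- (cxy[, 1L] - endp[w, 1L])^2 + (cxy[, 2L] - endp[w, 2L])^2 <= 16
    cand <- cxy[near, , drop = FALSE]
    dc <- sqrt((cand[, 1L] - pose$cx)^2 + (cand[, 2L] - pose$cy)^2)
    # report the mean of the most distal pixels: on a ~3-px rounded tip
    # this approximates the blob centre an annotator would pick
    distal <- dc >= max(dc) - 1
    tip <- colMeans(cand[distal, , drop = FALSE])
    tips <- rbind(tips, c(tip[1L], tip[2L], k, max(dc)))
  }
  if (is.null(tips))
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                xb = numeric(0), yb = numeric(0),
                                component = integer(0), dist = numeric(0)),
                     class = c("TipSet", "data.frame")))
  bf <- toBodyFrame(tips[, 1:2, drop = FALSE], pose)
  structure(data.frame(x = tips[, 1L], y = tips[, 2L],
                       xb = bf[, 1L], yb = bf[, 2L],
                       component = as.integer(tips[, 3L]),
                       dist = tips[, 4L]),
            class = c("TipSet", "data.frame"))
}

# Geometric labels for a clean stance: split by body-frame x sign into
# left (x < 0) / right, rank each side by descending y (anterior first).
# Returns tip-row indices named by leg label, or NULL if sides unbalanced.
.labelByGeometry <- function(tips, nLegs) {
  half <- nLegs %/% 2L
  li <- which(tips$xb < 0); ri <- which(tips$xb >= 0)
  if (length(li) != half || length(ri) != half) return(NULL)
  li <- li[order(tips$yb[li], decreasing = TRUE)]
  ri <- ri[order(tips$yb[ri], decreasing = TRUE)]
  idx <- c(li, ri)
  names(idx) <- c(paste0("L", seq_len(half)), paste0("R", seq_len(half)))
  idx
}

#' Initialize track identities
#'
#' Finds the first frame with exactly \code{nLegs} claw candidates arranged
#' in a clean stance (equal numbers left and right of the body axis) and
#' labels them by geometric position: side by the sign of the body-frame x
#' coordinate, rank 1 (front) to rear by descending body-frame y. For
#' animals whose stance cannot be labeled geometrically (e.g. arachnids) a
#' user-supplied labeling of a chosen frame can be passed to
#' \code{\link{trackClaws}} instead.
#'
#' @param tipsets list of per-frame \code{TipSet}s.
#' @param nLegs number of legs (6, or 8 in arachnid mode).
#' @return list: \code{frame} (1-based index), \code{labels} (tip-row
#'   indices named by leg).
#' @export
initializeTracks <- function(tipsets, nLegs = 6L) {
  bestFrame <- NA_integer_; bestDiff <- Inf
  for (f in seq_along(tipsets)) {
    tips <- tipsets[[f]]
    dd <- abs(nrow(tips) - nLegs)
    if (dd < bestDiff) { bestDiff <- dd; bestFrame <- f }
    if (nrow(tips) != nLegs) next
    lab <- .labelByGeometry(tips, nLegs)
    if (!is.null(lab)) return(list(frame = f, labels = lab))
  }
  stop("initialization error: no frame with a clean ", nLegs,
       "-tip stance; closest was frame ", bestFrame, " with ",
       nrow(tipsets[[bestFrame]]), " tips")
}

#' Assign new tips to tracked legs (one frame step)
#'
#' Stage 1 matches legs seen in the previous frame to the new tips by
#' minimum-total-squared-distance injective assignment in the body frame
#' (Hungarian method), with pairs farther apart than the gate forbidden.
#' Stage 2 matches legs that are currently missing against the leftover tips
#' using their last-seen positions, under the same gate. Legs that remain
#' unmatched are flagged missing for this frame; leftover tips beyond the
#' leg count are discarded.
#'
#' @param current nLegs x 2 matrix of body-frame positions at the previous
#'   frame (NA rows = currently missing).
#' @param lastSeen nLegs x 2 matrix of the most recent known body-frame
#'   position of every leg.
#' @param tips a \code{TipSet} for the new frame.
#' @param gatePx hard distance gate in px.
#' @return integer vector (length nLegs) of tip-row indices, NA = missing.
#' @export
assignTips <- function(current, lastSeen, tips, gatePx = 20) {
  nLegs <- nrow(current)
  match <- rep(NA_integer_, nLegs)
  if (nrow(tips) == 0L) return(match)
  tp <- cbind(tips$xb, tips$yb)
  g2 <- gatePx^2

  active <- which(!is.na(current[, 1L]))
  if (length(active)) {
    cost <- outer(seq_along(active), seq_len(nrow(tp)),
                  Vectorize(function(i, j)
                    sum((current[active[i], ] - tp[j, ])^2)))
    cost[cost > g2] <- Inf
    a <- solveAssignment(cost)
    match[active] <- a
  }
  lost <- which(is.na(match) & !is.na(lastSeen[, 1L]))
  leftover <- setdiff(seq_len(nrow(tp)), match[!is.na(match)])
  if (length(lost) && length(leftover)) {
    cost <- outer(seq_along(lost), seq_along(leftover),
                  Vectorize(function(i, j)
                    sum((lastSeen[lost[i], ] - tp[leftover[j], ])^2)))
    cost[cost > g2] <- Inf
    a <- solveAssignment(cost)
    match[lost] <- leftover[a]
  }
  match
}

#' Track leg claws through a frame stack
#'
#' Runs the full tracking pass: per frame it extracts the silhouette,
#' estimates the body pose (axis angle kept temporally continuous; the
#' anterior end is chosen so that the body on average moves head-first, with
#' the broader axis half used as the head end if the animal is essentially
#' stationary), computes the leg-confidence map, segments legs and finds
#' claw candidates; identities are then initialized at the first clean
#' stance frame (or from \code{firstFrameTips}) and propagated by gated
#' Hungarian assignment. The gate defaults to 20 px at 512-px image width
#' and scales with the image width.
#'
#' @param stack a \code{FrameStack}.
#' @param classifier a trained \code{KernelBoostClassifier}.
#' @param background optional \code{BackgroundImage}.
#' @param thr classification threshold (default 0.65).
#' @param nLegs number of legs (6 or 8).
#' @param minSize minimum leg-component size, px.
#' @param gatePx optional gate override, px.
#' @param firstFrameTips optional manual initialization: a data.frame with
#'   \code{leg}, \code{x}, \code{y} (arena px) for one frame, used instead
#'   of geometric labeling (arachnid mode).
#' @param silhouetteThr threshold for silhouette extraction
#'   (\code{"auto"} = Otsu).
#' @return a \code{\link{TrackSet-class}}.
#' @export
trackClaws <- function(stack, classifier, background = NULL, thr = 0.65,
                       nLegs = 6L, minSize = 4L, gatePx = NULL,
                       firstFrameTips = NULL, silhouetteThr = "auto",
                       thinLimit = 6) {
  if (is.null(background)) background <- estimateBackground(stack)
  nf <- nFrames(stack)
  d <- dim(stack@frames[[1L]])
  if (is.null(gatePx)) gatePx <- 20 * d[2L] / 512

  poses <- vector("list", nf)
  tipsRaw <- vector("list", nf)
  heading <- numeric(nf)
  prevPose <- NULL
  flat <- .flattenForest(classifier@learners)
  for (f in seq_len(nf)) {
    mask <- extractSilhouette(stack@frames[[f]], background,
                              thr = silhouetteThr)
    pose <- bodyPose(mask, prevPose)
    # temporal axis continuity: pick the representation of the (mod-180)
    # axis closest to the previous heading
    if (f == 1L) heading[f] <- pose$theta
    else {
      cands <- pose$theta + c(-180, 0, 180)
      heading[f] <- cands[which.min(abs(cands - heading[f - 1L]))]
    }
    poses[[f]] <- pose
    prevPose <- pose
    # segmentation works on the animal's bounding box (patches reach 20 px
    # beyond a pixel, so the margin keeps every patch inside the crop)
    idx <- which(mask, arr.ind = TRUE)
    mrg <- 25L
    r0 <- max(1L, min(idx[, 1L]) - mrg); r1 <- min(nrow(mask), max(idx[, 1L]) + mrg)
    c0 <- max(1L, min(idx[, 2L]) - mrg); c1 <- min(ncol(mask), max(idx[, 2L]) + mrg)
    subFrame <- stack@frames[[f]][r0:r1, c0:c1, drop = FALSE]
    subMask <- mask[r0:r1, c0:c1, drop = FALSE]
    conf <- predictConfidence(classifier, subFrame, subMask,
                              thinLimit = thinLimit, flat = flat)
    seg <- segmentLegs(conf, thr = thr, minSize = minSize)
    subPose <- pose
    subPose$cx <- pose$cx - (c0 - 1L); subPose$cy <- pose$cy - (r0 - 1L)
    tips <- findClawCandidates(seg, subPose, conf = conf)
    if (nrow(tips)) {
      tips$x <- tips$x + (c0 - 1L); tips$y <- tips$y + (r0 - 1L)
    }
    tipsRaw[[f]] <- tips
  }

  # anterior disambiguation: net head-first motion, else the broader half
  cxs <- vapply(poses, `[[`, numeric(1L), "cx")
  cys <- vapply(poses, `[[`, numeric(1L), "cy")
  vx <- diff(cxs); vy <- diff(cys)
  hmid <- .deg2rad((heading[-1L] + heading[-nf]) / 2)
  S <- sum(sin(hmid) * vx + cos(hmid) * vy)
  totalDisp <- sqrt((cxs[nf] - cxs[1L])^2 + (cys[nf] - cys[1L])^2)
  if (totalDisp < 5) {
    wPos <- mean(vapply(poses, `[[`, numeric(1L), "widthPos"))
    wNeg <- mean(vapply(poses, `[[`, numeric(1L), "widthNeg"))
    if (wNeg > wPos) heading <- heading + 180
  } else if (S < 0) heading <- heading + 180

  tipsets <- vector("list", nf)
  for (f in seq_len(nf)) {
    poses[[f]]$theta <- .foldAxis(heading[f])
    poses[[f]]$flip <- abs(((heading[f] - poses[[f]]$theta) %% 360)) > 90
    tr <- tipsRaw[[f]]
    if (nrow(tr)) {
      bf <- toBodyFrame(as.matrix(tr[, c("x", "y")]), poses[[f]])
      tr$xb <- bf[, 1L]; tr$yb <- bf[, 2L]
    }
    tipsets[[f]] <- tr
  }

  legs <- c(paste0("L", seq_len(nLegs %/% 2L)),
            paste0("R", seq_len(nLegs %/% 2L)))
  if (is.null(firstFrameTips)) {
    init <- initializeTracks(tipsets, nLegs)
  } else {
    f0 <- attr(firstFrameTips, "frame")
    if (is.null(f0)) f0 <- 1L
    idx <- vapply(seq_len(nrow(firstFrameTips)), function(i) {
      d2 <- (tipsets[[f0]]$x - firstFrameTips$x[i])^2 +
            (tipsets[[f0]]$y - firstFrameTips$y[i])^2
      which.min(d2)
    }, integer(1L))
    names(idx) <- firstFrameTips$leg
    init <- list(frame = f0, labels = idx[legs])
  }

  ts <- new("TrackSet", legs = legs,
            arena = array(NA_real_, c(nf, nLegs, 2L)),
            body = array(NA_real_, c(nf, nLegs, 2L)),
            missing = matrix(TRUE, nf, nLegs),
            poses = data.frame(
              frame = seq_len(nf) - 1L, cx = cxs, cy = cys,
              theta = vapply(poses, `[[`, numeric(1L), "theta"),
              flip = vapply(poses, `[[`, logical(1L), "flip"),
              extent_px = vapply(poses, `[[`, numeric(1L), "extentPx")),
            tipSets = tipsets, corrections = data.frame(),
            frameRate = stack@frameRate, mmPerPx = stack@mmPerPx,
            gatePx = gatePx, startFrame = as.integer(init$frame))
  ts <- .runAssignment(ts, init$frame, init$labels)
  ts
}

# Forward assignment pass from frame f0 with given tip labels at f0.
# `labels`: tip-row indices named by leg, or NA entries for missing legs.
.runAssignment <- function(ts, f0, labels, overrides = NULL) {
  nf <- dim(ts@arena)[1L]
  legs <- ts@legs
  nLegs <- length(legs)
  setFrame <- function(ts, f, tipIdx) {
    tips <- ts@tipSets[[f]]
    for (j in seq_len(nLegs)) {
      if (!is.na(tipIdx[j])) {
        ts@arena[f, j, ] <- c(tips$x[tipIdx[j]], tips$y[tipIdx[j]])
        ts@body[f, j, ] <- c(tips$xb[tipIdx[j]], tips$yb[tipIdx[j]])
        ts@missing[f, j] <- FALSE
      } else {
        ts@arena[f, j, ] <- NA_real_
        ts@body[f, j, ] <- NA_real_
        ts@missing[f, j] <- TRUE
      }
    }
    ts
  }
  tipIdx <- labels[legs]
  ts <- setFrame(ts, f0, tipIdx)
  # most recent known position up to f0 (so a leg marked absent at f0 can
  # still be recovered from where it was last seen)
  lastSeen <- matrix(NA_real_, nLegs, 2L)
  for (j in seq_len(nLegs)) {
    seenIdx <- which(!ts@missing[seq_len(f0), j])
    if (length(seenIdx))
      lastSeen[j, ] <- ts@body[max(seenIdx), j, ]
  }
  if (f0 < nf) for (f in (f0 + 1L):nf) {
    current <- ts@body[f - 1L, , , drop = TRUE]
    a <- assignTips(current, lastSeen, ts@tipSets[[f]], ts@gatePx)
    # manual override hook used when re-running after corrections
    if (!is.null(overrides) && !is.null(overrides[[as.character(f)]])) {
      ov <- overrides[[as.character(f)]]
      for (nm in names(ov)) a[match(nm, legs)] <- ov[[nm]]
    }
    ts <- setFrame(ts, f, a)
    seen <- !is.na(a)
    if (any(seen)) lastSeen[seen, ] <- ts@body[f, seen, , drop = TRUE]
  }
  ts
}

#' Apply manual corrections and re-run tracking
#'
#' Each correction names a frame and a leg and either a corrected arena
#' position or an absent-mark. The position is snapped to the nearest claw
#' candidate within the gate if one exists (else inserted verbatim), and
#' tracking is re-run forward from the earliest corrected frame so the fix
#' propagates.
#'
#' @param tracks a \code{TrackSet}.
#' @param fixes data.frame with columns \code{frame} (0-based), \code{leg},
#'   \code{x}, \code{y} (arena px; NA = mark the leg absent).
#' @return the corrected \code{TrackSet}.
#' @export
applyCorrections <- function(tracks, fixes) {
  if (is.null(fixes) || nrow(fixes) == 0L) return(tracks)
  nf <- dim(tracks@arena)[1L]
  legs <- tracks@legs
  for (i in seq_len(nrow(fixes))) {
    f <- fixes$frame[i] + 1L
    if (f < 1L || f > nf) stop("correction frame out of range: ", fixes$frame[i])
    if (!fixes$leg[i] %in% legs) stop("unknown leg in correction: ", fixes$leg[i])
    if (!is.na(fixes$x[i]) && (fixes$x[i] < 0 || fixes$y[i] < 0))
      stop("correction position out of image bounds")
  }
  f0 <- min(fixes$frame) + 1L
  overrides <- list()
  for (i in seq_len(nrow(fixes))) {
    f <- fixes$frame[i] + 1L
    leg <- fixes$leg[i]
    tips <- tracks@tipSets[[f]]
    if (is.na(fixes$x[i])) {
      tipIdx <- NA_integer_
    } else {
      if (nrow(tips)) {
        d2 <- (tips$x - fixes$x[i])^2 + (tips$y - fixes$y[i])^2
        w <- which.min(d2)
        tipIdx <- if (sqrt(d2[w]) <= tracks@gatePx) w else NA_integer_
      } else tipIdx <- NA_integer_
      if (is.na(tipIdx)) {
        # insert the user position as a synthetic tip
        pose <- list(cx = tracks@poses$cx[f], cy = tracks@poses$cy[f],
                     theta = tracks@poses$theta[f],
                     flip = tracks@poses$flip[f])
        bf <- toBodyFrame(c(fixes$x[i], fixes$y[i]), pose)
        tips <- rbind(tips, data.frame(
          x = fixes$x[i], y = fixes$y[i], xb = bf[1L], yb = bf[2L],
          component = NA_integer_,
          dist = sqrt((fixes$x[i] - pose$cx)^2 + (fixes$y[i] - pose$cy)^2)))
        tracks@tipSets[[f]] <- tips
        tipIdx <- nrow(tips)
      }
    }
    key <- as.character(f)
    if (is.null(overrides[[key]])) overrides[[key]] <- list()
    overrides[[key]][[leg]] <- tipIdx
  }
  # assemble the starting labels at f0 (current assignment + overrides)
  tips0 <- tracks@tipSets[[f0]]
  labels <- rep(NA_integer_, length(legs)); names(labels) <- legs
  for (j in seq_along(legs)) {
    if (!tracks@missing[f0, j] && nrow(tips0)) {
      d2 <- (tips0$x - tracks@arena[f0, j, 1L])^2 +
            (tips0$y - tracks@arena[f0, j, 2L])^2
      labels[j] <- which.min(d2)
    }
  }
  ov0 <- overrides[[as.character(f0)]]
  if (!is.null(ov0)) for (nm in names(ov0)) labels[nm] <- ov0[[nm]]
  out <- .runAssignment(tracks, f0, labels, overrides)
  out@corrections <- rbind(tracks@corrections, fixes)
  out
}
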