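# Deterministic synthetic walker videos with full ground truth: a dark
# hexapod silhouette (two-lobed body, six tapering legs ending in ~3-px
# tips) walking over a bright background under a scripted gait schedule.
# Every quantity the tracker estimates is known exactly, so segmentation,
# tracking and gait statistics can all be validated end to end.

#' Parameters of a synthetic walker recording
#'
#' Defaults emulate the default recording regime: 512 x 512 px frames over a
#' 10 mm field of view at 1000 fps, a body about 133 px long, leg tips about
#' 3 px wide, and enough travel (> 1.5 body lengths) for automatic
#' background estimation. The walking speed is derived from the stride
#' length and cycle duration (1.0 mm per 100 ms cycle = 10 mm/s, a typical
#' moderate walking speed giving about 2.3 body lengths of travel over 600
#' frames), which keeps every claw displacement well under the 20-px
#' tracking gate.
#'
#' @param imageSize frame side length, px.
#' @param fovMM field-of-view width, mm.
#' @param fps frames per second.
#' @param nFrames number of frames.
#' @param bodyLengthPx body length along the axis, px.
#' @param tipWidthPx leg-tip width, px.
#' @param gait \code{"tripod"}, \code{"tetrapod"} or \code{"custom"} (then
#'   supply \code{schedule}, a logical nFrames x nLegs matrix).
#' @param strideLengthMM stride length, mm.
#' @param stanceDurMs,swingDurMs stance/swing durations, ms.
#' @param headingDeg initial heading, degrees from the +y image axis.
#' @param path \code{"straight"} or \code{"zigzag"}.
#' @param bendDeg,bendEveryMs zigzag bend angle (alternating sign) and bend
#'   spacing.
#' @param tremor NULL, or \code{list(freqHz=, ampPx=, legs=)} adding a
#'   lateral oscillation (amplitude = peak-to-valley px) to the named claws.
#' @param contrast \code{"default"} (background 200 / body 50),
#'   \code{"low"} (140 / 90) or \code{"high"} (230 / 20).
#' @param noiseSD Gaussian pixel noise SD (8-bit counts).
#' @param occlusions NULL, \code{"default"} (one 30-frame retraction episode
#'   per fore leg, emulating fore-leg occlusion during retraction), or a
#'   data.frame \code{leg}, \code{start}, \code{end} (1-based frames).
#' @param nLegs 6, or 8 for an arachnid-like walker.
#' @param schedule custom swing schedule for \code{gait = "custom"}.
#' @param seed RNG seed for the pixel noise.
#' @return list of class \code{"WalkerParams"}.
#' @export
walkerParams <- function(imageSize = 512L, fovMM = 10, fps = 1000,
                         nFrames = 600L, bodyLengthPx = 133,
                         tipWidthPx = 3, gait = "tripod",
                         strideLengthMM = 1.0, stanceDurMs = 70,
                         swingDurMs = 30, headingDeg = 40,
                         path = "straight", bendDeg = 60,
                         bendEveryMs = 200, tremor = NULL,
                         contrast = "default", noiseSD = 2,
                         occlusions = "default", nLegs = 6L, schedule = NULL,
                         seed = 1L) {
  p <- list(imageSize = as.integer(imageSize), fovMM = fovMM, fps = fps,
            nFrames = as.integer(nFrames), bodyLengthPx = bodyLengthPx,
            tipWidthPx = tipWidthPx, gait = gait,
            strideLengthMM = strideLengthMM, stanceDurMs = stanceDurMs,
            swingDurMs = swingDurMs, headingDeg = headingDeg, path = path,
            bendDeg = bendDeg, bendEveryMs = bendEveryMs, tremor = tremor,
            contrast = contrast, noiseSD = noiseSD, occlusions = occlusions,
            nLegs = as.integer(nLegs), schedule = schedule,
            seed = as.integer(seed))
  p$mmPerPx <- fovMM / imageSize
  p$periodMs <- stanceDurMs + swingDurMs
  p$speedMMs <- strideLengthMM / (p$periodMs / 1000)
  # geometry scaled to the requested body length (reference 133 px)
  sc <- bodyLengthPx / 133
  p$scale <- sc
  p$lobes <- list(
    ant = list(centre = 22 * sc, a = 32 * sc, b = 20 * sc),
    post = list(centre = -32 * sc, a = 47 * sc, b = 14 * sc))
  half <- nLegs %/% 2L
  baseAttach <- list(c(14, 30), c(14, 8), c(14, -14), c(12, 40))[
    if (half == 3L) c(1L, 2L, 3L) else c(4L, 1L, 2L, 3L)]
  # stance zones spread so adjacent claw paths stay >= ~10 px apart at all
  # gait phases (touching/crossing legs are outside this fixture's scope)
  baseClaw <- list(c(30, 52), c(44, 4), c(30, -48), c(26, 62))[
    if (half == 3L) c(1L, 2L, 3L) else c(4L, 1L, 2L, 3L)]
  legs <- c(paste0("L", seq_len(half)), paste0("R", seq_len(half)))
  p$legs <- legs
  p$attach <- p$claw0 <- matrix(0, nLegs, 2L, dimnames = list(legs, NULL))
  for (i in seq_len(half)) {
    p$attach[i, ] <- c(-baseAttach[[i]][1L], baseAttach[[i]][2L]) * sc
    p$attach[half + i, ] <- baseAttach[[i]] * sc
    p$claw0[i, ] <- c(-baseClaw[[i]][1L], baseClaw[[i]][2L]) * sc
    p$claw0[half + i, ] <- baseClaw[[i]] * sc
  }
  lv <- switch(contrast, low = c(140, 90), high = c(230, 20), c(200, 50))
  p$bgLevel <- lv[1L]; p$fgLevel <- lv[2L]
  # swing-phase offsets per leg (fraction of the cycle)
  p$phase <- setNames(numeric(nLegs), legs)
  if (gait == "tripod" && nLegs == 6L) {
    p$phase[c("L1", "R2", "L3")] <- 0
    p$phase[c("R1", "L2", "R3")] <- 0.5
  } else if (gait == "tripod") {
    # alternating-wave fallback for non-hexapods
    num <- as.integer(substring(legs, 2L))
    right <- substring(legs, 1L, 1L) == "R"
    p$phase[] <- ((num + right) %% 2L) / 2
  } else if (gait == "tetrapod") {
    p$phase[c("R1", "L2")] <- 0
    p$phase[c("R2", "L3")] <- 1 / 3
    p$phase[c("R3", "L1")] <- 2 / 3
  }
  if (identical(occlusions, "default")) {
    s1 <- min(150L, max(1L, nFrames %/% 4L))
    s2 <- min(400L, max(1L, (2L * nFrames) %/% 3L))
    p$occlusions <- data.frame(
      leg = c("L1", "R1"), start = c(s1, s2),
      end = c(min(s1 + 29L, nFrames), min(s2 + 29L, nFrames)))
  } else if (is.null(occlusions)) {
    p$occlusions <- data.frame(leg = character(0), start = integer(0),
                               end = integer(0))
  } else p$occlusions <- occlusions
  class(p) <- "WalkerParams"
  p
}

# Body-centre position and heading (deg from +y) at time t (seconds);
# vectorized over t. The walker starts so that the path is centred in the
# arena.
.walkerPath <- function(p, t) {
  spdPx <- p$speedMMs / p$mmPerPx
  Ttot <- p$nFrames / p$fps
  if (p$path == "zigzag") {
    bendT <- p$bendEveryMs / 1000
    segIdx <- floor(t / bendT)
    hFun <- function(si) p$headingDeg + p$bendDeg *
      (cumsum(c(0, rep_len(c(1, -1), max(si, 0))))[si + 1L])
    heading <- vapply(pmax(segIdx, 0), hFun, numeric(1L))
    # integrate position piecewise
    pos <- matrix(0, length(t), 2L)
    maxSeg <- floor(Ttot / bendT)
    segH <- vapply(0:(maxSeg + 1L), hFun, numeric(1L))
    hr <- .deg2rad(segH)
    segStep <- cbind(sin(hr), cos(hr)) * spdPx * bendT
    cumPos <- rbind(c(0, 0), apply(segStep, 2L, cumsum))
    within <- t - segIdx * bendT
    hr2 <- .deg2rad(heading)
    pos <- cumPos[segIdx + 1L, , drop = FALSE] +
      cbind(sin(hr2), cos(hr2)) * spdPx * within
  } else {
    hr <- .deg2rad(p$headingDeg)
    heading <- rep(p$headingDeg, length(t))
    pos <- outer(t * spdPx, c(sin(hr), cos(hr)))
  }
  # centre the whole path in the arena
  ctr <- p$imageSize / 2
  mid <- (.walkerPathRaw(p, 0, spdPx) + .walkerPathRaw(p, Ttot, spdPx)) / 2
  list(pos = sweep(pos, 2L, mid - ctr), heading = heading)
}

# raw (un-centred) position for path centring
.walkerPathRaw <- function(p, t, spdPx) {
  if (p$path == "zigzag") {
    bendT <- p$bendEveryMs / 1000
    si <- floor(t / bendT)
    hFun <- function(k) p$headingDeg + p$bendDeg *
      (cumsum(c(0, rep_len(c(1, -1), max(k, 0))))[k + 1L])
    if (si > 0) {
      hs <- vapply(0:(si - 1L), hFun, numeric(1L))
      hr <- .deg2rad(hs)
      base <- colSums(cbind(sin(hr), cos(hr))) * spdPx * bendT
    } else base <- c(0, 0)
    hr2 <- .deg2rad(hFun(si))
    base + c(sin(hr2), cos(hr2)) * spdPx * (t - si * bendT)
  } else {
    hr <- .deg2rad(p$headingDeg)
    c(sin(hr), cos(hr)) * spdPx * t
  }
}

# Full kinematic ground truth: body pose, claw positions (arena and body
# frame), swing and occlusion flags for every frame.
walkerKinematics <- function(p) {
  n <- p$nFrames
  tFrames <- (seq_len(n) - 1L) / p$fps
  bp <- .walkerPath(p, tFrames)
  pos <- bp$pos; heading <- bp$heading
  period <- p$periodMs / 1000
  swingFrac <- p$swingDurMs / p$periodMs
  S <- p$strideLengthMM / p$mmPerPx

  rot <- function(v, hDeg) {
    hr <- .deg2rad(hDeg)
    c(v[1L] * cos(hr) + v[2L] * sin(hr),
      -v[1L] * sin(hr) + v[2L] * cos(hr))
  }

  clawArena <- array(NA_real_, c(n, p$nLegs, 2L))
  swing <- matrix(FALSE, n, p$nLegs, dimnames = list(NULL, p$legs))
  smoothstep <- function(u) 3 * u^2 - 2 * u^3

  customSchedule <- if (p$gait == "custom") p$schedule else NULL

  for (j in seq_len(p$nLegs)) {
    off <- p$phase[j]
    # anchor (landing) position of cycle k: body position at landing time
    # plus the neutral claw offset advanced half a stride
    anchor <- function(k) {
      tl <- (k + swingFrac - off) * period
      cpos <- .walkerPath(p, tl)$pos[1L, ]
      h <- .walkerPath(p, tl)$heading[1L]
      cpos + rot(p$claw0[j, ] + c(0, S / 2), h)
    }
    kMin <- floor((tFrames[1L]) / period + off) - 1L
    kMax <- floor((tFrames[n]) / period + off) + 1L
    anchors <- vapply(kMin:kMax, anchor, numeric(2L))
    for (f in seq_len(n)) {
      u <- (tFrames[f] / period + off) %% 1
      k <- floor(tFrames[f] / period + off)
      ai <- k - kMin + 1L
      if (u < swingFrac) {
        swing[f, j] <- TRUE
        w <- smoothstep(u / swingFrac)
        clawArena[f, j, ] <- (1 - w) * anchors[, ai - 1L] + w * anchors[, ai]
      } else {
        clawArena[f, j, ] <- anchors[, ai]
      }
    }
    if (!is.null(customSchedule)) swing[, j] <- customSchedule[, j]
  }

  # optional lateral tremor on selected claws
  if (!is.null(p$tremor)) {
    stopifnot(p$tremor$freqHz < p$fps / 2)
    for (leg in p$tremor$legs) {
      j <- match(leg, p$legs)
      hr <- .deg2rad(heading)
      lat <- cbind(cos(hr), -sin(hr))   # unit vector perpendicular to path
      osc <- (p$tremor$ampPx / 2) * sin(2 * pi * p$tremor$freqHz * tFrames)
      clawArena[, j, ] <- clawArena[, j, ] + lat * osc
    }
  }

  occluded <- matrix(FALSE, n, p$nLegs, dimnames = list(NULL, p$legs))
  occ <- p$occlusions
  for (i in seq_len(nrow(occ))) {
    j <- match(occ$leg[i], p$legs)
    occluded[occ$start[i]:occ$end[i], j] <- TRUE
  }

  clawBody <- array(NA_real_, c(n, p$nLegs, 2L))
  for (f in seq_len(n)) {
    hr <- .deg2rad(heading[f])
    dx <- clawArena[f, , 1L] - pos[f, 1L]
    dy <- clawArena[f, , 2L] - pos[f, 2L]
    clawBody[f, , 1L] <- dx * cos(hr) - dy * sin(hr)
    clawBody[f, , 2L] <- dx * sin(hr) + dy * cos(hr)
  }

  list(pos = pos, heading = heading, clawArena = clawArena,
       clawBody = clawBody, swing = swing, occluded = occluded,
       tSec = tFrames)
}

# Draw an anti-aliased capsule (line segment with linearly varying
# half-width) into an alpha canvas; returns the updated canvas.
.drawCapsule <- function(alpha, p0, p1, hw0, hw1) {
  d <- dim(alpha)
  lo <- floor(pmin(p0, p1) - max(hw0, hw1) - 1)
  hi <- ceiling(pmax(p0, p1) + max(hw0, hw1) + 1)
  x0 <- max(0, lo[1L]); x1 <- min(d[2L] - 1L, hi[1L])
  y0 <- max(0, lo[2L]); y1 <- min(d[1L] - 1L, hi[2L])
  if (x0 > x1 || y0 > y1) return(alpha)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  v <- p1 - p0
  len2 <- sum(v^2)
  tt <- if (len2 < 1e-12) matrix(0, nrow(gx), ncol(gx)) else
    pmin(pmax(((gx - p0[1L]) * v[1L] + (gy - p0[2L]) * v[2L]) / len2, 0), 1)
  px <- p0[1L] + tt * v[1L]; py <- p0[2L] + tt * v[2L]
  dist <- sqrt((gx - px)^2 + (gy - py)^2)
  hw <- hw0 + tt * (hw1 - hw0)
  cov <- pmin(pmax(hw + 0.5 - dist, 0), 1)
  sub <- alpha[ys + 1L, xs + 1L, drop = FALSE]
  alpha[ys + 1L, xs + 1L] <- pmax(sub, cov)
  alpha
}

# Draw an anti-aliased rotated ellipse (centre c, semi-axes a along the
# heading direction and b across it).
.drawEllipse <- function(alpha, centre, a, b, headingDeg) {
  d <- dim(alpha)
  rmax <- max(a, b) + 1
  x0 <- max(0, floor(centre[1L] - rmax)); x1 <- min(d[2L] - 1L, ceiling(centre[1L] + rmax))
  y0 <- max(0, floor(centre[2L] - rmax)); y1 <- min(d[1L] - 1L, ceiling(centre[2L] + rmax))
  if (x0 > x1 || y0 > y1) return(alpha)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys)) - centre[1L]
  gy <- matrix(rep(ys, times = length(xs)), length(ys)) - centre[2L]
  hr <- .deg2rad(headingDeg)
  u <- c(sin(hr), cos(hr))              # along-axis unit
  ta <- gx * u[1L] + gy * u[2L]
  tb <- gx * u[2L] - gy * u[1L]
  f <- sqrt((ta / a)^2 + (tb / b)^2)
  cov <- pmin(pmax((1 - f) * min(a, b) + 0.5, 0), 1)
  sub <- alpha[ys + 1L, xs + 1L, drop = FALSE]
  alpha[ys + 1L, xs + 1L] <- pmax(sub, cov)
  alpha
}

# Render the body and leg alpha masks of one frame from precomputed
# kinematics. Returns list(body, legs) of alpha matrices in [0, 1].
.renderAlphas <- function(p, kin, f) {
  n <- p$imageSize
  bodyA <- matrix(0, n, n)
  legA <- matrix(0, n, n)
  centre <- kin$pos[f, ]; h <- kin$heading[f]
  hr <- .deg2rad(h)
  u <- c(sin(hr), cos(hr))
  bodyA <- .drawEllipse(bodyA, centre + u * p$lobes$ant$centre,
                        p$lobes$ant$a, p$lobes$ant$b, h)
  bodyA <- .drawEllipse(bodyA, centre + u * p$lobes$post$centre,
                        p$lobes$post$a, p$lobes$post$b, h)
  rot <- function(v) c(v[1L] * cos(hr) + v[2L] * sin(hr),
                       -v[1L] * sin(hr) + v[2L] * cos(hr))
  tipHW <- p$tipWidthPx / 2
  for (j in seq_len(p$nLegs)) {
    att <- centre + rot(p$attach[j, ])
    claw <- kin$clawArena[f, j, ]
    if (kin$occluded[f, j]) {
      # retracted under the body: draw only a stub toward the body edge
      claw <- att + 0.3 * (claw - att)
    }
    mid <- (att + claw) / 2
    outward <- claw - att
    perp <- c(outward[2L], -outward[1L])
    nl <- sqrt(sum(perp^2))
    if (nl > 1e-9) perp <- perp / nl
    sgn <- sign(sum((mid + perp - centre)^2) - sum((mid - perp - centre)^2))
    knee <- mid + sgn * perp * 8 * p$scale
    legA <- .drawCapsule(legA, att, knee, 2.2 * p$scale, 1.8 * p$scale)
    # the nominal claw is the centre of the rounded tip cap -- the pixel a
    # human annotator would click on the ~3-px tip blob
    legA <- .drawCapsule(legA, knee, claw, 1.8 * p$scale, tipHW)
  }
  list(body = bodyA, legs = legA)
}

#' Render a synthetic walker video with ground truth
#'
#' @param p a \code{\link{walkerParams}} list.
#' @param keepMasks frame indices for which the per-pixel ground-truth leg
#'   and body masks are retained (they are large; regenerate any frame later
#'   with \code{\link{walkerLegMask}}).
#' @return list: \code{stack} (a \code{FrameStack}) and \code{truth} (class
#'   \code{"WalkerTruth"}: body positions/headings, per-leg claw positions in
#'   arena and body frame, swing/occlusion flags, and masks for the kept
#'   frames).
#' @export
renderWalkerVideo <- function(p, keepMasks = integer(0)) {
  kin <- walkerKinematics(p)
  n <- p$nFrames
  framesL <- vector("list", n)
  masks <- list()
  withSeed(p$seed, for (f in seq_len(n)) {
    al <- .renderAlphas(p, kin, f)
    alpha <- pmax(al$body, al$legs)
    img <- p$bgLevel * (1 - alpha) + p$fgLevel * alpha
    if (p$noiseSD > 0)
      img <- img + matrix(rnorm(length(img), 0, p$noiseSD),
                          p$imageSize, p$imageSize)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    framesL[[f]] <- img
    if (f %in% keepMasks)
      masks[[as.character(f)]] <- list(body = al$body > 0.5,
                                       legs = al$legs > 0.5 & al$body <= 0.5)
  })
  stack <- frameStack(framesL, p$fps, p$fovMM, sourceDir = "")
  truth <- structure(list(
    pos = kin$pos, heading = kin$heading, clawArena = kin$clawArena,
    clawBody = kin$clawBody, swing = kin$swing, occluded = kin$occluded,
    legs = p$legs, masks = masks, params = p), class = "WalkerTruth")
  list(stack = stack, truth = truth)
}

#' Ground-truth leg mask of one frame
#'
#' Re-renders the requested frame's leg and body masks (pixels where the
#' leg / body coverage exceeds one half).
#'
#' @param p a \code{WalkerParams} list.
#' @param f 1-based frame index.
#' @return list with logical matrices \code{legs} and \code{body}.
#' @export
walkerLegMask <- function(p, f) {
  kin <- walkerKinematics(p)
  al <- .renderAlphas(p, kin, f)
  list(legs = al$legs > 0.5 & al$body <= 0.5, body = al$body > 0.5)
}

#' @export
print.WalkerTruth <- function(x, ...) {
  cat(sprintf("WalkerTruth: %d frames, %d legs, gait '%s'\n",
              nrow(x$pos), length(x$legs), x$params$gait))
  invisible(x)
}

#' Synthetic swing/stance schedule
#'
#' Noise-free canonical schedules: \code{tripod} alternates the two tripod
#' sets back to back (each set swings half the cycle), \code{tetrapod}
#' cycles three diagonal leg pairs (each pair swings a third of the cycle),
#' and \code{none} keeps every leg in stance.
#'
#' @param mode \code{"tripod"}, \code{"tetrapod"} or \code{"none"}.
#' @param fps frame rate.
#' @param nFrames number of frames.
#' @param periodMs full gait-cycle duration, ms.
#' @return logical nFrames x 6 matrix with columns L1,L2,L3,R1,R2,R3.
#' @export
synthGaitPattern <- function(mode = c("tripod", "tetrapod", "none"),
                             fps = 1000, nFrames = 600L, periodMs = 100) {
  mode <- match.arg(mode)
  legs <- c("L1", "L2", "L3", "R1", "R2", "R3")
  sw <- matrix(FALSE, nFrames, 6L, dimnames = list(NULL, legs))
  if (mode == "none") return(sw)
  tMs <- (seq_len(nFrames) - 1L) / fps * 1000
  u <- (tMs %% periodMs) / periodMs
  if (mode == "tripod") {
    setA <- c("L1", "R2", "L3"); setB <- c("R1", "L2", "R3")
    sw[, setA] <- u < 0.5
    sw[, setB] <- u >= 0.5
  } else {
    pairs <- list(c("R1", "L2"), c("R2", "L3"), c("R3", "L1"))
    for (k in 1:3) {
      on <- u >= (k - 1) / 3 & u < k / 3
      sw[, pairs[[k]]] <- sw[, pairs[[k]]] | on
    }
  }
  sw
}

#' Synthetic claw trace with an injected oscillation
#'
#' Emulates a body-frame claw trace during walking: a slow protraction
#' drift along y, plus one brief biphasic lateral flick per stride on x
#' whose default amplitude sits just below the 3-px shake cut (so a trace
#' without tremor yields no shake events, while the flicks still perturb
#' the timing and amplitude of any riding oscillation the way stride
#' motion does), plus an optional lateral sinusoidal oscillation of the
#' requested frequency and peak-to-valley amplitude. Returned as an (x, y)
#' trace in px; the truth lists the oscillation's extremum times.
#'
#' @param freqHz oscillation frequency (must be below fps/2).
#' @param ampPx peak-to-valley oscillation amplitude, px (0 = none).
#' @param fps frame rate.
#' @param nFrames trace length.
#' @param strideHz stride (flick) rhythm, default 6.5.
#' @param burstHz burst-modulation rate of the oscillation (tremor occurs
#'   in episodes rather than as a pure tone; 0 = unmodulated). Near burst
#'   edges the oscillation dips below the detection cut, so recovered
#'   inter-event intervals disperse around the carrier period the way real
#'   episodic tremor does.
#' @param flickAmpPx peak-to-valley amplitude of the per-stride flick.
#' @param driftAmpPx,driftHz slow protraction drift on y.
#' @param noiseSD positional jitter SD, px.
#' @param seed RNG seed for the jitter.
#' @return list: \code{trace} (nFrames x 2), \code{extremumFrames} (1-based
#'   frame indices of oscillation peaks and valleys), \code{periodMs}.
#' @export
synthTrace <- function(freqHz, ampPx, fps = 1000, nFrames = 1000L,
                       strideHz = 6.5, burstHz = 2.5, flickAmpPx = 2.5,
                       driftAmpPx = 20, driftHz = 0.7, noiseSD = 0,
                       seed = 1L) {
  if (freqHz >= fps / 2)
    stop("aliasing: oscillation frequency must be below fps/2")
  t <- (seq_len(nFrames) - 1L) / fps
  y <- driftAmpPx * sin(2 * pi * driftHz * t)
  T <- 1 / strideHz
  tin <- t %% T
  flick <- ifelse(tin < 0.04,
                  (flickAmpPx / 2) * sin(2 * pi * tin / 0.04), 0)
  m <- if (burstHz > 0) pmax(sin(2 * pi * burstHz * t), 0) else 1
  x <- flick + (ampPx / 2) * m * sin(2 * pi * freqHz * t)
  if (noiseSD > 0) {
    jit <- withSeed(seed, matrix(rnorm(2L * nFrames, 0, noiseSD), ncol = 2L))
    x <- x + jit[, 1L]; y <- y + jit[, 2L]
  }
  extremumFrames <- integer(0)
  if (ampPx > 0) {
    # extrema of sin(2 pi f t) at t = (2k+1) / (4 f)
    k <- 0:floor(2 * freqHz * max(t))
    te <- (2 * k + 1) / (4 * freqHz)
    te <- te[te <= max(t)]
    extremumFrames <- round(te * fps) + 1L
  }
  list(trace = cbind(x = x, y = y), extremumFrames = extremumFrames,
       periodMs = 1000 / freqHz)
}
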