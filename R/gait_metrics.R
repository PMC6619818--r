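# Body, stride, leg-domain, gait-index and stance statistics computed from a
# TrackSet. All distances are reported in mm (claw positions are converted
# with the stack's mm-per-px calibration); durations in ms; speeds in mm/s.

# Remove single-sample out-and-back displacement spikes (completing within
# 1 ms) from a coordinate trace: such jumps are correction artifacts, not
# motion. The spiked sample is replaced by the neighbour midpoint.
filterSpikes <- function(xy, fps, minJumpPx = 5) {
  n <- nrow(xy)
  w <- max(1L, round(fps / 1000))      # samples per ms
  if (n < 3L) return(xy)
  for (t in 2:(n - w)) {
    a <- xy[t - 1L, ]; b <- xy[t, ]; cc <- xy[t + w, ]
    if (anyNA(a) || anyNA(b) || anyNA(cc)) next
    out <- sqrt(sum((b - a)^2)); back <- sqrt(sum((cc - b)^2))
    net <- sqrt(sum((cc - a)^2))
    if (out > minJumpPx && back > minJumpPx && net < minJumpPx)
      xy[t, ] <- (a + cc) / 2
  }
  xy
}

# Smoothed instantaneous speed (mm/s) of a 2-column px trace.
.traceSpeed <- function(xy, fps, mmPerPx, smoothMs = 15) {
  n <- nrow(xy)
  sp <- c(NA_real_, sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)) * fps * mmPerPx
  k <- max(1L, round(smoothMs / 1000 * fps))
  ok <- !is.na(sp)
  if (any(ok)) sp[ok] <- rollMeanCentered(sp[ok], k)
  sp
}

#' Detect stride (swing) events of one leg
#'
#' The claw's arena-frame speed trace (smoothed over \code{smoothMs}) is
#' split into swing and stance by a hysteresis detector: a swing starts when
#' the speed rises above \code{vOn} and ends when it falls below
#' \code{vOff}; runs shorter than \code{minSwingMs} are discarded. Each
#' swing is one stride event; the take-off (posterior extreme position, PEP)
#' is the body-frame claw position at swing start and the landing (anterior
#' extreme position, AEP) the position at swing end. Gaps of up to
#' \code{maxGap} frames are interpolated first; longer gaps split the trace.
#'
#' @param bodyXY,arenaXY nFrames x 2 matrices of claw positions, px.
#' @param fps frame rate.
#' @param mmPerPx spatial calibration.
#' @param vOn,vOff swing on/off speed thresholds, mm/s.
#' @param minSwingMs minimum swing duration, ms.
#' @param smoothMs speed smoothing window, ms.
#' @param maxGap maximum interpolated gap, frames.
#' @return data.frame, one row per stride: \code{start}, \code{end} (1-based
#'   frames), \code{duration_ms}, PEP/AEP body-frame positions in mm, and a
#'   \code{swing} attribute (logical per-frame swing flags).
#' @export
detectStrides <- function(bodyXY, arenaXY, fps, mmPerPx,
                          vOn = 4, vOff = 2, minSwingMs = 3,
                          smoothMs = 15, maxGap = 5L) {
  n <- nrow(arenaXY)
  arenaI <- apply(arenaXY, 2L, interpolateGaps, maxGap = maxGap)
  bodyI <- apply(bodyXY, 2L, interpolateGaps, maxGap = maxGap)
  sp <- .traceSpeed(arenaI, fps, mmPerPx, smoothMs)
  swing <- rep(FALSE, n)
  inSwing <- FALSE
  for (t in seq_len(n)) {
    s <- sp[t]
    if (is.na(s)) { inSwing <- FALSE; next }
    if (!inSwing && s > vOn) inSwing <- TRUE
    else if (inSwing && s < vOff) inSwing <- FALSE
    swing[t] <- inSwing
  }
  minFrames <- max(1L, round(minSwingMs / 1000 * fps))
  r <- rle(swing)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= minFrames)
  drop <- which(r$values & r$lengths < minFrames)
  for (i in drop) swing[starts[i]:ends[i]] <- FALSE

  ev <- data.frame(start = integer(0), end = integer(0),
                   duration_ms = numeric(0),
                   pep_x = numeric(0), pep_y = numeric(0),
                   aep_x = numeric(0), aep_y = numeric(0))
  for (i in keep) {
    s <- starts[i]; e <- ends[i]
    if (anyNA(bodyI[s, ]) || anyNA(bodyI[e, ])) next
    ev <- rbind(ev, data.frame(
      start = s, end = e, duration_ms = (e - s + 1L) / fps * 1000,
      pep_x = bodyI[s, 1L] * mmPerPx, pep_y = bodyI[s, 2L] * mmPerPx,
      aep_x = bodyI[e, 1L] * mmPerPx, aep_y = bodyI[e, 2L] * mmPerPx))
  }
  attr(ev, "swing") <- swing
  attr(ev, "bodyI") <- bodyI
  attr(ev, "arenaI") <- arenaI
  ev
}

#' Per-stride parameters
#'
#' For every stride event: displacement (straight-line PEP-to-AEP distance),
#' path (summed inter-frame steps), amplitude (displacement projected onto
#' the body axis, i.e. along the direction of motion), period (start-to-start
#' interval to the next stride of the same leg; empty for the last),
#' stance linearity (RMS deviation of the arena-frame stride path from a
#' cubic-spline curve through control points sampled every 20 ms), and
#' stretch (distance of the claw from the body centre at the temporal
#' midpoint of the stride). All distances mm, times ms.
#'
#' @param events output of \code{\link{detectStrides}}.
#' @param fps frame rate.
#' @param mmPerPx spatial calibration.
#' @return the events data.frame with parameter columns added.
#' @export
strideParameters <- function(events, fps, mmPerPx) {
  bodyI <- attr(events, "bodyI"); arenaI <- attr(events, "arenaI")
  n <- nrow(events)
  out <- events
  out$displacement_mm <- out$path_mm <- out$amplitude_mm <-
    out$period_ms <- out$linearity_mm <- out$stretch_mm <- NA_real_
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    s <- events$start[i]; e <- events$end[i]
    seg <- bodyI[s:e, , drop = FALSE] * mmPerPx
    pep <- c(events$pep_x[i], events$pep_y[i])
    aep <- c(events$aep_x[i], events$aep_y[i])
    out$displacement_mm[i] <- sqrt(sum((aep - pep)^2))
    steps <- sqrt(diff(seg[, 1L])^2 + diff(seg[, 2L])^2)
    out$path_mm[i] <- sum(steps, na.rm = TRUE)
    out$amplitude_mm[i] <- abs(aep[2L] - pep[2L])
    mid <- bodyI[(s + e) %/% 2L, ] * mmPerPx
    out$stretch_mm[i] <- sqrt(sum(mid^2))
    # stance linearity: spline through 20-ms control points of the arena path
    aseg <- arenaI[s:e, , drop = FALSE] * mmPerPx
    tAll <- (s:e) / fps * 1000
    tCtrl <- unique(c(seq(tAll[1L], tAll[length(tAll)], by = 20),
                      tAll[length(tAll)]))
    if (length(tCtrl) >= 2L && !anyNA(aseg)) {
      ci <- vapply(tCtrl, function(tc) which.min(abs(tAll - tc)), integer(1L))
      fitx <- spline(tAll[ci], aseg[ci, 1L], xout = tAll, method = "natural")$y
      fity <- spline(tAll[ci], aseg[ci, 2L], xout = tAll, method = "natural")$y
      out$linearity_mm[i] <- sqrt(mean((aseg[, 1L] - fitx)^2 +
                                       (aseg[, 2L] - fity)^2))
    }
  }
  if (n > 1L)
    out$period_ms[seq_len(n - 1L)] <- diff(events$start) / fps * 1000
  out
}

# Convex-hull domain of a body-frame trajectory (mm): hull vertices, area,
# and length/width as the extents of the projections onto the principal axes.
legDomain <- function(ptsMM) {
  pts <- ptsMM[!is.na(ptsMM[, 1L]) & !is.na(ptsMM[, 2L]), , drop = FALSE]
  if (nrow(unique(pts)) < 3L)
    return(list(hull = NULL, area = NA_real_, length = NA_real_,
                width = NA_real_))
  h <- chull(pts)
  hull <- pts[h, , drop = FALSE]
  pc <- prcomp(pts, center = TRUE)
  ext <- c(diff(range(pc$x[, 1L])), diff(range(pc$x[, 2L])))
  # PC1 maximizes variance, not extent; order so length >= width holds
  list(hull = hull, area = polygonArea(hull),
       length = max(ext), width = min(ext))
}

#' Per-leg summary parameters
#'
#' One row per leg: stride count, mean claw speed, movement percentage
#' (fraction of tracked frames spent in swing), mean stride period,
#' footprint regularity (mean of the standard deviations of the AEP and PEP
#' point clouds, where the cloud SD is \code{sqrt(var(x) + var(y))}), and
#' the leg trajectory domain (convex-hull area plus length/width via
#' principal-axis projections). Footprint regularity, domain length and mean
#' stride length are also reported normalized by body length.
#'
#' @param tracks a \code{TrackSet}.
#' @param strideList named list (per leg) of \code{\link{strideParameters}}
#'   outputs.
#' @param bodyLengthMM the individual's body length, mm.
#' @return data.frame, one row per leg.
#' @export
legParameters <- function(tracks, strideList, bodyLengthMM) {
  fps <- tracks@frameRate; mpp <- tracks@mmPerPx
  rows <- lapply(seq_along(tracks@legs), function(j) {
    leg <- tracks@legs[j]
    ev <- strideList[[leg]]
    arena <- tracks@arena[, j, , drop = TRUE]
    body <- tracks@body[, j, , drop = TRUE]
    sp <- .traceSpeed(apply(arena, 2L, interpolateGaps), fps, mpp)
    tracked <- sum(!tracks@missing[, j])
    swing <- attr(ev, "swing")
    cloudSD <- function(m) if (nrow(m) < 2L) NA_real_ else
      sqrt(var(m[, 1L]) + var(m[, 2L]))
    fpReg <- if (nrow(ev) >= 2L)
      mean(c(cloudSD(cbind(ev$aep_x, ev$aep_y)),
             cloudSD(cbind(ev$pep_x, ev$pep_y)))) else NA_real_
    dom <- legDomain(body * mpp)
    data.frame(
      leg = leg, n_strides = nrow(ev),
      mean_speed_mm_s = mean(sp, na.rm = TRUE),
      movement_pct = 100 * sum(swing & !tracks@missing[, j]) / max(tracked, 1L),
      mean_stride_period_ms = if (nrow(ev) > 1L)
        mean(ev$period_ms, na.rm = TRUE) else NA_real_,
      mean_stride_length_mm = if (nrow(ev)) mean(ev$displacement_mm)
        else NA_real_,
      footprint_regularity_mm = fpReg,
      domain_area_mm2 = dom$area,
      domain_length_mm = dom$length,
      domain_width_mm = dom$width,
      footprint_regularity_norm = fpReg / bodyLengthMM,
      domain_length_norm = dom$length / bodyLengthMM,
      stride_length_norm = if (nrow(ev))
        mean(ev$displacement_mm) / bodyLengthMM else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pairwise leg-domain overlap areas
#'
#' Intersection area of every unordered pair of leg trajectory domains
#' (convex polygon clipping), reported raw and normalized by the average
#' number of strides per leg.
#'
#' @param domains named list of \code{legDomain} results.
#' @param meanStridesPerLeg normalizer.
#' @return data.frame with one row per pair.
#' @export
domainOverlap <- function(domains, meanStridesPerLeg = NA_real_) {
  legs <- names(domains)
  out <- NULL
  for (i in seq_along(legs)) for (j in seq_along(legs)) {
    if (j <= i) next
    a <- domains[[i]]$hull; b <- domains[[j]]$hull
    ov <- if (is.null(a) || is.null(b)) NA_real_ else {
      inter <- clipConvexPolygon(a, b)
      if (nrow(inter) < 3L) 0 else polygonArea(inter)
    }
    out <- rbind(out, data.frame(
      leg_a = legs[i], leg_b = legs[j], overlap_mm2 = ov,
      overlap_norm = ov / meanStridesPerLeg))
  }
  out
}

#' Stance width
#'
#' The distance between the mean stance positions (midpoints of AEP and PEP)
#' of the left and right middle legs, mm. Undefined (NA) when either side
#' has no strides.
#'
#' @param strideList named list of per-leg stride tables.
#' @param leftLeg,rightLeg the middle-leg labels.
#' @return single-row data.frame.
#' @export
stanceWidth <- function(strideList, leftLeg = "L2", rightLeg = "R2") {
  mid <- function(ev) {
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    c(mean((ev$pep_x + ev$aep_x) / 2), mean((ev$pep_y + ev$aep_y) / 2))
  }
  a <- mid(strideList[[leftLeg]]); b <- mid(strideList[[rightLeg]])
  w <- if (is.null(a) || is.null(b)) NA_real_ else sqrt(sum((a - b)^2))
  data.frame(stance_width_mm = w)
}

#' Gait index from a swing/stance schedule
#'
#' Per frame, the set of swinging legs scores +1 when it is one of the two
#' canonical tripod sets ({L1,R2,L3} or {R1,L2,R3}), -1 when it is a
#' canonical tetrapod swing pair (one left and one right leg of different
#' segments) and 0 otherwise; the series is smoothed by a centred moving
#' average over \code{windowMs} and clipped to [-1, 1].
#'
#' @param swing logical nFrames x nLegs matrix; columns named by leg.
#' @param fps frame rate.
#' @param windowMs smoothing window, ms (default 120).
#' @return numeric vector of per-frame gait-index values.
#' @export
gaitIndexFromSchedule <- function(swing, fps, windowMs = 120) {
  legs <- colnames(swing)
  tripods <- list(c("L1", "R2", "L3"), c("R1", "L2", "R3"))
  raw <- apply(swing, 1L, function(s) {
    on <- legs[s]
    if (length(on) == 3L &&
        (setequal(on, tripods[[1L]]) || setequal(on, tripods[[2L]])))
      return(1)
    if (length(on) == 2L) {
      side <- substr(on, 1L, 1L); seg <- substr(on, 2L, 2L)
      if (side[1L] != side[2L] && seg[1L] != seg[2L]) return(-1)
    }
    0
  })
  k <- max(1L, round(windowMs / 1000 * fps))
  pmin(pmax(rollMeanCentered(raw, k), -1), 1)
}

#' Body parameters and turning points
#'
#' Per-frame body length (silhouette extent along the body axis, mm),
#' instantaneous centroid velocity (mm/s), and turning points: the centroid
#' trajectory is simplified with the Douglas-Peucker algorithm and a turn is
#' recorded wherever two neighbouring segments of the simplified polyline
#' differ in direction by more than \code{turnDeg} degrees.
#'
#' @param poses the \code{poses} data.frame of a \code{TrackSet}.
#' @param fps frame rate.
#' @param mmPerPx spatial calibration.
#' @param dpTolPx Douglas-Peucker tolerance, px (default 5).
#' @param turnDeg turn threshold, degrees (default 50).
#' @return list: \code{bodyLength} (per-frame data.frame),
#'   \code{bodyVelocity}, \code{turns} (one row per turn).
#' @export
bodyParameters <- function(poses, fps, mmPerPx, dpTolPx = 5, turnDeg = 50) {
  n <- nrow(poses)
  bl <- data.frame(frame = poses$frame,
                   body_length_mm = poses$extent_px * mmPerPx)
  vel <- c(NA_real_, sqrt(diff(poses$cx)^2 + diff(poses$cy)^2)) * fps * mmPerPx
  bv <- data.frame(frame = poses$frame, velocity_mm_s = vel)
  pts <- cbind(poses$cx, poses$cy)
  keep <- douglasPeucker(pts, dpTolPx)
  turns <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      angle_deg = numeric(0))
  if (length(keep) >= 3L) {
    for (i in 2:(length(keep) - 1L)) {
      a <- pts[keep[i - 1L], ]; b <- pts[keep[i], ]; cc <- pts[keep[i + 1L], ]
      v1 <- b - a; v2 <- cc - b
      ang <- acos(pmin(pmax(sum(v1 * v2) /
                            (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) *
             180 / pi
      if (is.finite(ang) && ang > turnDeg)
        turns <- rbind(turns, data.frame(frame = poses$frame[keep[i]],
                                         x = b[1L], y = b[2L],
                                         angle_deg = ang))
    }
  }
  list(bodyLength = bl, bodyVelocity = bv, turns = turns)
}

#' Assemble the full gait report
#'
#' Runs stride detection and all parameter computations for every leg and
#' collects the result tables. Single-frame displacement spikes are filtered
#' from the traces before analysis.
#'
#' @param tracks a \code{TrackSet}.
#' @param vOn,vOff,minSwingMs,smoothMs,maxGap stride-detector settings, see
#'   \code{\link{detectStrides}}.
#' @param dpTolPx,turnDeg turning-point settings.
#' @param windowMs gait-index smoothing window, ms.
#' @return a \code{\link{GaitReport-class}}.
#' @export
gaitReport <- function(tracks, vOn = 4, vOff = 2, minSwingMs = 3,
                       smoothMs = 15, maxGap = 5L, dpTolPx = 5,
                       turnDeg = 50, windowMs = 120) {
  fps <- tracks@frameRate; mpp <- tracks@mmPerPx
  nf <- dim(tracks@arena)[1L]
  legs <- tracks@legs

  strideList <- list()
  swingMat <- matrix(FALSE, nf, length(legs),
                     dimnames = list(NULL, legs))
  for (j in seq_along(legs)) {
    arena <- filterSpikes(tracks@arena[, j, , drop = TRUE], fps)
    body <- filterSpikes(tracks@body[, j, , drop = TRUE], fps)
    ev <- detectStrides(body, arena, fps, mpp, vOn, vOff, minSwingMs,
                        smoothMs, maxGap)
    ev <- strideParameters(ev, fps, mpp)
    strideList[[legs[j]]] <- ev
    swingMat[, j] <- attr(ev, "swing")
  }

  bp <- bodyParameters(tracks@poses, fps, mpp, dpTolPx, turnDeg)
  bodyLengthMM <- median(bp$bodyLength$body_length_mm, na.rm = TRUE)
  legTab <- legParameters(tracks, strideList, bodyLengthMM)
  domains <- lapply(seq_along(legs), function(j)
    legDomain(tracks@body[, j, , drop = TRUE] * mpp))
  names(domains) <- legs
  meanStrides <- mean(legTab$n_strides)
  gi <- gaitIndexFromSchedule(swingMat, fps, windowMs)
  bp$bodyVelocity$gait_index <- gi

  strideTab <- do.call(rbind, lapply(legs, function(l) {
    ev <- strideList[[l]]
    if (nrow(ev) == 0L) return(NULL)
    cbind(data.frame(leg = l), ev)
  }))
  if (is.null(strideTab)) strideTab <- data.frame()

  new("GaitReport", bodyLengthMM = bodyLengthMM, tables = list(
    bodyLength = bp$bodyLength,
    bodyVelocity = bp$bodyVelocity,
    turns = bp$turns,
    strides = strideTab,
    legs = legTab,
    domainOverlap = domainOverlap(domains, meanStrides),
    stanceWidth = stanceWidth(strideList),
    strideList = strideList,
    swing = swingMat))
}
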