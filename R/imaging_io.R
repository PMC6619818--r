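# Frame-stack input, background estimation, silhouette extraction and the
# CSV writers for all tracking/gait output tables.

#' Build a FrameStack from in-memory matrices
#'
#' @param frames list of same-shaped grayscale matrices (0--255).
#' @param frameRate frames per second.
#' @param fovMM width of the field of view in millimetres; the spatial
#'   calibration is \code{fovMM / image width}.
#' @param sourceDir optional provenance string.
#' @return a \code{\link{FrameStack-class}} object.
#' @export
frameStack <- function(frames, frameRate, fovMM, sourceDir = "") {
  w <- ncol(frames[[1L]])
  new("FrameStack", frames = frames, frameRate = as.numeric(frameRate),
      mmPerPx = fovMM / w, sourceDir = sourceDir)
}

#' Load a TIFF/PNG frame sequence from a directory
#'
#' Frames are read in filename (lexicographic) order and must share one
#' shape. Multi-channel images are collapsed to their first channel.
#' Tracking needs at least two frames.
#'
#' @param dir directory containing the image sequence.
#' @param frameRate acquisition frame rate, fps.
#' @param fovMM field-of-view width in mm.
#' @param pattern filename regexp, default matches .tif/.tiff/.png.
#' @return a \code{\link{FrameStack-class}} object.
#' @export
loadFrameStack <- function(dir, frameRate, fovMM,
                           pattern = "\\.(tif|tiff|png)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no readable frames found in ", dir)
  if (length(files) < 2L)
    stop("tracking needs at least 2 frames; found ", length(files))
  readOne <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    # readers return [0,1] doubles; restore the 8-bit scale
    if (max(img) <= 1) img <- img * 255
    img
  }
  frames <- lapply(files, readOne)
  d <- dim(frames[[1L]])
  bad <- which(!vapply(frames, function(f) identical(dim(f), d), logical(1L)))
  if (length(bad))
    stop("frame shape mismatch at ", basename(files[bad[1L]]),
         " (expected ", d[1L], " x ", d[2L], ")")
  frameStack(frames, frameRate, fovMM, sourceDir = dir)
}

#' Write a FrameStack to a directory of TIFF frames
#'
#' @param stack a \code{FrameStack}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; frames are numbered with enough zero
#'   padding to sort lexicographically.
#' @return the directory, invisibly.
#' @export
writeFrameStack <- function(stack, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nFrames(stack)
  w <- nchar(as.character(n))
  for (i in seq_len(n)) {
    f <- file.path(dir, sprintf("%s_%0*d.tif", prefix, w, i))
    tiff::writeTIFF(pmin(pmax(stack@frames[[i]] / 255, 0), 1), f,
                    bits.per.sample = 8L)
  }
  invisible(dir)
}

# Centroid of the dark blob of one raw frame (Otsu on inverted intensities),
# used by the spliced background mode. Returns c(x, y) 0-based, or NULL.
.darkBlobCentroid <- function(frame) {
  thr <- otsuThreshold(frame)
  mask <- frame < thr
  xy <- maskCoords(mask)
  if (!nrow(xy)) return(NULL)
  colMeans(xy)
}

#' Estimate the arena background of a frame stack
#'
#' Three modes are supported. \code{auto} takes the per-pixel median over
#' every \code{sampleStride}-th frame: with a dark animal moving over a
#' bright, static background, the median at each pixel is the background
#' value provided the animal does not dwell there for most of the sampled
#' frames. \code{spliced} mosaics the first and the last frame along the
#' perpendicular bisector of the two body centroids: each pixel is taken from
#' the frame whose animal is \emph{farther} away, so the animal is absent from
#' the mosaic whenever it displaced far enough between the two frames.
#' \code{loaded} passes a user-supplied image through.
#'
#' The automatic modes presume the animal travels at least about 1.5 body
#' lengths across the stack; when the observed displacement (of the dark
#' blob) falls short of that, the result carries a \code{"stationary"} flag.
#'
#' @param stack a \code{FrameStack}.
#' @param mode one of \code{"auto"}, \code{"spliced"}, \code{"loaded"}.
#' @param image background matrix for \code{mode = "loaded"}.
#' @param sampleStride frame sampling stride for \code{mode = "auto"}
#'   (default 20, mirroring the training-frame sampling rate).
#' @return a \code{\link{BackgroundImage-class}} object.
#' @export
estimateBackground <- function(stack,
                               mode = c("auto", "spliced", "loaded"),
                               image = NULL, sampleStride = 20L) {
  mode <- match.arg(mode)
  fr <- stack@frames
  if (mode == "loaded") {
    if (is.null(image)) stop("mode 'loaded' needs a background image")
    if (!identical(dim(image), dim(fr[[1L]])))
      stop("loaded background shape does not match the frames")
    return(new("BackgroundImage", image = image, mode = "loaded",
               flags = character(0)))
  }

  c1 <- .darkBlobCentroid(fr[[1L]])
  c2 <- .darkBlobCentroid(fr[[length(fr)]])
  flags <- character(0)
  # displacement check against ~1.5 body lengths, body length taken as the
  # major-axis extent of the first-frame blob
  if (!is.null(c1) && !is.null(c2)) {
    thr <- otsuThreshold(fr[[1L]])
    xy <- maskCoords(fr[[1L]] < thr)
    ext <- if (nrow(xy) > 1L) {
      pc <- prcomp(xy, center = TRUE)
      diff(range(pc$x[, 1L]))
    } else 0
    disp <- sqrt(sum((c2 - c1)^2))
    if (ext > 0 && disp < 1.5 * ext) flags <- "stationary"
  }

  if (mode == "auto") {
    sel <- seq(1L, length(fr), by = as.integer(sampleStride))
    if (length(sel) < 3L) sel <- seq_along(fr)
    m <- vapply(fr[sel], as.vector, as.vector(fr[[1L]] * 1.0))
    bg <- matrix(rowMedians(m), nrow(fr[[1L]]), ncol(fr[[1L]]))
    return(new("BackgroundImage", image = bg, mode = "auto", flags = flags))
  }

  # spliced
  if (is.null(c1) || is.null(c2))
    stop("could not locate the animal in the first/last frame")
  d <- dim(fr[[1L]])
  xg <- matrix(rep(0:(d[2L] - 1L), each = d[1L]), d[1L], d[2L])
  yg <- matrix(rep(0:(d[1L] - 1L), times = d[2L]), d[1L], d[2L])
  nearFirst <- (xg - c1[1L])^2 + (yg - c1[2L])^2 <
               (xg - c2[1L])^2 + (yg - c2[2L])^2
  bg <- fr[[1L]] * 1.0
  bg[nearFirst] <- fr[[length(fr)]][nearFirst]
  new("BackgroundImage", image = bg, mode = "spliced", flags = flags)
}

#' Extract the animal silhouette of one frame
#'
#' Thresholds the absolute background difference,
#' \code{|frame - background| > thr}, keeps the largest connected component,
#' and re-attaches any smaller component lying within \code{dustRadius}
#' pixels of it (legs occasionally detach from the body by a pixel or two;
#' genuinely distant specks are dust and get dropped).
#'
#' @param frame grayscale matrix.
#' @param bg a \code{BackgroundImage} (or plain matrix).
#' @param thr intensity threshold, or \code{"auto"} for Otsu on the
#'   difference image.
#' @param dustRadius attachment radius in px (default 5).
#' @return logical silhouette mask with attributes \code{threshold}.
#' @export
extractSilhouette <- function(frame, bg, thr = "auto", dustRadius = 5L) {
  bgimg <- if (is(bg, "BackgroundImage")) bg@image else bg
  if (!identical(dim(frame), dim(bgimg)))
    stop("frame and background shapes differ")
  d <- abs(frame - bgimg)
  if (identical(thr, "auto")) thr <- otsuThreshold(d)
  mask <- d > thr
  if (!any(mask)) {
    warning("empty silhouette: no pixel exceeds the threshold")
    attr(mask, "threshold") <- thr
    return(mask)
  }
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  main <- which.max(sizes)
  keepZone <- dilateMask(lab == main, dustRadius)
  keepIds <- unique(lab[keepZone & lab > 0L])
  out <- matrix(lab %in% keepIds, nrow(mask), ncol(mask))
  attr(out, "threshold") <- thr
  out
}

# Full-precision numeric formatting so CSV round trips reproduce doubles
# bit-exactly; NAs become empty cells.
.fmtNum <- function(x) {
  s <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17L, format = "g")
  }, character(1L))
  s
}

.writeTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) &
         !vapply(df, is.integer, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- .fmtNum(df[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write all tracking and gait tables to CSV
#'
#' Writes the nine result files: \code{CoM.csv} (per-frame body centroid and
#' axis angle), \code{trajectory.csv} (arena-frame claw positions),
#' \code{norm_trajectory.csv} (body-centred claw positions),
#' \code{bodylength.csv}, \code{bodyvelocity.csv} (instantaneous centroid
#' velocity plus the smoothed gait-index series),
#' \code{StrideParameters.csv}, \code{LegParameters.csv},
#' \code{LegDomainOverlap.csv} and \code{StanceWidth.csv}.
#' All pixel coordinates are 0-based with x = column and y = row from the
#' top-left corner; missing claws are written as empty cells. Numeric values
#' are written with 17 significant digits so a read/write cycle is lossless.
#'
#' @param tracks a \code{TrackSet}.
#' @param report a \code{GaitReport} (from \code{\link{gaitReport}}); pass
#'   \code{NULL} to write only the raw position tables.
#' @param outdir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
writeTrackTables <- function(tracks, report, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output dir ", outdir)
  }
  files <- character(0)
  legs <- tracks@legs
  nf <- dim(tracks@arena)[1L]

  coordDF <- function(a) {
    df <- data.frame(frame = seq_len(nf) - 1L)
    for (j in seq_along(legs)) {
      df[[paste0(legs[j], "_x")]] <- a[, j, 1L]
      df[[paste0(legs[j], "_y")]] <- a[, j, 2L]
    }
    df
  }

  p <- file.path(outdir, "CoM.csv")
  .writeTable(data.frame(frame = seq_len(nf) - 1L,
                         x = tracks@poses$cx, y = tracks@poses$cy,
                         theta_deg = tracks@poses$theta), p)
  files <- c(files, p)

  p <- file.path(outdir, "trajectory.csv")
  .writeTable(coordDF(tracks@arena), p); files <- c(files, p)
  p <- file.path(outdir, "norm_trajectory.csv")
  .writeTable(coordDF(tracks@body), p); files <- c(files, p)

  tb <- if (is.null(report)) list() else report@tables
  emptyDF <- data.frame()
  p <- file.path(outdir, "bodylength.csv")
  .writeTable(if (!is.null(tb$bodyLength)) tb$bodyLength else emptyDF, p)
  files <- c(files, p)
  p <- file.path(outdir, "bodyvelocity.csv")
  .writeTable(if (!is.null(tb$bodyVelocity)) tb$bodyVelocity else emptyDF, p)
  files <- c(files, p)
  p <- file.path(outdir, "StrideParameters.csv")
  .writeTable(if (!is.null(tb$strides)) tb$strides else emptyDF, p)
  files <- c(files, p)
  p <- file.path(outdir, "LegParameters.csv")
  .writeTable(if (!is.null(tb$legs)) tb$legs else emptyDF, p)
  files <- c(files, p)
  p <- file.path(outdir, "LegDomainOverlap.csv")
  .writeTable(if (!is.null(tb$domainOverlap)) tb$domainOverlap else emptyDF, p)
  files <- c(files, p)
  p <- file.path(outdir, "StanceWidth.csv")
  .writeTable(if (!is.null(tb$stanceWidth)) tb$stanceWidth else emptyDF, p)
  files <- c(files, p)
  invisible(files)
}
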