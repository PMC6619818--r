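#' @rdname FrameStack-class
#' @param object,x a \code{FrameStack}
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FrameStack-class
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TrackSet-class
#' @export
setGeneric("legLabels", function(x) standardGeneric("legLabels"))

#' @rdname TrackSet-class
#' @export
setGeneric("arenaTrack", function(x, leg) standardGeneric("arenaTrack"))

#' @rdname TrackSet-class
#' @export
setGeneric("bodyTrack", function(x, leg) standardGeneric("bodyTrack"))

#' @rdname TrackSet-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname GaitReport-class
#' @export
setGeneric("reportTables", function(x) standardGeneric("reportTables"))

#' @export
#' @describeIn FrameStack-class frames as a list of matrices
setMethod("frames", "FrameStack", function(x) x@frames)

#' @export
#' @describeIn FrameStack-class acquisition frame rate (fps)
setMethod("frameRate", "FrameStack", function(x) x@frameRate)

#' @export
#' @describeIn FrameStack-class spatial calibration (mm per pixel)
setMethod("mmPerPx", "FrameStack", function(x) x@mmPerPx)

#' @export
#' @describeIn FrameStack-class number of frames
setMethod("nFrames", "FrameStack", function(x) length(x@frames))

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameStack: %d frames of %d x %d px, %.0f fps, %.5f mm/px\n",
              length(object@frames), d[1L], d[2L],
              object@frameRate, object@mmPerPx))
  if (nzchar(object@sourceDir))
    cat("  source:", object@sourceDir, "\n")
})

setMethod("show", "BackgroundImage", function(object) {
  cat(sprintf("BackgroundImage (%s): %d x %d px\n", object@mode,
              nrow(object@image), ncol(object@image)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TrainingPatchSet", function(object) {
  cat(sprintf("TrainingPatchSet: %d patches (%d x %d), %d positive / %d negative, round %d\n",
              nrow(object@patches), object@patchSize, object@patchSize,
              sum(object@labels > 0), sum(object@labels < 0),
              object@roundIndex))
})

setMethod("show", "KernelBoostClassifier", function(object) {
  cat(sprintf("KernelBoostClassifier: %d weak learners (of %d rounds), gamma = %g\n",
              length(object@learners), object@nRounds, object@gamma))
  if (nrow(object@trainingLog))
    cat(sprintf("  mean training loss: %.4f -> %.4f\n",
                object@trainingLog$loss[1L],
                tail(object@trainingLog$loss, 1L)))
})

#' @export
#' @describeIn TrackSet-class the ordered leg labels
setMethod("legLabels", "TrackSet", function(x) x@legs)

#' @export
#' @describeIn TrackSet-class arena-frame (x, y) positions of one leg over
#'   frames, an nFrames x 2 matrix with NA where the leg is missing
#' @param leg a leg label such as \code{"L1"}
setMethod("arenaTrack", "TrackSet", function(x, leg) {
  j <- match(leg, x@legs)
  if (is.na(j)) stop("unknown leg label: ", leg)
  m <- x@arena[, j, , drop = TRUE]
  colnames(m) <- c("x", "y")
  m
})

#' @export
#' @describeIn TrackSet-class body-frame (x, y) positions of one leg
setMethod("bodyTrack", "TrackSet", function(x, leg) {
  j <- match(leg, x@legs)
  if (is.na(j)) stop("unknown leg label: ", leg)
  m <- x@body[, j, , drop = TRUE]
  colnames(m) <- c("x", "y")
  m
})

#' @export
#' @describeIn TrackSet-class logical nFrames x nLegs matrix of missing flags
setMethod("missingMask", "TrackSet", function(x) x@missing)

setMethod("show", "TrackSet", function(object) {
  nf <- dim(object@arena)[1L]
  pctMiss <- 100 * mean(object@missing)
  cat(sprintf("TrackSet: %d legs (%s) over %d frames\n",
              length(object@legs), paste(object@legs, collapse = ","), nf))
  cat(sprintf("  start frame %d, gate %.1f px, missing %.2f%%\n",
              object@startFrame, object@gatePx, pctMiss))
  if (nrow(object@corrections))
    cat(sprintf("  %d manual corrections applied\n", nrow(object@corrections)))
})

#' @export
#' @describeIn GaitReport-class the named list of result tables
setMethod("reportTables", "GaitReport", function(x) x@tables)

setMethod("show", "GaitReport", function(object) {
  cat(sprintf("GaitReport: body length %.3f mm\n", object@bodyLengthMM))
  cat(sprintf("  tables: %s\n", paste(names(object@tables), collapse = ", ")))
  if (!is.null(object@tables$strides))
    cat(sprintf("  %d stride events\n", nrow(object@tables$strides)))
})
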