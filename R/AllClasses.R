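# Central S4 containers. Pixel coordinate convention used throughout:
# 0-based, origin at the top-left corner, x = column index, y = row index.
# A point (x, y) therefore addresses matrix element [y + 1, x + 1].

#' FrameStack: an ordered grayscale image sequence with acquisition metadata
#'
#' Frames are stored as numeric or integer matrices sharing one shape, with
#' intensities on the native 8-bit scale (0--255). \code{mmPerPx} is derived
#' from the field of view as \code{fovMM / image width}.
#'
#' @slot frames list of same-shaped grayscale matrices, in temporal order.
#' @slot frameRate frames per second (> 0).
#' @slot mmPerPx millimetres per pixel (> 0).
#' @slot sourceDir directory the frames were read from ("" for in-memory
#'   stacks).
#'
#' @seealso \code{\link{loadFrameStack}}, \code{\link{frameStack}}
#' @export
setClass("FrameStack", representation(
  frames   = "list",
  frameRate = "numeric",
  mmPerPx  = "numeric",
  sourceDir = "character"
))

setValidity("FrameStack", function(object) {
  f <- object@frames
  if (length(f) < 1L) return("a FrameStack needs at least one frame")
  d <- dim(f[[1L]])
  if (is.null(d)) return("frames must be matrices")
  for (i in seq_along(f)) {
    if (!identical(dim(f[[i]]), d))
      return(sprintf("frame %d has a different shape from frame 1", i))
  }
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) return("frameRate must be a positive number")
  if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
      object@mmPerPx <= 0) return("mmPerPx must be a positive number")
  rng <- range(f[[1L]], na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 255)
    return("intensities must lie within the 8-bit range [0, 255]")
  TRUE
})

#' BackgroundImage: an animal-free estimate of the arena background
#'
#' @slot image 2-D intensity matrix, same shape as the video frames.
#' @slot mode how the background was obtained: \code{"auto"} (per-pixel
#'   median over sampled frames), \code{"spliced"} (first and last frame
#'   mosaicked along the perpendicular bisector of the two body centroids) or
#'   \code{"loaded"} (user supplied).
#' @slot flags character vector of quality warnings (e.g.
#'   \code{"stationary"} when the animal did not displace enough for the
#'   automatic estimate to be trustworthy).
#'
#' @seealso \code{\link{estimateBackground}}
#' @export
setClass("BackgroundImage", representation(
  image = "matrix",
  mode  = "character",
  flags = "character"
))

setValidity("BackgroundImage", function(object) {
  if (!object@mode %in% c("auto", "spliced", "loaded"))
    return("mode must be one of 'auto', 'spliced', 'loaded'")
  TRUE
})

#' TrainingPatchSet: labeled image patches for classifier training
#'
#' Each row of \code{patches} is one 41 x 41 grayscale patch (flattened
#' column-major, intensities scaled to [0, 1]) centred on a harvested pixel.
#' Labels are +1 for leg and -1 otherwise. Weights and residuals are the
#' per-round boosting quantities; at construction the weights are 1 and the
#' residuals equal the labels.
#'
#' @slot patches numeric matrix, n x patchSize^2.
#' @slot labels numeric vector of +1 / -1.
#' @slot weights positive numeric vector.
#' @slot residuals numeric vector.
#' @slot patchSize side length of the square patch (default 41).
#' @slot roundIndex self-training round the set was built in.
#'
#' @seealso \code{\link{extractPatches}}
#' @export
setClass("TrainingPatchSet", representation(
  patches   = "matrix",
  labels    = "numeric",
  weights   = "numeric",
  residuals = "numeric",
  patchSize = "integer",
  roundIndex = "integer"
))

setValidity("TrainingPatchSet", function(object) {
  n <- nrow(object@patches)
  if (length(object@labels) != n) return("labels must match patch count")
  if (length(object@weights) != n) return("weights must match patch count")
  if (length(object@residuals) != n) return("residuals must match patch count")
  if (!all(object@labels %in% c(-1, 1))) return("labels must be +1 or -1")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (ncol(object@patches) != object@patchSize^2)
    return("patch matrix width must equal patchSize^2")
  TRUE
})

#' KernelBoostClassifier: a boosted forest of kernel-split decision trees
#'
#' Each weak learner is a binary decision tree of depth at most 5 whose
#' internal nodes hold a learned convolution kernel (a 4--19 px square window
#' anchored at a fixed offset inside the patch) and a threshold; leaves hold
#' real-valued responses. The classifier score of a patch is
#' \code{gamma * sum_j h_j(patch)} and is mapped to a leg-confidence value in
#' [0, 1] by the logistic transform \code{1 / (1 + exp(-2 * score))}.
#'
#' @slot learners list of tree structures (see \code{\link{growTree}}).
#' @slot gamma shrinkage factor applied to every weak learner (default 0.1).
#' @slot nRounds number of boosting rounds the forest was fit with.
#' @slot trainingLog data.frame with per-round mean exponential loss.
#' @slot patchSize patch side length the forest was trained on.
#' @slot config snapshot of the training configuration.
#'
#' @seealso \code{\link{fitClassifier}}, \code{\link{predictConfidence}}
#' @export
setClass("KernelBoostClassifier", representation(
  learners   = "list",
  gamma      = "numeric",
  nRounds    = "integer",
  trainingLog = "data.frame",
  patchSize  = "integer",
  config     = "list"
))

setValidity("KernelBoostClassifier", function(object) {
  if (length(object@learners) > object@nRounds)
    return("more learners than boosting rounds")
  if (length(object@gamma) != 1L || !is.finite(object@gamma))
    return("gamma must be a single finite number")
  TRUE
})

#' TrackSet: per-leg, per-frame claw positions
#'
#' Positions are kept both in arena coordinates and in the body-centred frame
#' (centroid at the origin, anterior along +y). Frames where a leg could not
#' be matched are flagged missing and hold NA coordinates.
#'
#' @slot legs leg labels; \code{c("L1","L2","L3","R1","R2","R3")} for a
#'   hexapod, eight labels in arachnid mode. 1 = front, increasing to the
#'   rear.
#' @slot arena numeric array [nFrames, nLegs, 2] of (x, y) arena positions px.
#' @slot body numeric array [nFrames, nLegs, 2] of body-frame positions px.
#' @slot missing logical matrix [nFrames, nLegs].
#' @slot poses data.frame with one row per frame: \code{frame}, centroid
#'   \code{cx}, \code{cy}, axis angle \code{theta} (degrees from the arena
#'   y-axis, in (-90, 90]), \code{flip} (TRUE when the anterior points along
#'   the negative axis direction), and the silhouette extent along
#'   (\code{extent_px}) the body axis.
#' @slot tipSets list (per frame) of candidate tip tables, kept so tracking
#'   can be re-run from a corrected frame without re-segmenting.
#' @slot corrections data.frame log of applied manual corrections.
#' @slot frameRate frames per second.
#' @slot mmPerPx millimetres per pixel.
#' @slot gatePx hard limit on the distance a claw may move between frames.
#' @slot startFrame frame at which tracking was initialized.
#'
#' @seealso \code{\link{trackClaws}}, \code{\link{applyCorrections}}
#' @export
setClass("TrackSet", representation(
  legs       = "character",
  arena      = "array",
  body       = "array",
  missing    = "matrix",
  poses      = "data.frame",
  tipSets    = "list",
  corrections = "data.frame",
  frameRate  = "numeric",
  mmPerPx    = "numeric",
  gatePx     = "numeric",
  startFrame = "integer"
))

setValidity("TrackSet", function(object) {
  nl <- length(object@legs)
  if (dim(object@arena)[2L] != nl) return("arena array does not match legs")
  if (dim(object@body)[2L] != nl) return("body array does not match legs")
  if (ncol(object@missing) != nl) return("missing matrix does not match legs")
  if (dim(object@arena)[3L] != 2L) return("arena array must have 2 coords")
  TRUE
})

#' GaitReport: the full set of computed movement statistics
#'
#' @slot bodyLengthMM median body length over frames, mm.
#' @slot tables named list of data.frames: \code{com} (per-frame centroid and
#'   axis angle), \code{trajectory} and \code{normTrajectory} (per-frame claw
#'   positions, arena and body frame), \code{bodyLength}, \code{bodyVelocity}
#'   (includes the smoothed gait-index series), \code{strides},
#'   \code{legs}, \code{domainOverlap}, \code{stanceWidth}, \code{turns}.
#'
#' @seealso \code{\link{gaitReport}}, \code{\link{writeTrackTables}}
#' @export
setClass("GaitReport", representation(
  bodyLengthMM = "numeric",
  tables       = "list"
))
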