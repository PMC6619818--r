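# Binary-morphology helpers built on EBImage plus compiled thinning and
# labeling. All functions take and return plain logical/integer matrices in
# the package's row/column orientation.

#' Skeletonize a binary mask
#'
#' Iterative thinning to a 1-px-wide, 8-connected skeleton, the discrete
#' analogue of the medial axis. The computation is restricted to the bounding
#' box of the foreground for speed.
#'
#' @param mask logical matrix, TRUE = foreground.
#' @return logical matrix of the same shape holding the skeleton.
#' @export
skeletonizeMask <- function(mask) {
  storage.mode(mask) <- "logical"
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  r0 <- max(1L, min(idx[, 1L]) - 1L); r1 <- min(nrow(mask), max(idx[, 1L]) + 1L)
  c0 <- max(1L, min(idx[, 2L]) - 1L); c1 <- min(ncol(mask), max(idx[, 2L]) + 1L)
  out[r0:r1, c0:c1] <- cpp_thin(mask[r0:r1, c0:c1, drop = FALSE])
  out
}

#' Boundary (edge) pixels of a binary mask
#'
#' The inner morphological gradient: foreground pixels with at least one
#' 8-neighbour in the background. The pipeline is silhouette driven, so edges
#' are taken from the mask geometry rather than from image intensities.
#'
#' @param mask logical matrix.
#' @return logical matrix marking the boundary pixels.
#' @export
maskEdges <- function(mask) {
  m <- mask * 1
  er <- EBImage::erode(m, EBImage::makeBrush(3L, "box"))
  mask & !(er > 0.5)
}

# Binary dilation/erosion with a disc of radius r (r = 1 gives the 3x3 box).
dilateMask <- function(mask, r) {
  if (r <= 0) return(mask)
  b <- if (r == 1) EBImage::makeBrush(3L, "box")
       else EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  EBImage::dilate(mask * 1, b) > 0.5
}

erodeMask <- function(mask, r) {
  if (r <= 0) return(mask)
  b <- if (r == 1) EBImage::makeBrush(3L, "box")
       else EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  EBImage::erode(mask * 1, b) > 0.5
}

# Euclidean distance of each foreground pixel to the nearest background pixel.
distanceToBackground <- function(mask) {
  EBImage::distmap(mask * 1)
}

# 8-connected component labels (integer matrix, 0 = background).
labelComponents <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_label8(mask)
}

# Otsu threshold of an intensity matrix on its native 0..255 scale, computed
# on the 256-bin histogram.
otsuThreshold <- function(img) {
  256 * EBImage::otsu(EBImage::Image(pmin(pmax(img / 255, 0), 1)),
                      range = c(0, 1), levels = 256L)
}

# Count of TRUE 8-neighbours for every pixel of a logical matrix.
neighbourCount8 <- function(mask) {
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  z <- matrix(0L, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + z[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}
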