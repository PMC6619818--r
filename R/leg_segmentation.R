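# Turn a per-pixel confidence map into labeled leg regions.

#' Segment legs from a confidence map
#'
#' Thresholds the map at \code{thr}, labels the surviving pixels with
#' 8-connectivity, and removes components smaller than \code{minSize} pixels
#' (a leg tip spans about 3 px at the default resolution, so the default of
#' 4 keeps tips while dropping speckle). Grouping rectifies small
#' segmentation dropouts: fragments separated by no more than
#' \code{2 * bridgeRadius} px are treated as one leg component (the labeled
#' pixels themselves stay exactly the supra-threshold set).
#'
#' @param conf confidence matrix in [0, 1] (0 outside the silhouette).
#' @param thr classification threshold, default 0.65.
#' @param minSize minimum component area in px.
#' @param bridgeRadius fragment-bridging radius in px (0 disables).
#' @return list of class \code{"LegSegmentation"}: \code{labels} (integer
#'   matrix, 0 = non-leg), \code{sizes} (component pixel counts, named by
#'   label), \code{thr}.
#' @export
segmentLegs <- function(conf, thr = 0.65, minSize = 4L, bridgeRadius = 1L) {
  stopifnot(thr > 0, thr < 1)
  bin <- conf >= thr
  lab <- if (bridgeRadius > 0L) {
    wide <- labelComponents(dilateMask(bin, bridgeRadius))
    wide[!bin] <- 0L
    wide
  } else labelComponents(bin)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < minSize)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel compactly in first-encounter order
    keep <- sort(unique(lab[lab > 0L]))
    if (length(keep)) {
      remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      sizes <- tabulate(lab[lab > 0L])
    } else sizes <- integer(0)
  } else sizes <- integer(0)
  structure(list(labels = lab, sizes = sizes, thr = thr),
            class = "LegSegmentation")
}

#' @export
print.LegSegmentation <- function(x, ...) {
  cat(sprintf("LegSegmentation: %d components at thr %.2f (sizes: %s)\n",
              length(x$sizes), x$thr,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}
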