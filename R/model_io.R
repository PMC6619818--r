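# Portable classifier serialization: one JSON document holding kernels, tree
# topology, thresholds, leaf values, shrinkage and the config snapshot.

.treeToList <- function(node) {
  if (node$leaf) return(list(leaf = TRUE, value = node$value))
  list(leaf = FALSE, tau = node$tau, cost = node$cost,
       s = node$kernel$s, anchor = node$kernel$anchor,
       lambda = node$kernel$lambda,
       kernel = as.vector(node$kernel$weights),
       left = .treeToList(node$left), right = .treeToList(node$right))
}

.treeFromList <- function(x) {
  if (isTRUE(x$leaf)) return(list(leaf = TRUE, value = x$value))
  s <- as.integer(x$s)
  list(leaf = FALSE, tau = x$tau, cost = x$cost,
       kernel = list(weights = matrix(unlist(x$kernel), s, s), s = s,
                     anchor = as.integer(unlist(x$anchor)),
                     lambda = x$lambda),
       left = .treeFromList(x$left), right = .treeFromList(x$right))
}

#' Save / load a boosted classifier
#'
#' The on-disk format is a single JSON document (kernels stored as flat
#' numeric arrays at full precision) so trained models are portable across
#' platforms and sessions.
#'
#' @param clf a \code{KernelBoostClassifier}.
#' @param path file path.
#' @return \code{saveKernelBoost} the path invisibly;
#'   \code{readKernelBoost} the classifier.
#' @export
saveKernelBoost <- function(clf, path) {
  doc <- list(format = "hexgait-kernel-boost", version = 1L,
              gamma = clf@gamma, nRounds = clf@nRounds,
              patchSize = clf@patchSize, config = clf@config,
              trainingLog = clf@trainingLog,
              learners = lapply(clf@learners, .treeToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveKernelBoost
#' @export
readKernelBoost <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "hexgait-kernel-boost"))
    stop("not a serialized kernel-boost classifier: ", path)
  tl <- do.call(rbind, lapply(doc$trainingLog, function(q)
    data.frame(round = q$round, loss = q$loss)))
  new("KernelBoostClassifier",
      learners = lapply(doc$learners, .treeFromList),
      gamma = doc$gamma, nRounds = as.integer(doc$nRounds),
      trainingLog = if (is.null(tl)) data.frame() else tl,
      patchSize = as.integer(doc$patchSize),
      config = doc$config)
}
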