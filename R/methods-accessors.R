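#' @rdname FrameStack-class
#' @aliases frames pixelSize frameRate timestamps nFrames fieldOfView
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname FrameStack-class
setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)

#' @rdname FrameStack-class
setMethod("frameRate", "FrameStack", function(x) x@frameRate)

#' @rdname FrameStack-class
setMethod("timestamps", "FrameStack", function(x) x@timestamps)

#' @rdname FrameStack-class
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname FrameStack-class
#' @details `fieldOfView()` returns the physical extent of the imaged field
#'   in micrometres, `c(x, y) = image dimensions * pixelSize`.
setMethod("fieldOfView", "FrameStack", function(x) {
  d <- dim(x@frames)
  c(x = d[2] * x@pixelSize, y = d[1] * x@pixelSize)
})

#' @rdname FrameStack-class
#' @param i frame indices
setMethod("[", "FrameStack", function(x, i) {
  new("FrameStack", frames = x@frames[, , i, drop = FALSE],
      pixelSize = x@pixelSize, frameRate = x@frameRate,
      timestamps = x@timestamps[i])
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  fov <- fieldOfView(object)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%.0f x %.0f um) @ %g fps\n",
              d[3], d[2], d[1], fov["x"], fov["y"], object@frameRate))
  cat(sprintf("  pixel size %g um/px; time %.1f - %.1f s after transfer\n",
              object@pixelSize, min(object@timestamps), max(object@timestamps)))
})

#' Construct a FrameStack
#'
#' @param frames numeric array `ny x nx x nframes` (a single matrix is
#'   promoted to a one-frame stack), intensities in 0..1.
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second.
#' @param timestamps seconds after transfer; defaults to a regular grid at
#'   `frameRate` starting at `startTime`.
#' @param startTime acquisition start (s after transfer) used when
#'   `timestamps` is missing.
#' @return a [FrameStack-class] object.
#' @examples
#' fs <- frameStack(array(0.8, c(64, 64, 3)), pixelSize = 6.25, frameRate = 2)
#' nFrames(fs)
#' @export
frameStack <- function(frames, pixelSize, frameRate, timestamps = NULL,
                       startTime = 0) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (is.null(timestamps))
    timestamps <- startTime + (seq_len(dim(frames)[3]) - 1) / frameRate
  new("FrameStack", frames = frames, pixelSize = pixelSize,
      frameRate = frameRate, timestamps = timestamps)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d worms, %g s @ %g fps, %d px @ %g um/px, seed %d\n",
              object@nWorms, object@duration, object@frameRate,
              object@imageSize, object@pixelSize, object@rngSeed))
  cat("  speeds (mm/s):",
      paste(sprintf("%s=%g", names(object@speedPerState), object@speedPerState),
            collapse = ", "), "\n")
})

#' @rdname EigenwormBasis-class
#' @aliases eigenworms eigenvalues varianceExplained
#' @param x,object an `EigenwormBasis`
setMethod("eigenworms", "EigenwormBasis", function(x) x@vectors)

#' @rdname EigenwormBasis-class
setMethod("eigenvalues", "EigenwormBasis", function(x) x@values)

#' @rdname EigenwormBasis-class
#' @details `varianceExplained()` returns the cumulative fraction of posture
#'   variance captured by the first m eigenworms.
setMethod("varianceExplained", "EigenwormBasis", function(x) {
  cumsum(x@values) / sum(x@values)
})

setMethod("show", "EigenwormBasis", function(object) {
  ve <- varianceExplained(object)
  cat(sprintf("EigenwormBasis: %d modes from %d postures\n",
              ncol(object@vectors), object@nPostures))
  m <- min(4, length(ve))
  cat("  cumulative variance explained:",
      paste(sprintf("%d: %.3f", seq_len(m), ve[seq_len(m)]), collapse = "  "), "\n")
})

#' @rdname PostureLibrary-class
#' @aliases centroids mirrorPairs postureClasses nClasses classRepresentatives
#' @param x,object a `PostureLibrary`
setMethod("centroids", "PostureLibrary", function(x) x@centroids)

#' @rdname PostureLibrary-class
setMethod("mirrorPairs", "PostureLibrary", function(x) x@pairMap)

#' @rdname PostureLibrary-class
setMethod("postureClasses", "PostureLibrary", function(x) x@classId)

#' @rdname PostureLibrary-class
setMethod("nClasses", "PostureLibrary", function(x) {
  if (length(x@classId)) max(x@classId) else 0L
})

#' @rdname PostureLibrary-class
#' @details `classRepresentatives()` returns one sign-canonical angle vector
#'   per merged class: the count-weighted mean of the pair's centroids after
#'   aligning the partner to the first member's orientation (negating it),
#'   then flipped so the summed angle is non-negative. Used for meta-posture
#'   clustering.
setMethod("classRepresentatives", "PostureLibrary", function(x) {
  k <- nrow(x@centroids)
  ids <- sort(unique(x@classId))
  reps <- matrix(0, length(ids), ncol(x@centroids))
  for (j in seq_along(ids)) {
    members <- which(x@classId == ids[j])
    ref <- members[1]
    v <- x@counts[ref] * x@centroids[ref, ]
    w <- x@counts[ref]
    for (m in setdiff(members, ref)) {       # mirror partner: align by negation
      v <- v + x@counts[m] * (-x@centroids[m, ])
      w <- w + x@counts[m]
    }
    v <- v / w
    if (sum(v) < 0) v <- -v
    reps[j, ] <- v
  }
  rownames(reps) <- ids
  reps
})

setMethod("show", "PostureLibrary", function(object) {
  cat(sprintf("PostureLibrary '%s': %d centroids -> %d merged classes (%d mirror pairs)\n",
              object@condition, nrow(object@centroids), nClasses(object),
              sum(object@pairMap != seq_along(object@pairMap)) / 2))
})

setMethod("show", "MetaPostureGroups", function(object) {
  cat(sprintf("MetaPostureGroups: %d posture classes in %d groups (%s)\n",
              length(object@group), nrow(object@centers),
              paste(tabulate(object@group, nrow(object@centers)), collapse = "/")))
})

setMethod("show", "TurnClassifier", function(object) {
  cat(sprintf("TurnClassifier: random forest, %d trees, seed %d\n",
              object@nTrees, object@seed))
  cat(sprintf("  held-out accuracy %.3f; score threshold %.2f\n",
              object@heldOutAccuracy, object@threshold))
})
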