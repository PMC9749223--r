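#' @import methods
#' @importFrom stats approx cov kmeans mad median na.omit quantile rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

#' Simulation configuration for synthetic plate timelapses
#'
#' Holds every parameter of the synthetic plate simulator: acquisition
#' geometry (image size, pixel calibration, frame rate), worm geometry,
#' rendering contrast, the three-state locomotion model
#' (quiescent / dispersal / dwelling) with per-second transition rates,
#' state-dependent speeds and heading persistence, sinusoidal bend-mode
#' amplitudes, turn probability, and the RNG seed. Construct with
#' [simConfig()], which supplies defaults matching a standard plate
#' acquisition (1024 px at 6.25 um/px, 2 fps).
#'
#' @slot imageSize integer, pixels per (square) image side.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot frameRate numeric, frames per second.
#' @slot nWorms integer, number of simulated worms.
#' @slot duration numeric, simulated seconds.
#' @slot wormLength numeric, body length in pixels (>= 26 so that valid
#'   skeletons exist).
#' @slot wormWidth numeric, body width in pixels.
#' @slot backgroundLevel numeric, background intensity on a 0..1 scale.
#' @slot noiseSd numeric, additive Gaussian noise standard deviation.
#' @slot contrast numeric, intensity drop of worm pixels below background.
#' @slot transitionRates 3x3 numeric matrix of per-second transition
#'   probabilities between the named states (rows = from, cols = to);
#'   diagonal is ignored and rebuilt as the complement.
#' @slot speedPerState named numeric, centroid speed per state in mm/s.
#' @slot headingPersistence named numeric in `[0, 1]`; 1 = perfectly straight
#'   heading, lower values add per-frame heading diffusion.
#' @slot bendModeAmplitudes numeric, amplitudes (radians) of the two
#'   sinusoidal spatial bend modes.
#' @slot bendScalePerState named numeric, state-dependent multiplier of the
#'   bend amplitudes ("dauer-stiff" states use low values).
#' @slot waveSpeed numeric, phase advance of the travelling locomotion wave
#'   in radians per second while the worm is moving.
#' @slot turnProbability numeric, per-second probability of initiating a
#'   self-overlapping turn while dwelling.
#' @slot turnDuration numeric, seconds a scripted turn lasts.
#' @slot stateSchedule `NULL` or a data.frame with columns `time` (s) and
#'   `state`; when given, it overrides the Markov chain and forces every
#'   worm into the scheduled state from that time onward.
#' @slot startTime numeric, acquisition start in seconds after transfer
#'   (the h.a.t. origin).
#' @slot rngSeed integer seed making the simulation deterministic.
#' @seealso [simulatePlate()]
#' @export
setClass("SimConfig",
  representation(
    imageSize = "integer", pixelSize = "numeric", frameRate = "numeric",
    nWorms = "integer", duration = "numeric",
    wormLength = "numeric", wormWidth = "numeric",
    backgroundLevel = "numeric", noiseSd = "numeric", contrast = "numeric",
    transitionRates = "matrix", speedPerState = "numeric",
    headingPersistence = "numeric", bendModeAmplitudes = "numeric",
    bendScalePerState = "numeric", waveSpeed = "numeric",
    turnProbability = "numeric", turnDuration = "numeric",
    stateSchedule = "ANY", startTime = "numeric", rngSeed = "integer"
  )
)

.simStates <- c("quiescent", "dispersal", "dwelling")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@imageSize <= 0) msg <- c(msg, "imageSize must be > 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nWorms < 0) msg <- c(msg, "nWorms must be >= 0")
  if (object@wormLength < 26)
    msg <- c(msg, "wormLength must be >= 26 px so valid skeletons exist")
  if (object@wormLength >= object@imageSize)
    msg <- c(msg, "wormLength must be smaller than imageSize")
  if (any(object@transitionRates < 0) || object@turnProbability < 0)
    msg <- c(msg, "all rates must be >= 0")
  if (!identical(dim(object@transitionRates), c(3L, 3L)))
    msg <- c(msg, "transitionRates must be a 3x3 matrix")
  for (s in list(object@speedPerState, object@headingPersistence,
                 object@bendScalePerState)) {
    if (!all(.simStates %in% names(s)))
      msg <- c(msg, "per-state parameters must be named quiescent/dispersal/dwelling")
  }
  if (any(object@speedPerState < 0)) msg <- c(msg, "speeds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Calibrated grayscale frame sequence
#'
#' A stack of equally sized grayscale frames together with the spatial
#' calibration (um/px), temporal calibration (frames/s) and per-frame
#' acquisition timestamps in seconds after transfer to the assay plate
#' (the h.a.t. time origin).
#'
#' @slot frames numeric array `ny x nx x nframes`, intensities on a 0..1
#'   scale.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot frameRate numeric, frames per second.
#' @slot timestamps numeric vector, seconds after transfer, strictly
#'   increasing, one per frame.
#' @seealso [frameStack()], [readFrames()], [simulatePlate()]
#' @export
setClass("FrameStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameRate = "numeric", timestamps = "numeric"))

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a ny x nx x nframes array")
  else if (length(object@timestamps) != d[3])
    msg <- c(msg, "one timestamp per frame required")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Eigenworm basis of posture space
#'
#' Eigendecomposition of the covariance matrix of 24-dimensional
#' intersegment-angle posture vectors. Columns of the basis are the
#' eigenworms (principal bend modes), unit norm, ordered by decreasing
#' eigenvalue.
#'
#' @slot vectors numeric matrix (24 x m), orthonormal columns.
#' @slot values numeric, non-increasing eigenvalues.
#' @slot center numeric(24), the mean posture removed before decomposition.
#' @slot nPostures integer, number of posture vectors used.
#' @seealso [computeEigenworms()]
#' @export
setClass("EigenwormBasis",
  representation(vectors = "matrix", values = "numeric",
                 center = "numeric", nPostures = "integer"))

setValidity("EigenwormBasis", function(object) {
  msg <- character()
  if (length(object@values) != ncol(object@vectors))
    msg <- c(msg, "one eigenvalue per eigenvector required")
  if (is.unsorted(-object@values)) msg <- c(msg, "eigenvalues must be non-increasing")
  g <- crossprod(object@vectors)
  if (ncol(g) > 0 && max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "eigenvectors must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Posture library: clustered posture dictionary with mirror merging
#'
#' k-means centroids of posture vectors for one experimental condition
#' (pooled across repeats), the mirror-pair map identifying centroid pairs
#' that are negations of each other (left/right reflections of the same
#' body shape), and the merged posture classes obtained by treating each
#' mirror pair as a single posture.
#'
#' @slot condition character condition label.
#' @slot centroids numeric matrix (k x 24) of cluster centroids.
#' @slot pairMap integer(k); `pairMap[i]` is the index of centroid i's
#'   mirror partner, or `i` itself when unpaired.
#' @slot classId integer(k); merged class index of each centroid.
#' @slot counts integer(k); number of training postures per centroid.
#' @slot seed integer seed used for clustering.
#' @seealso [buildPostureLibrary()], [findMirrorPairs()]
#' @export
setClass("PostureLibrary",
  representation(condition = "character", centroids = "matrix",
                 pairMap = "integer", classId = "integer",
                 counts = "integer", seed = "integer"))

setValidity("PostureLibrary", function(object) {
  k <- nrow(object@centroids)
  msg <- character()
  if (length(object@pairMap) != k || length(object@classId) != k ||
      length(object@counts) != k)
    msg <- c(msg, "pairMap, classId and counts must have one entry per centroid")
  if (k > 0) {
    if (any(object@pairMap < 1 | object@pairMap > k))
      msg <- c(msg, "pairMap indices out of range")
    if (any(object@pairMap[object@pairMap] != seq_len(k)))
      msg <- c(msg, "pairMap must be an involution (mutual pairs)")
    if (any(object@classId[object@pairMap] != object@classId))
      msg <- c(msg, "mirror partners must share a class")
    if (max(object@classId) > k) msg <- c(msg, "class count cannot exceed k")
  }
  if (length(msg)) msg else TRUE
})

#' Meta-posture grouping of a pooled posture library
#'
#' Assignment of every merged posture class (pooled across conditions) to
#' one of three coarse groups obtained by a second k-means clustering;
#' group 1..3 typically separate low-, medium- and high-curvature postures.
#'
#' @slot group integer, group index (1..k) of each pooled posture class.
#' @slot centers numeric matrix (k x 24), group mean angle vectors.
#' @slot representatives numeric matrix, the class-representative angle
#'   vectors that were clustered.
#' @slot condition character, condition label of each pooled class.
#' @seealso [assignMetaPostures()]
#' @export
setClass("MetaPostureGroups",
  representation(group = "integer", centers = "matrix",
                 representatives = "matrix", condition = "character"))

setValidity("MetaPostureGroups", function(object) {
  msg <- character()
  if (length(object@group) != nrow(object@representatives))
    msg <- c(msg, "one group per representative required")
  if (length(object@group) && !all(object@group %in% seq_len(nrow(object@centers))))
    msg <- c(msg, "group indices must point into centers")
  if (length(msg)) msg else TRUE
})

#' Random-forest turn classifier
#'
#' A seeded random forest trained on 17 shape descriptors of segmented worm
#' bitmasks to detect self-overlapping turn postures (omega/U shapes), which
#' defeat skeletonization and are therefore invisible to posture analysis.
#'
#' @slot model the fitted `randomForest` object.
#' @slot featureNames character(17), feature order expected at prediction.
#' @slot nTrees integer, forest size.
#' @slot seed integer, training seed.
#' @slot heldOutAccuracy numeric, accuracy on the internal stratified
#'   held-out split.
#' @slot threshold numeric, score threshold for flagging a turn.
#' @seealso [trainTurnClassifier()], [predictTurns()]
#' @export
setClass("TurnClassifier",
  representation(model = "ANY", featureNames = "character",
                 nTrees = "integer", seed = "integer",
                 heldOutAccuracy = "numeric", threshold = "numeric"))

setValidity("TurnClassifier", function(object) {
  if (length(object@featureNames) != 17L)
    "feature vector length must be 17" else TRUE
})
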