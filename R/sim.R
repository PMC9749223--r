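# Synthetic plate-timelapse simulator with full ground truth.
#
# Worms are modeled as inextensible midlines of 26 equally spaced points
# whose tangent-angle profile is a sum of two sinusoidal spatial bend modes
# with a travelling phase (the locomotion wave). The centroid follows a
# state-dependent speed / heading-persistence random walk driven by a
# three-state Markov chain (quiescent, dispersal, dwelling); scripted turns
# overlay a large uniform-curvature bend that produces self-overlapping
# omega/U shapes. Frames render worms as dark thick curves on a bright
# noisy background, emulating transmitted illumination from below.

#' Build a simulation configuration
#'
#' Defaults emulate the standard acquisition geometry (1024 px at
#' 6.25 um/px, 2 fps after downsampling) and a behavioral repertoire whose
#' state kinematics straddle the dispersal thresholds (0.01 mm/s, 15 deg/s):
#' dispersal moves fast and straight, dwelling slow with frequent
#' reorientation, quiescence barely at all. Bend amplitudes are scaled down
#' in quiescent/dispersal states to emulate the stiff, low-curvature dauer
#' posture.
#'
#' @param imageSize pixels per image side.
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second.
#' @param nWorms number of worms.
#' @param duration simulated seconds.
#' @param wormLength,wormWidth body dimensions in pixels.
#' @param backgroundLevel,noiseSd,contrast rendering intensities (0..1
#'   scale); default contrast is 15x the noise sd.
#' @param transitionRates 3x3 per-second transition probability matrix
#'   (rows from, cols to, order quiescent/dispersal/dwelling).
#' @param speedPerState named centroid speeds in mm/s.
#' @param headingPersistence named values in `[0, 1]`.
#' @param bendModeAmplitudes amplitudes (rad) of the two spatial bend modes.
#' @param bendScalePerState named multipliers of the bend amplitudes.
#' @param waveSpeed locomotion-wave phase speed, rad/s.
#' @param turnProbability per-second probability of starting a turn while
#'   dwelling.
#' @param turnDuration seconds per turn.
#' @param stateSchedule `NULL`, or data.frame(time, state) forcing all worms
#'   into the given state from `time` (s) onward (overrides the Markov
#'   chain) -- used to script behavioral switches with a known time.
#' @param startTime acquisition start, seconds after transfer.
#' @param rngSeed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(imageSize = 256, nWorms = 2, duration = 10, rngSeed = 1)
#' cfg
#' @export
simConfig <- function(imageSize = 1024, pixelSize = 6.25, frameRate = 2,
                      nWorms = 10, duration = 60,
                      wormLength = 60, wormWidth = 5,
                      backgroundLevel = 0.75, noiseSd = 0.02,
                      contrast = 15 * noiseSd,
                      transitionRates = defaultTransitionRates(),
                      speedPerState = c(quiescent = 0.0005,
                                        dispersal = 0.03,
                                        dwelling = 0.008),
                      headingPersistence = c(quiescent = 0.9,
                                             dispersal = 0.985,
                                             dwelling = 0.88),
                      bendModeAmplitudes = c(0.55, 0.35),
                      bendScalePerState = c(quiescent = 0.4,
                                            dispersal = 0.5,
                                            dwelling = 1.0),
                      waveSpeed = 2.5, turnProbability = 0.02,
                      turnDuration = 3,
                      stateSchedule = NULL, startTime = 0, rngSeed = 1L) {
  new("SimConfig",
      imageSize = as.integer(imageSize), pixelSize = pixelSize,
      frameRate = frameRate, nWorms = as.integer(nWorms), duration = duration,
      wormLength = wormLength, wormWidth = wormWidth,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      contrast = contrast, transitionRates = transitionRates,
      speedPerState = speedPerState[.simStates],
      headingPersistence = headingPersistence[.simStates],
      bendModeAmplitudes = bendModeAmplitudes,
      bendScalePerState = bendScalePerState[.simStates],
      waveSpeed = waveSpeed, turnProbability = turnProbability,
      turnDuration = turnDuration, stateSchedule = stateSchedule,
      startTime = startTime, rngSeed = as.integer(rngSeed))
}

#' @rdname simConfig
#' @details `defaultTransitionRates()` returns slow switching (mean state
#'   dwell times of minutes) so that 10-s kinematics bins are usually pure.
#' @export
defaultTransitionRates <- function() {
  m <- matrix(c(0,     0.008, 0.002,
                0.002, 0,     0.004,
                0.002, 0.004, 0), 3, 3, byrow = TRUE,
              dimnames = list(.simStates, .simStates))
  m
}

# per-frame state transition matrix P = I + Q*dt
.stepMatrix <- function(rates, dt) {
  P <- rates * dt
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  if (any(diag(P) < 0)) stop("transition rates too large for this frame rate")
  P
}

#' Stationary distribution of the simulator's state chain
#'
#' @param config a [SimConfig-class] (or a 3x3 rate matrix).
#' @return named numeric(3) stationary occupancy probabilities.
#' @export
stationaryDistribution <- function(config) {
  rates <- if (is(config, "SimConfig")) config@transitionRates else config
  P <- .stepMatrix(rates, 1)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  setNames(v / sum(v), .simStates)
}

#' Simulate a state-label sequence from the locomotion Markov chain
#'
#' Exposes the simulator's behavioral-state chain on its own, e.g. to check
#' long-run occupancy against [stationaryDistribution()].
#'
#' @param config a [SimConfig-class].
#' @param nSteps number of frames to simulate.
#' @param seed RNG seed.
#' @return character vector of state labels.
#' @export
simulateStateSequence <- function(config, nSteps, seed = config@rngSeed) {
  set.seed(seed)
  P <- .stepMatrix(config@transitionRates, 1 / config@frameRate)
  out <- character(nSteps)
  s <- sample.int(3, 1, prob = stationaryDistribution(config))
  for (t in seq_len(nSteps)) {
    out[t] <- .simStates[s]
    s <- sample.int(3, 1, prob = P[s, ])
  }
  out
}

# tangent-angle bend profile at 25 chord positions
.bendProfile <- function(amplitudes, scale, phase, turnBend = 0) {
  u <- (seq_len(25) - 0.5) / 25
  b <- scale * (amplitudes[1] * sin(2 * pi * 1.5 * u + phase) +
                amplitudes[2] * sin(2 * pi * 2.5 * u + 1.7 * phase))
  b <- b - mean(b)
  b + turnBend * (u - 0.5)
}

# 26-point midline (head first) with centroid at `center`
.midlineFromBend <- function(center, heading, bend, wormLength) {
  alpha <- heading + pi + bend          # chord directions, head -> tail
  ds <- wormLength / 25
  x <- c(0, cumsum(ds * cos(alpha)))
  y <- c(0, cumsum(ds * sin(alpha)))
  cbind(x = x - mean(x) + center[1], y = y - mean(y) + center[2])
}

# rasterize a thick curve: pixels within width/2 of the midline polyline
.renderMidline <- function(canvas, midline, width, value) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  r <- width / 2
  x0 <- max(1L, floor(min(midline[, 1]) - r)); x1 <- min(nx, ceiling(max(midline[, 1]) + r))
  y0 <- max(1L, floor(min(midline[, 2]) - r)); y1 <- min(ny, ceiling(max(midline[, 2]) + r))
  if (x0 > x1 || y0 > y1) return(canvas)  # fully off-field
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  dmin <- rep(Inf, length(gx))
  for (i in seq_len(nrow(midline) - 1)) {
    a <- midline[i, ]; b <- midline[i + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / L2))
    dmin <- pmin(dmin, (gx - a[1] - t * ab[1])^2 + (gy - a[2] - t * ab[2])^2)
  }
  inside <- dmin <= r^2
  idx <- gy[inside] + (gx[inside] - 1L) * ny
  canvas[idx] <- pmin(canvas[idx], value)
  canvas
}

#' Simulate a plate timelapse with ground truth
#'
#' Runs the worm model forward and (optionally) renders frames. Ground truth
#' records, per frame and worm, the centroid, the 26-point midline (head to
#' tail), the behavioral state label and the 24 intersegment angles
#' recomputed from the stored midline. Worms whose trajectory leaves the
#' field keep evolving off-screen and are flagged `visible = FALSE` when any
#' midline point falls outside the image.
#'
#' @param config a [SimConfig-class].
#' @param render if `FALSE`, skip rasterization and return only ground truth
#'   (fast; useful for long kinematics-level simulations).
#' @return a list with elements `frames` (a [FrameStack-class], or `NULL`
#'   when `render = FALSE`), `truth` (data.frame: frame, time, worm, x, y,
#'   state, visible, mx1..mx26, my1..my26, a1..a24), `background` (the
#'   noise-free background image) and `config`.
#' @examples
#' sim <- simulatePlate(simConfig(imageSize = 128, nWorms = 1, duration = 5,
#'                                wormLength = 30, rngSeed = 7))
#' dim(frames(sim$frames))
#' @export
simulatePlate <- function(config, render = TRUE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@rngSeed)
  dt <- 1 / config@frameRate
  nF <- max(1L, round(config@duration * config@frameRate))
  n <- config@nWorms
  sz <- config@imageSize
  pxmm <- config@pixelSize / 1000            # mm per px
  P <- .stepMatrix(config@transitionRates, dt)
  sched <- config@stateSchedule
  background <- matrix(config@backgroundLevel, sz, sz)

  # per-worm state
  margin <- config@wormLength
  cx <- runif(n, 1 + margin, sz - margin)
  cy <- runif(n, 1 + margin, sz - margin)
  heading <- runif(n, -pi, pi)
  phase <- runif(n, -pi, pi)
  stateIdx <- if (n) sample.int(3, n, replace = TRUE,
                                prob = stationaryDistribution(config)) else integer()
  turnLeft <- numeric(n)                     # remaining turn seconds
  turnSign <- rep(1, n)

  framesArr <- if (render) array(0, c(sz, sz, nF)) else NULL
  numCols <- c("frame", "time", "worm", "x", "y", "visible",
               paste0("mx", 1:26), paste0("my", 1:26), paste0("a", 1:24))
  M <- matrix(NA_real_, nF * n, length(numCols),
              dimnames = list(NULL, numCols))
  stateLab <- character(nF * n)

  for (f in seq_len(nF)) {
    tNow <- (f - 1) * dt
    if (render) canvas <- background + matrix(rnorm(sz * sz, 0, config@noiseSd), sz, sz)
    for (w in seq_len(n)) {
      if (!is.null(sched)) {
        idx <- max(which(sched$time <= tNow), 1)
        stateIdx[w] <- match(sched$state[idx], .simStates)
      }
      st <- .simStates[stateIdx[w]]
      inTurn <- turnLeft[w] > 0
      label <- if (inTurn) "turn" else st

      sp <- config@speedPerState[st] / pxmm * dt     # px per frame
      if (inTurn) sp <- sp * 0.3
      pers <- config@headingPersistence[st]
      heading[w] <- wrapAngle(heading[w] + rnorm(1, 0, (1 - pers) * pi))
      cx[w] <- cx[w] + sp * cos(heading[w])
      cy[w] <- cy[w] + sp * sin(heading[w])
      if (sp > 0.05) phase[w] <- wrapAngle(phase[w] + config@waveSpeed * dt)

      turnBend <- 0
      if (inTurn) {
        prog <- 1 - turnLeft[w] / config@turnDuration
        turnBend <- turnSign[w] * (2 * pi) * sin(pi * prog)
        turnLeft[w] <- turnLeft[w] - dt
      } else if (st == "dwelling" &&
                 runif(1) < config@turnProbability * dt) {
        turnLeft[w] <- config@turnDuration
        turnSign[w] <- sample(c(-1, 1), 1)
      }

      bend <- .bendProfile(config@bendModeAmplitudes,
                           config@bendScalePerState[st], phase[w], turnBend)
      ml <- .midlineFromBend(c(cx[w], cy[w]), heading[w], bend,
                             config@wormLength)
      visible <- all(ml[, 1] >= 1 & ml[, 1] <= sz & ml[, 2] >= 1 & ml[, 2] <= sz)
      if (render)
        canvas <- .renderMidline(canvas, ml, config@wormWidth,
                                 config@backgroundLevel - config@contrast)
      ang <- chordAngles(ml)
      r <- (f - 1L) * n + w
      M[r, ] <- c(f, config@startTime + tNow, w, cx[w], cy[w],
                  visible, ml[, 1], ml[, 2], ang)
      stateLab[r] <- label

      # Markov step (skipped when a schedule pins the state)
      if (is.null(sched) && !inTurn)
        stateIdx[w] <- sample.int(3, 1, prob = P[stateIdx[w], ])
    }
    if (render) framesArr[, , f] <- pmin(pmax(canvas, 0), 1)
  }

  truthDf <- as.data.frame(M)
  truthDf$state <- stateLab
  truthDf$visible <- as.logical(truthDf$visible)
  truthDf <- truthDf[, c("frame", "time", "worm", "x", "y", "state",
                         "visible", paste0("mx", 1:26), paste0("my", 1:26),
                         paste0("a", 1:24))]
  fs <- if (render)
    frameStack(framesArr, pixelSize = config@pixelSize,
               frameRate = config@frameRate,
               startTime = config@startTime) else NULL
  list(frames = fs, truth = truthDf, background = background, config = config)
}

#' Render a standalone worm shape from a bend profile and label it
#'
#' Builds a midline whose chord directions follow the given tangent-angle
#' profile, rasterizes it as a filled thick curve, and applies the turn
#' annotation rule: the shape is a turn when the head or tail touches the
#' rest of the body, or when head and tail point in the same direction
#' (U-shape). Used to build labeled training sets for the turn classifier.
#'
#' @param bendProfile numeric vector of tangent angles (radians) along the
#'   body; resampled to the 25 chord positions. A single number is treated
#'   as a total bend spread uniformly along the body.
#' @param wormLength,wormWidth body dimensions in pixels.
#' @return list with `mask` (logical matrix), `turn` (logical label),
#'   `midline` (26 x 2 matrix).
#' @examples
#' omega <- renderTurnShape(2 * pi)      # 360 degree bend
#' omega$turn
#' straight <- renderTurnShape(0)
#' straight$turn
#' @export
renderTurnShape <- function(bendProfile, wormLength = 60, wormWidth = 5) {
  if (length(bendProfile) == 1) {
    u <- (seq_len(25) - 0.5) / 25
    bendProfile <- bendProfile * (u - 0.5)
  } else if (length(bendProfile) != 25) {
    bendProfile <- approx(seq_along(bendProfile), bendProfile,
                          xout = seq(1, length(bendProfile), length.out = 25))$y
  }
  ml <- .midlineFromBend(c(0, 0), 0, bendProfile - mean(bendProfile), wormLength)
  pad <- wormWidth + 2
  ml[, 1] <- ml[, 1] - min(ml[, 1]) + pad
  ml[, 2] <- ml[, 2] - min(ml[, 2]) + pad
  nx <- ceiling(max(ml[, 1])) + pad
  ny <- ceiling(max(ml[, 2])) + pad
  canvas <- matrix(1, ny, nx)
  canvas <- .renderMidline(canvas, ml, wormWidth, 0)
  mask <- canvas == 0

  # annotation rule: self-contact of an end with the body, or U-shape
  endContact <- function(endIdx) {
    p <- ml[endIdx, ]
    arcSep <- abs(seq_len(26) - endIdx) * (wormLength / 25)
    far <- which(arcSep > 3 * wormWidth)
    if (!length(far)) return(FALSE)
    min(sqrt((ml[far, 1] - p[1])^2 + (ml[far, 2] - p[2])^2)) <= wormWidth
  }
  outHead <- ml[1, ] - ml[2, ]
  outTail <- ml[26, ] - ml[25, ]
  uShape <- sum(outHead * outTail) /
    (sqrt(sum(outHead^2)) * sqrt(sum(outTail^2))) >= cos(pi / 4)
  list(mask = mask, turn = endContact(1) || endContact(26) || uShape,
       midline = ml)
}

#' Generate a labeled set of turn / non-turn worm shapes
#'
#' Samples total body bends spanning straight through omega shapes, renders
#' each with [renderTurnShape()] (plus small bend-mode wiggles), and labels
#' it by the geometric annotation rule. Sampling continues until the
#' requested number of shapes per class is reached.
#'
#' @param nTurn,nNonTurn shapes per class.
#' @param wormLength,wormWidth body dimensions in pixels.
#' @param seed RNG seed.
#' @return list with `masks` (list of logical matrices) and `turn`
#'   (logical vector).
#' @export
makeTurnShapeSet <- function(nTurn = 500, nNonTurn = 500,
                             wormLength = 60, wormWidth = 5, seed = 1L) {
  set.seed(seed)
  masks <- list(); labels <- logical()
  want <- function() sum(labels) < nTurn || sum(!labels) < nNonTurn
  while (want()) {
    total <- runif(1, 0, 2.2 * pi) * sample(c(-1, 1), 1)
    u <- (seq_len(25) - 0.5) / 25
    prof <- total * (u - 0.5) +
      runif(1, 0, 0.3) * sin(2 * pi * runif(1, 1, 2.5) * u + runif(1, -pi, pi))
    sh <- renderTurnShape(prof, wormLength, wormWidth)
    if ((sh$turn && sum(labels) < nTurn) || (!sh$turn && sum(!labels) < nNonTurn)) {
      masks[[length(masks) + 1L]] <- sh$mask
      labels <- c(labels, sh$turn)
    }
  }
  list(masks = masks, turn = labels)
}

#' Convert simulator ground truth into the tracking table format
#'
#' Turns the per-frame, per-worm ground-truth centroids into the same
#' detection/track table produced by [linkTracks()], with the true worm
#' identity as the track id. This lets kinematics and behavior stages run
#' directly on noiseless simulator output.
#'
#' @param truth ground-truth data.frame from [simulatePlate()].
#' @return data.frame with columns track_id, frame, x, y, area.
#' @export
groundTruthTracks <- function(truth) {
  data.frame(track_id = truth$worm, frame = truth$frame,
             x = truth$x, y = truth$y, area = NA_real_)
}
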