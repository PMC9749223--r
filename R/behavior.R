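# Behavioral-state classification and turn detection.

#' Classify dispersal behavior from bin kinematics
#'
#' Dispersal is fast, straight locomotion: a 10-s kinematics bin is
#' classified dispersal when its speed is at least 0.01 mm/s and its
#' angular velocity is below 15 deg/s ("minimum speed" read as inclusive,
#' "below" as strict). Everything else is non-dispersal.
#'
#' @param speed speed in mm/s (vectorized).
#' @param angvel angular velocity in deg/s.
#' @param minSpeed dispersal speed floor (mm/s).
#' @param maxAngvel dispersal angular-velocity ceiling (deg/s).
#' @return character vector, `"dispersal"` or `"non_dispersal"`.
#' @examples
#' classifyDispersal(c(0.02, 0.005, 0.02), c(5, 5, 20))
#' @export
classifyDispersal <- function(speed, angvel, minSpeed = 0.01,
                              maxAngvel = 15) {
  ifelse(speed >= minSpeed & angvel < maxAngvel,
         "dispersal", "non_dispersal")
}

#' Flag quiescent bins
#'
#' Quiescence is reported descriptively as locomotion below the dispersal
#' speed floor.
#'
#' @inheritParams classifyDispersal
#' @return logical vector.
#' @export
isQuiescent <- function(speed, minSpeed = 0.01) speed < minSpeed

#' Two-dimensional speed / angular-velocity probability histogram
#'
#' Normalized 2D histogram of per-bin kinematics over a fixed grid; total
#' mass sums to 1. Values beyond the last break are clamped into the final
#' cell so no bin is lost.
#'
#' @param speed,angvel per-bin kinematics.
#' @param speedBreaks,angvelBreaks ascending cell edges.
#' @return list with `density` (speed cells x angvel cells, sums to 1),
#'   `speedBreaks`, `angvelBreaks`.
#' @export
speedAngvelDensity <- function(speed, angvel,
                               speedBreaks = seq(0, 0.05, by = 0.0025),
                               angvelBreaks = seq(0, 100, by = 5)) {
  if (!length(speed)) stop("need at least one kinematics bin")
  clamp <- function(x, br) pmin(pmax(x, br[1]), br[length(br)])
  si <- cut(clamp(speed, speedBreaks), speedBreaks, include.lowest = TRUE)
  ai <- cut(clamp(angvel, angvelBreaks), angvelBreaks, include.lowest = TRUE)
  h <- table(si, ai)
  list(density = unclass(h / sum(h)), speedBreaks = speedBreaks,
       angvelBreaks = angvelBreaks)
}

.turnFeatureNames <- c(
  "area", "perimeter", "areaPerim2", "majorAxis", "minorAxis",
  "eccentricity", "solidity", "extent", "hullBoxRatio",
  "nSkeletonEndpoints", "skeletonLength", "endToEndRatio",
  "maxConvexityDefect", "bboxAspect", "hu1", "hu2", "meanDistanceTransform")

#' Extract 17 shape descriptors from a worm bitmask
#'
#' A fixed, documented set of region descriptors chosen to separate
#' elongated crawling shapes from self-contacting turn shapes (omega/U):
#' area; perimeter; area/perimeter^2; major and minor axis lengths;
#' eccentricity; solidity (area / convex hull area); extent (area /
#' bounding-box area); hull-to-bounding-box area ratio; number of skeleton
#' endpoints; skeleton length; endpoint-to-endpoint distance over skeleton
#' length; maximum convexity-defect depth; bounding-box aspect ratio; Hu
#' moments 1 and 2; and mean distance-transform value. All values are
#' finite for any non-empty mask.
#'
#' @param mask logical or 0/1 matrix containing one connected component.
#' @return named numeric(17).
#' @export
extractTurnFeatures <- function(mask) {
  if (!any(mask)) stop("empty mask")
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  idx <- which(m == 1L)
  yy <- (idx - 1) %% nrow(m) + 1
  xx <- (idx - 1) %/% nrow(m) + 1
  area <- length(idx)

  # perimeter: foreground pixels with at least one 4-neighbor background
  nb4 <- .shift(m, -1, 0) + .shift(m, 1, 0) + .shift(m, 0, -1) + .shift(m, 0, 1)
  perimeter <- max(sum(m == 1L & nb4 < 4L), 1L)

  # second-order central moments -> axes, eccentricity, Hu moments
  mx <- mean(xx); my <- mean(yy)
  mu20 <- mean((xx - mx)^2) + 1 / 12    # pixel-extent correction
  mu02 <- mean((yy - my)^2) + 1 / 12
  mu11 <- mean((xx - mx) * (yy - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  majorAxis <- 4 * sqrt(max(l1, 0))
  minorAxis <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  # normalized central moments (order 2): Hu invariants 1 and 2
  eta20 <- mu20 / area; eta02 <- mu02 / area; eta11 <- mu11 / area
  hu1 <- eta20 + eta02
  hu2 <- (eta20 - eta02)^2 + 4 * eta11^2

  # convex hull of pixel centers
  hullArea <- area; defect <- 0
  pts <- cbind(xx, yy)
  if (nrow(unique(pts)) >= 3) {
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    nh <- nrow(hp)
    if (nh >= 3) {
      x1 <- hp[, 1]; y1 <- hp[, 2]
      x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
      hullArea <- max(abs(sum(x1 * y2 - x2 * y1)) / 2, area)
      # max convexity defect: largest distance from a boundary pixel to hull
      bidx <- which(m == 1L & nb4 < 4L)
      bx <- (bidx - 1) %/% nrow(m) + 1; by <- (bidx - 1) %% nrow(m) + 1
      dmin <- rep(Inf, length(bx))
      for (e in seq_len(nh)) {
        a <- hp[e, ]; b <- hp[if (e == nh) 1 else e + 1, ]
        ab <- b - a; L2 <- sum(ab^2)
        t <- if (L2 == 0) rep(0, length(bx)) else
          pmin(1, pmax(0, ((bx - a[1]) * ab[1] + (by - a[2]) * ab[2]) / L2))
        dmin <- pmin(dmin, sqrt((bx - a[1] - t * ab[1])^2 +
                                (by - a[2] - t * ab[2])^2))
      }
      defect <- max(dmin)
    }
  }

  bw <- diff(range(xx)) + 1; bh <- diff(range(yy)) + 1
  bboxArea <- bw * bh

  sk <- skeletonizeMask(m)
  skn <- sum(sk)
  tc <- .transitionCount(matrix(as.integer(sk), nrow(sk), ncol(sk)))
  nEnds <- sum(sk & tc == 1L)
  skelLength <- max(skn - 1, 1)
  e2e <- 0
  if (nEnds == 2L) {
    ei <- which(sk & tc == 1L)
    ex <- (ei - 1) %/% nrow(sk) + 1; ey <- (ei - 1) %% nrow(sk) + 1
    e2e <- sqrt(diff(ex)^2 + diff(ey)^2) / skelLength
  }

  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m)))
  meanDT <- mean(dm[idx])

  setNames(c(area, perimeter, area / perimeter^2, majorAxis, minorAxis,
             ecc, area / hullArea, area / bboxArea, hullArea / bboxArea,
             nEnds, skelLength, e2e, defect, max(bw, bh) / min(bw, bh),
             hu1, hu2, meanDT),
           .turnFeatureNames)
}

#' Feature matrix for a list of masks
#' @param masks list of bitmasks.
#' @return matrix (n x 17).
#' @export
turnFeatureMatrix <- function(masks) {
  t(vapply(masks, extractTurnFeatures, numeric(17)))
}

#' Train the random-forest turn classifier
#'
#' Fits a seeded random forest on 17-feature shape descriptors with a
#' stratified 80/20 train/held-out split and reports held-out accuracy.
#' Labels follow the annotation rule: a shape is a turn when head or tail
#' touch the body or when both point in the same direction (U-shape); the
#' simulator's [makeTurnShapeSet()] produces such labeled sets.
#'
#' @param features numeric matrix (n x 17) from [turnFeatureMatrix()].
#' @param labels logical (or 0/1) turn labels.
#' @param nTrees forest size.
#' @param seed RNG seed (controls the split and the forest).
#' @param holdout fraction held out for accuracy estimation.
#' @param threshold score threshold for flagging turns at prediction time.
#' @return a [TurnClassifier-class].
#' @export
trainTurnClassifier <- function(features, labels, nTrees = 500L, seed = 1L,
                                holdout = 0.2, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("training set must contain both turn and non-turn shapes")
  features <- as.matrix(features)
  set.seed(seed)
  testIdx <- unlist(lapply(split(seq_along(labels), labels), function(i)
    sample(i, max(1, round(holdout * length(i))))))
  train <- setdiff(seq_along(labels), testIdx)
  y <- factor(ifelse(labels, "turn", "non_turn"), levels = c("non_turn", "turn"))
  if (max(apply(features[train, , drop = FALSE], 2, var)) == 0) {
    # degenerate: no feature varies, nothing to learn; constant-score model
    rf <- list(constantScore = mean(labels[train]))
    pred <- rep(rf$constantScore, length(testIdx))
  } else {
    rf <- randomForest::randomForest(x = features[train, , drop = FALSE],
                                     y = y[train], ntree = nTrees)
    pred <- predict(rf, features[testIdx, , drop = FALSE],
                    type = "prob")[, "turn"]
  }
  acc <- mean((pred >= threshold) == labels[testIdx])
  if (acc < 0.6)
    warning(sprintf("held-out accuracy %.2f: features carry little signal", acc))
  new("TurnClassifier", model = rf, featureNames = colnames(features),
      nTrees = as.integer(nTrees), seed = as.integer(seed),
      heldOutAccuracy = acc, threshold = threshold)
}

#' Predict turn flags for shapes
#'
#' @param classifier a [TurnClassifier-class].
#' @param features matrix (n x 17) or list of masks.
#' @return data.frame with `score` in `[0, 1]` and binary `turn` flag.
#' @export
predictTurns <- function(classifier, features) {
  if (is.list(features) && !is.matrix(features))
    features <- turnFeatureMatrix(features)
  score <- if (is.list(classifier@model) &&
               !is.null(classifier@model$constantScore))
    rep(classifier@model$constantScore, nrow(as.matrix(features)))
  else
    predict(classifier@model, as.matrix(features), type = "prob")[, "turn"]
  data.frame(score = score,
             turn = as.integer(score >= classifier@threshold))
}

#' Bin per-frame turn flags into 10-s windows
#'
#' A still worm flagged in many consecutive frames is one turn event, not
#' many: each window of `binSeconds` reports 1 when at least one frame in
#' it is flagged, else 0.
#'
#' @param flags per-frame 0/1 turn flags of one track, in frame order.
#' @param frameRate frames per second.
#' @param binSeconds window width in seconds.
#' @return integer vector, one 0/1 value per window.
#' @examples
#' binTurns(c(rep(1, 7), rep(0, 13)), frameRate = 2)   # one window, one turn
#' @export
binTurns <- function(flags, frameRate = 2, binSeconds = 10) {
  binFrames <- round(binSeconds * frameRate)
  win <- (seq_along(flags) - 1) %/% binFrames
  as.integer(vapply(split(flags, win), function(f) any(f > 0), logical(1)))
}

#' Time-resolved behavioral summary of a condition
#'
#' Aggregates per-bin behavior records onto an hours-after-transfer grid:
#' the fraction of 10-s bins classified dispersal, the distribution of
#' per-track mean speeds, and the mean per-window turn occurrence with its
#' standard error across tracks.
#'
#' @param records data.frame of kinematics bins with columns track_id,
#'   speed, angvel, hat, and optionally `turn` (0/1 per bin).
#' @param gridHours width of the time-grid bins in hours.
#' @return list with `timeSeries` (data.frame: hat, nBins, dispersalFraction,
#'   meanSpeed, turnFrequency, turnSEM) and `trackMeanSpeed` (data.frame:
#'   track_id, meanSpeed).
#' @export
summarizeCondition <- function(records, gridHours = 1) {
  state <- classifyDispersal(records$speed, records$angvel)
  cell <- floor(records$hat / gridHours)
  lev <- seq(min(cell), max(cell))
  ts <- do.call(rbind, lapply(lev, function(b) {
    i <- which(cell == b)
    if (!length(i))
      return(data.frame(hat = b * gridHours, nBins = 0L,
                        dispersalFraction = NA_real_, meanSpeed = NA_real_,
                        turnFrequency = NA_real_, turnSEM = NA_real_))
    tf <- tse <- NA_real_
    if (!is.null(records$turn)) {
      perTrack <- vapply(split(records$turn[i], records$track_id[i]),
                         mean, numeric(1))
      tf <- mean(perTrack)
      tse <- if (length(perTrack) > 1) sd(perTrack) / sqrt(length(perTrack)) else NA_real_
    }
    data.frame(hat = b * gridHours, nBins = length(i),
               dispersalFraction = mean(state[i] == "dispersal"),
               meanSpeed = mean(records$speed[i]),
               turnFrequency = tf, turnSEM = tse)
  }))
  tms <- vapply(split(records$speed, records$track_id), mean, numeric(1))
  list(timeSeries = ts,
       trackMeanSpeed = data.frame(track_id = as.integer(names(tms)),
                                   meanSpeed = unname(tms)))
}
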