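# Gap-free track linking and 10-s-bin kinematics.

#' Link per-frame detections into gap-free tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames: the
#' globally closest detection pair under `maxLinkDistance` is linked first,
#' then the next closest among the remainder, and so on. Ties are broken by
#' smaller area difference. Unlinked detections start new tracks, and a
#' track ends at any frame where it finds no partner: there is no gap
#' closing, consistent with the downstream gap-free track filter.
#'
#' @param detections data.frame from [segmentStack()] (needs columns frame,
#'   x, y; area used for tie-breaks if present).
#' @param maxLinkDistance maximum centroid displacement (px) between
#'   consecutive frames; defaults to one body length per frame.
#' @return the detections data.frame with a `track_id` column, ordered by
#'   track and frame.
#' @export
linkTracks <- function(detections, maxLinkDistance = 60) {
  if (!nrow(detections)) {
    detections$track_id <- integer()
    return(detections)
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  detections$track_id <- NA_integer_
  nextId <- 1L
  frames <- sort(unique(detections$frame))
  prevIdx <- which(detections$frame == frames[1])
  detections$track_id[prevIdx] <- seq_len(length(prevIdx))
  nextId <- length(prevIdx) + 1L
  for (fi in seq_along(frames)[-1]) {
    curIdx <- which(detections$frame == frames[fi])
    consecutive <- frames[fi] == frames[fi - 1] + 1
    if (length(prevIdx) && length(curIdx) && consecutive) {
      D <- outer(detections$x[prevIdx], detections$x[curIdx], "-")^2 +
           outer(detections$y[prevIdx], detections$y[curIdx], "-")^2
      D <- sqrt(D)
      A <- if (!is.null(detections$area))
        abs(outer(detections$area[prevIdx], detections$area[curIdx], "-")) else
        D * 0
      D[D > maxLinkDistance] <- NA
      while (any(!is.na(D))) {
        best <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)
        if (nrow(best) > 1)                       # tie: smaller area difference
          best <- best[which.min(A[best]), , drop = FALSE]
        i <- best[1, 1]; j <- best[1, 2]
        detections$track_id[curIdx[j]] <- detections$track_id[prevIdx[i]]
        D[i, ] <- NA; D[, j] <- NA
      }
    }
    unlinked <- curIdx[is.na(detections$track_id[curIdx])]
    if (length(unlinked)) {
      detections$track_id[unlinked] <- seq(nextId, length.out = length(unlinked))
      nextId <- nextId + length(unlinked)
    }
    prevIdx <- curIdx
  }
  detections[order(detections$track_id, detections$frame), , drop = FALSE]
}

#' Filter tracks for analysis
#'
#' Keeps only tracks of at least `minFrames` consecutive frames (10 s at
#' 2 fps by default). With `movingOnly`, tracks whose net centroid
#' displacement is below half a body length are dropped as probable
#' segmentation artifacts (non-moving debris).
#'
#' @param tracks data.frame from [linkTracks()].
#' @param minFrames minimum track length in frames.
#' @param movingOnly drop non-moving tracks.
#' @param wormLength body length (px) used for the displacement floor.
#' @return filtered tracks data.frame.
#' @export
filterTracks <- function(tracks, minFrames = 20L, movingOnly = FALSE,
                         wormLength = 60) {
  if (!nrow(tracks)) return(tracks)
  keep <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(i) {
    if (length(i) < minFrames) return(FALSE)
    if (movingOnly) {
      dx <- tracks$x[i[length(i)]] - tracks$x[i[1]]
      dy <- tracks$y[i[length(i)]] - tracks$y[i[1]]
      if (sqrt(dx^2 + dy^2) < 0.5 * wormLength) return(FALSE)
    }
    TRUE
  }, logical(1))
  ids <- as.integer(names(keep)[keep])
  tracks[tracks$track_id %in% ids, , drop = FALSE]
}

#' Per-track kinematics in fixed time bins
#'
#' Splits each track into consecutive windows of `binSeconds` and reports,
#' per bin, the path speed and the angular velocity of the centroid path.
#' Speed is the summed frame-to-frame displacement divided by the elapsed
#' time, converted to mm/s. Angular velocity is the mean absolute change of
#' heading direction between successive displacement vectors times the
#' frame rate, in deg/s; displacements below a noise floor (0.5 px) carry
#' no usable heading and are skipped. Bins whose heading is undefined
#' (fewer than two usable displacement vectors) report 0 with
#' `angvelDefined = FALSE`.
#'
#' @param tracks data.frame with track_id, frame, x, y.
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second.
#' @param binSeconds bin width in seconds.
#' @param startTime acquisition start in seconds after transfer (h.a.t.
#'   origin); per-bin h.a.t. is the bin's mid-time converted to hours.
#' @param noiseFloor minimum displacement (px) for a usable heading vector.
#' @return data.frame with columns track_id, bin, nFrames, speed (mm/s),
#'   angvel (deg/s), angvelDefined, hat (hours after transfer).
#' @export
computeKinematics <- function(tracks, pixelSize = 6.25, frameRate = 2,
                              binSeconds = 10, startTime = 0,
                              noiseFloor = 0.5) {
  if (!nrow(tracks)) return(.emptyKinematics())
  pxmm <- pixelSize / 1000
  binFrames <- round(binSeconds * frameRate)
  out <- lapply(split(seq_len(nrow(tracks)), tracks$track_id), function(i) {
    i <- i[order(tracks$frame[i])]
    n <- length(i)
    bins <- split(seq_len(n), (seq_len(n) - 1) %/% binFrames)
    res <- lapply(bins, function(b) {
      if (length(b) < 2) return(NULL)
      x <- tracks$x[i[b]]; y <- tracks$y[i[b]]
      dx <- diff(x); dy <- diff(y)
      disp <- sqrt(dx^2 + dy^2)
      speed <- sum(disp) * pxmm / (length(disp) / frameRate)
      usable <- disp >= noiseFloor
      h <- atan2(dy[usable], dx[usable])
      if (length(h) >= 2) {
        angvel <- mean(abs(wrapAngle(diff(h)))) * frameRate * 180 / pi
        defined <- TRUE
      } else {
        angvel <- 0; defined <- FALSE
      }
      midFrame <- mean(tracks$frame[i[b]])
      data.frame(track_id = tracks$track_id[i[1]],
                 bin = (b[1] - 1) %/% binFrames + 1L,
                 nFrames = length(b), speed = speed, angvel = angvel,
                 angvelDefined = defined,
                 hat = (startTime + (midFrame - 1) / frameRate) / 3600)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .emptyKinematics() else `rownames<-`(out, NULL)
}

.emptyKinematics <- function() {
  data.frame(track_id = integer(), bin = integer(), nFrames = integer(),
             speed = numeric(), angvel = numeric(),
             angvelDefined = logical(), hat = numeric())
}

#' Discard the plate-settling period
#'
#' Removes all kinematics bins recorded during the first `firstMinutes`
#' after transfer, when worm handling introduces artifacts. The boundary is
#' inclusive: a bin at exactly the cutoff is kept.
#'
#' @param bins kinematics data.frame with an `hat` column (hours).
#' @param firstMinutes settling period to drop.
#' @return filtered data.frame.
#' @export
discardSettlingPeriod <- function(bins, firstMinutes = 30) {
  bins[bins$hat >= firstMinutes / 60, , drop = FALSE]
}

#' Decimate a frame stack to a lower frame rate
#'
#' Optional temporal downsampling (e.g. 5 fps acquisition to 2 fps for
#' tracking) implemented as nearest-timestamp frame decimation.
#'
#' @param stack a [FrameStack-class].
#' @param targetRate desired frames per second (must not exceed the
#'   stack's rate).
#' @return a decimated [FrameStack-class] with `frameRate = targetRate`.
#' @export
decimateFrames <- function(stack, targetRate) {
  if (targetRate > frameRate(stack))
    stop("targetRate exceeds the stack frame rate")
  ts <- timestamps(stack)
  wanted <- seq(ts[1], ts[length(ts)], by = 1 / targetRate)
  idx <- unique(vapply(wanted, function(t) which.min(abs(ts - t)), integer(1)))
  new("FrameStack", frames = frames(stack)[, , idx, drop = FALSE],
      pixelSize = pixelSize(stack), frameRate = targetRate,
      timestamps = ts[idx])
}
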