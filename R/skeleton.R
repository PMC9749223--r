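# Midline extraction: morphological thinning, validation, head assignment,
# and the 24-angle posture vector.

.shift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# 8-neighborhood in clockwise order starting north (image rows grow down)
.neighborShifts <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                        c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

.neighborCount <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (d in .neighborShifts) s <- s + .shift(m, d[1], d[2])
  s
}

# crossing number: 0->1 transitions around each pixel in clockwise order.
# On an 8-connected thinned curve: endpoints have 1, path pixels 2,
# junctions >= 3 (raw neighbor counts overcount at staircase corners).
.transitionCount <- function(m) {
  P <- lapply(.neighborShifts, function(d) .shift(m, d[1], d[2]))
  seqP <- c(P, P[1])
  Reduce(`+`, lapply(1:8, function(i) (seqP[[i]] == 0L) * (seqP[[i + 1]] == 1L)))
}

#' Skeletonize a binary mask by morphological thinning
#'
#' Zhang-Suen iterative thinning to a 1-px-wide 8-connected medial curve,
#' followed by removal of spur branches shorter than `pruneLength` pixels.
#'
#' @param mask logical or 0/1 matrix, one connected foreground component.
#' @param pruneLength spur branches up to this many pixels are removed.
#' @return logical matrix of the same dimensions marking skeleton pixels.
#' @export
skeletonizeMask <- function(mask, pruneLength = 3L) {
  if (!any(mask)) stop("empty mask")
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(.neighborShifts, function(d) .shift(m, d[1], d[2]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(i)
        (seqP[[i]] == 0L) * (seqP[[i + 1]] == 1L)))
      if (step == 1)
        cond <- P[[1]] * P[[3]] * P[[5]] == 0L & P[[3]] * P[[5]] * P[[7]] == 0L
      else
        cond <- P[[1]] * P[[3]] * P[[7]] == 0L & P[[1]] * P[[5]] * P[[7]] == 0L
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- .pruneSpurs(m, pruneLength)
  m == 1L
}

.pixelList <- function(m) {
  idx <- which(m == 1L)
  cbind(y = (idx - 1L) %% nrow(m) + 1L, x = (idx - 1L) %/% nrow(m) + 1L)
}

.pruneSpurs <- function(m, pruneLength) {
  if (pruneLength <= 0) return(m)
  for (pass in 1:4) {
    tc <- .transitionCount(m)
    ends <- which(m == 1L & tc == 1L & .neighborCount(m) >= 1L)
    removedAny <- FALSE
    for (e in ends) {
      if (m[e] == 0L) next
      path <- integer(); cur <- e; prev <- -1L
      repeat {
        y <- (cur - 1L) %% nrow(m) + 1L; x <- (cur - 1L) %/% nrow(m) + 1L
        nb <- integer()
        for (d in .neighborShifts) {
          yy <- y + d[1]; xx <- x + d[2]
          if (yy >= 1 && yy <= nrow(m) && xx >= 1 && xx <= ncol(m) &&
              m[yy, xx] == 1L) {
            id <- yy + (xx - 1L) * nrow(m)
            if (id != prev) nb <- c(nb, id)
          }
        }
        if (tc[cur] >= 3L || length(nb) >= 2L) { # junction: prune the walked spur
          if (length(path) > 0 && length(path) <= pruneLength) {
            m[path] <- 0L; removedAny <- TRUE
          }
          break
        }
        path <- c(path, cur)
        if (length(nb) == 0L || length(path) > pruneLength) break
        prev <- cur; cur <- nb[1]
      }
    }
    if (!removedAny) break
  }
  m
}

#' Validate a thinned skeleton
#'
#' A skeleton is retained only when it is a single unbranched 8-connected
#' path (exactly two endpoints, no junction pixels) of arc length at least
#' `minLength` pixels; everything else is rejected with a reason
#' (`too_short`, `branched`, `fragmented`, or `empty`).
#'
#' @param skeleton logical matrix from [skeletonizeMask()].
#' @param minLength minimum arc length in pixels.
#' @return list with `valid`, `reason` (`NA` when valid), `path` (ordered
#'   n x 2 matrix of (x, y) pixel coordinates, endpoint to endpoint) and
#'   `arcLength` (px).
#' @export
validateSkeleton <- function(skeleton, minLength = 26) {
  m <- matrix(as.integer(skeleton > 0), nrow(skeleton), ncol(skeleton))
  reject <- function(reason) list(valid = FALSE, reason = reason,
                                  path = NULL, arcLength = 0)
  if (!any(m == 1L)) return(reject("empty"))
  tc <- .transitionCount(m)
  ends <- which(m == 1L & tc == 1L)
  if (any(m == 1L & tc >= 3L)) return(reject("branched"))
  if (length(ends) != 2L) {
    return(reject(if (length(ends) > 2L) "branched" else "fragmented"))
  }
  path <- .walkPath(m, ends[1])
  if (nrow(path) != sum(m)) return(reject("fragmented"))
  arc <- sum(sqrt(rowSums(diff(path)^2)))
  if (arc < minLength) return(reject("too_short"))
  list(valid = TRUE, reason = NA_character_,
       path = cbind(x = path[, 2], y = path[, 1]), arcLength = arc)
}

# ordered walk along an unbranched skeleton from a starting linear index;
# prefers 4-connected steps over diagonals
.walkPath <- function(m, start) {
  ny <- nrow(m)
  visited <- matrix(FALSE, ny, ncol(m))
  cur <- start
  out <- matrix(0L, sum(m), 2)
  k <- 0L
  repeat {
    y <- (cur - 1L) %% ny + 1L; x <- (cur - 1L) %/% ny + 1L
    visited[y, x] <- TRUE
    k <- k + 1L
    out[k, ] <- c(y, x)
    nxt <- NULL; nxtDiag <- NULL
    for (d in .neighborShifts) {
      yy <- y + d[1]; xx <- x + d[2]
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= ncol(m) &&
          m[yy, xx] == 1L && !visited[yy, xx]) {
        if (abs(d[1]) + abs(d[2]) == 1L) nxt <- c(yy, xx) else nxtDiag <- c(yy, xx)
      }
    }
    step <- if (!is.null(nxt)) nxt else nxtDiag
    if (is.null(step)) break
    cur <- step[1] + (step[2] - 1L) * ny
  }
  out[seq_len(k), , drop = FALSE]
}

#' Assign the head end of a skeleton from the direction of movement
#'
#' Worms move head-first, so the head is the endpoint whose position
#' projects furthest onto the (smoothed) track displacement vector. The
#' motion-based call is accepted only when the displacement is at least
#' `minDisplacement` px/frame and the two endpoints' projections differ by
#' at least `projectionMargin` of the body length; otherwise the assignment
#' is deferred (orientation can then be inherited from adjacent frames of
#' the same track, see [orientTrackSkeletons()]).
#'
#' @param path ordered skeleton path (n x 2, columns x, y).
#' @param displacement numeric(2), smoothed per-frame displacement (px).
#' @param minDisplacement confidence floor on `|displacement|` (px/frame).
#' @param projectionMargin required projection gap, fraction of arc length.
#' @return list with `path` (oriented head first, or unchanged), `source`
#'   (`"motion"` or `"unresolved"`).
#' @export
assignHead <- function(path, displacement, minDisplacement = 1,
                       projectionMargin = 0.25) {
  arc <- sum(sqrt(rowSums(diff(path)^2)))
  nrm <- sqrt(sum(displacement^2))
  if (is.na(nrm) || nrm < minDisplacement)
    return(list(path = path, source = "unresolved"))
  u <- displacement / nrm
  ctr <- colMeans(path)
  pHead <- sum((path[1, ] - ctr) * u)
  pTail <- sum((path[nrow(path), ] - ctr) * u)
  if (abs(pHead - pTail) < projectionMargin * arc)
    return(list(path = path, source = "unresolved"))
  if (pTail > pHead) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  list(path = path, source = "motion")
}

#' Orient all skeletons of one track
#'
#' First pass: motion-based head assignment per frame using a 3-frame
#' smoothed centroid displacement. Second pass: frames left unresolved
#' inherit the orientation of the nearest oriented frame in the same track,
#' matching endpoints by proximity. Frames that remain unresolved are
#' discarded (`keep = FALSE`).
#'
#' @param paths list of skeleton paths (or `NULL` for invalid frames), one
#'   per track frame in order.
#' @param centroids matrix (nframes x 2) of track centroids.
#' @return list of lists with `path`, `source`
#'   (motion/adjacent_frame/unresolved) and `keep`.
#' @export
orientTrackSkeletons <- function(paths, centroids) {
  n <- length(paths)
  disp <- matrix(0, n, 2)
  if (n >= 2) {
    d <- diff(centroids)
    disp[2:n, ] <- d
    disp[1, ] <- d[1, ]
    disp[, 1] <- movingAverage(disp[, 1], 3L)
    disp[, 2] <- movingAverage(disp[, 2], 3L)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(paths[[i]])) { out[[i]] <- list(path = NULL, source = NA, keep = FALSE); next }
    a <- assignHead(paths[[i]], disp[i, ])
    out[[i]] <- list(path = a$path, source = a$source,
                     keep = a$source == "motion")
  }
  oriented <- which(vapply(out, function(o) identical(o$source, "motion"), logical(1)))
  if (length(oriented)) {
    for (i in seq_len(n)) {
      if (is.null(out[[i]]$path) || out[[i]]$source != "unresolved") next
      ref <- oriented[which.min(abs(oriented - i))]
      refHead <- out[[ref]]$path[1, ]
      p <- out[[i]]$path
      dHead <- sum((p[1, ] - refHead)^2)
      dTail <- sum((p[nrow(p), ] - refHead)^2)
      if (dTail < dHead) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      out[[i]] <- list(path = p, source = "adjacent_frame", keep = TRUE)
    }
  }
  out
}

.bilinear <- function(img, x, y) {
  x0 <- pmin(pmax(floor(x), 1), ncol(img) - 1)
  y0 <- pmin(pmax(floor(y), 1), nrow(img) - 1)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# move each point to the distance-transform-weighted centroid along the
# local normal: sub-pixel correction of thinning wobble toward the true
# medial ridge of the mask
.refineMidline <- function(pts, dtimg, maxOffset = 2) {
  off <- seq(-maxOffset, maxOffset, by = 0.5)
  d <- diff(pts)
  tg <- rbind(d[1, ], (d[-1, , drop = FALSE] + d[-nrow(d), , drop = FALSE]) / 2,
              d[nrow(d), ])
  tg <- tg / sqrt(rowSums(tg^2))
  nr <- cbind(-tg[, 2], tg[, 1])
  for (i in seq_len(nrow(pts))) {
    w <- .bilinear(dtimg, pts[i, 1] + off * nr[i, 1],
                   pts[i, 2] + off * nr[i, 2])^2
    if (sum(w) > 0)
      pts[i, ] <- pts[i, ] + (sum(off * w) / sum(w)) * nr[i, ]
  }
  pts
}

.splineSmoothPath <- function(path, df) {
  s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  keep <- !duplicated(s)
  s <- s[keep]; path <- path[keep, , drop = FALSE]
  df <- min(df, nrow(path) - 2)
  if (df < 4) return(path)
  cbind(stats::predict(stats::smooth.spline(s, path[, 1], df = df), s)$y,
        stats::predict(stats::smooth.spline(s, path[, 2], df = df), s)$y)
}

#' Midline from a skeleton path, with sub-pixel refinement
#'
#' Smooths an ordered pixel path with a cubic smoothing spline over arc
#' length (suppressing thinning wobble and stair-casing), optionally refines
#' each point to the distance-transform-weighted center of the source mask
#' along the local normal (sub-pixel medial correction), and resamples to
#' `nPoints` equally arc-length-spaced points.
#'
#' @param path ordered skeleton path (n x 2, columns x, y).
#' @param mask optional source bitmask in the same coordinates; enables the
#'   distance-transform refinement.
#' @param nPoints output points (default 26).
#' @param smoothDf spline degrees of freedom for the initial fit.
#' @return `nPoints` x 2 matrix of midline points.
#' @export
skeletonMidline <- function(path, mask = NULL, nPoints = 26L, smoothDf = 12) {
  sm <- .splineSmoothPath(as.matrix(path), smoothDf)
  if (!is.null(mask)) {
    dtimg <- EBImage::imageData(EBImage::distmap(EBImage::Image(
      matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))))
    pts <- resamplePath(sm, max(2L * nPoints - 1L, nrow(sm)))
    pts <- .refineMidline(pts, dtimg)
    pts <- .splineSmoothPath(pts, smoothDf + 2)
    sm <- pts
  }
  resamplePath(sm, nPoints)
}

#' Posture vector: 24 intersegment angles of an oriented midline
#'
#' The midline is resampled to 26 equally arc-length-spaced points head to
#' tail and the 24 signed planar angles between the 25 consecutive chord
#' vectors are returned (positive = counter-clockwise in image
#' coordinates). Pixelated skeleton paths (integer coordinates) are first
#' smoothed and sub-pixel-refined via [skeletonMidline()], and the angle
#' vector is lightly smoothed (moving average, window 3) to suppress
#' residual rasterization noise; continuous midlines are resampled
#' directly. Mirroring the worm (left-right reflection) negates the
#' vector; translation and global rotation leave it unchanged.
#'
#' @param path oriented midline or skeleton path (n x 2, columns x, y,
#'   head first).
#' @param mask optional source bitmask (same coordinates as `path`) used
#'   for sub-pixel refinement of pixelated paths.
#' @param smoothing `"auto"` (smooth only integer-coordinate pixel paths),
#'   `"pixel"` (always smooth) or `"none"`.
#' @return numeric(24) of signed angles in radians.
#' @examples
#' straight <- cbind(seq(0, 39), 0)
#' max(abs(postureAngles(straight)))
#' @export
postureAngles <- function(path, mask = NULL,
                          smoothing = c("auto", "pixel", "none")) {
  smoothing <- match.arg(smoothing)
  path <- as.matrix(path)
  if (nrow(path) < 3) stop("path too short for posture angles")
  if (smoothing == "auto")
    smoothing <- if (all(path == round(path))) "pixel" else "none"
  if (smoothing == "pixel") {
    pts <- skeletonMidline(path, mask)
    movingAverage(chordAngles(pts), 3L)
  } else {
    chordAngles(resamplePath(path, 26L))
  }
}

#' Skeletonize and orient every frame of one track
#'
#' Runs thinning, validation, orientation (motion first, then adjacent-frame
#' propagation) and posture-angle extraction over the detections of a single
#' track, returning one row per frame.
#'
#' @param trackDetections detections of one track (rows ordered by frame;
#'   needs `mask`, `bx0`, `by0`, `x`, `y`).
#' @param minLength minimum skeleton arc length (px).
#' @return data.frame with frame, valid, reason, headSource, arcLength,
#'   skeleton (encoded path string) and a1..a24 angle columns (NA when the
#'   frame was rejected or could not be oriented).
#' @export
trackPostures <- function(trackDetections, minLength = 26) {
  n <- nrow(trackDetections)
  paths <- vector("list", n)
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sk <- skeletonizeMask(trackDetections$mask[[i]])
    v <- validateSkeleton(sk, minLength)
    if (v$valid) {
      p <- v$path
      p[, 1] <- p[, 1] + trackDetections$bx0[i] - 1  # full-image coordinates
      p[, 2] <- p[, 2] + trackDetections$by0[i] - 1
      paths[[i]] <- p
    } else reasons[i] <- v$reason
  }
  oriented <- orientTrackSkeletons(paths,
                                   cbind(trackDetections$x, trackDetections$y))
  ang <- matrix(NA_real_, n, 24)
  src <- character(n); keep <- logical(n); skel <- rep(NA_character_, n)
  arc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    o <- oriented[[i]]
    src[i] <- if (is.null(o$path)) NA_character_ else o$source
    keep[i] <- isTRUE(o$keep)
    if (keep[i]) {
      local <- cbind(o$path[, 1] - trackDetections$bx0[i] + 1,
                     o$path[, 2] - trackDetections$by0[i] + 1)
      ang[i, ] <- postureAngles(local, mask = trackDetections$mask[[i]])
      skel[i] <- encodePath(o$path)
      arc[i] <- sum(sqrt(rowSums(diff(o$path)^2)))
    }
  }
  colnames(ang) <- paste0("a", 1:24)
  data.frame(frame = trackDetections$frame, valid = keep, reason = reasons,
             headSource = src, arcLength = arc, skeleton = skel, ang)
}
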