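# Worm detection: background subtraction, filtering, size selection.

#' Estimate a static background image by temporal median
#'
#' Computes the per-pixel median over a stride-sampled subset of frames.
#' Worms are sparse and moving, so any pixel is worm-covered in well under
#' half of the sampled frames and the median recovers the background.
#'
#' @param x a [FrameStack-class] or a `ny x nx x nframes` array.
#' @param sampleStride keep every `sampleStride`-th frame for the median.
#' @return background image matrix.
#' @export
estimateBackground <- function(x, sampleStride = 1L) {
  arr <- if (is(x, "FrameStack")) frames(x) else x
  idx <- seq(1, dim(arr)[3], by = sampleStride)
  if (length(idx) < 3)
    stop("need at least 3 sampled frames to estimate a background")
  k <- length(idx)
  m <- matrix(arr[, , idx], ncol = k)        # rows = pixels
  # row-wise median without per-pixel apply(): sort within rows via order()
  o <- order(rep(seq_len(nrow(m)), k), m)
  srt <- matrix(m[o], ncol = k, byrow = TRUE)
  med <- if (k %% 2 == 1) srt[, (k + 1) / 2] else
    (srt[, k / 2] + srt[, k / 2 + 1]) / 2
  matrix(med, dim(arr)[1], dim(arr)[2])
}

#' Default segmentation parameters from worm geometry
#'
#' Size-selection bounds are derived from the expected worm silhouette:
#' `minArea = 0.5 * length * width` (tolerates partial truncation at the
#' field edge) and `maxArea = 3 * length * width` (excludes merged pairs).
#'
#' @param wormLength,wormWidth expected body dimensions in pixels.
#' @param thresholdSd threshold in units of the robust noise scale.
#' @param smoothingSigma Gaussian smoothing sigma (px) before thresholding.
#' @return named list of parameters for [segmentFrame()].
#' @export
segmentParams <- function(wormLength = 60, wormWidth = 5,
                          thresholdSd = 5, smoothingSigma = 1) {
  list(thresholdSd = thresholdSd, smoothingSigma = smoothingSigma,
       minArea = 0.5 * wormLength * wormWidth,
       maxArea = 3 * wormLength * wormWidth)
}

#' Segment worm-shaped objects in one frame
#'
#' The difference from the background is Gaussian-smoothed and its absolute
#' value thresholded at `thresholdSd` times a robust (MAD-based) estimate
#' of the smoothed noise scale; the result is
#' hole-filled, and connected components outside `[minArea, maxArea]` are
#' discarded. Working on the absolute difference makes detection sign
#' agnostic (dark-on-bright and bright-on-dark) and invariant to a constant
#' intensity offset applied to both frame and background.
#'
#' @param frame numeric matrix.
#' @param background matrix of the same dimensions (see
#'   [estimateBackground()]).
#' @param params list from [segmentParams()].
#' @param frameIndex frame number recorded in the output.
#' @return data.frame with one row per detection: frame, x, y (centroid px),
#'   area, bbox (x0, x1, y0, y1), meanIntensity, and a list column `mask`
#'   holding the cropped logical bitmask of each component.
#' @export
segmentFrame <- function(frame, background, params = segmentParams(),
                         frameIndex = 1L) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  d <- frame - background                    # signed: smooth before abs()
  if (params$smoothingSigma > 0)
    d <- EBImage::imageData(EBImage::gblur(d, sigma = params$smoothingSigma))
  d <- d - median(d)
  noise <- mad(d, center = 0)
  thr <- params$thresholdSd * max(noise, .Machine$double.eps)
  mask <- abs(d) > thr
  if (!any(mask)) return(.emptyDetections())
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  labm <- EBImage::imageData(EBImage::bwlabel(mask))
  areas <- tabulate(labm)
  keep <- which(areas >= params$minArea & areas <= params$maxArea)
  if (!length(keep)) return(.emptyDetections())
  rows <- lapply(keep, function(l) {
    idx <- which(labm == l)
    yy <- (idx - 1) %% nrow(labm) + 1
    xx <- (idx - 1) %/% nrow(labm) + 1
    bb <- c(min(xx), max(xx), min(yy), max(yy))
    sub <- labm[bb[3]:bb[4], bb[1]:bb[2], drop = FALSE] == l
    data.frame(frame = frameIndex, x = mean(xx), y = mean(yy),
               area = areas[l], bx0 = bb[1], bx1 = bb[2],
               by0 = bb[3], by1 = bb[4],
               meanIntensity = mean(frame[idx]),
               mask = I(list(sub)))
  })
  do.call(rbind, rows)
}

.emptyDetections <- function() {
  data.frame(frame = integer(), x = numeric(), y = numeric(),
             area = numeric(), bx0 = integer(), bx1 = integer(),
             by0 = integer(), by1 = integer(), meanIntensity = numeric(),
             mask = I(list()))
}

#' Segment every frame of a stack
#'
#' @param stack a [FrameStack-class].
#' @param background background image; estimated from the stack when `NULL`.
#' @param params list from [segmentParams()].
#' @return data.frame of detections across frames (see [segmentFrame()]).
#' @export
segmentStack <- function(stack, background = NULL, params = segmentParams()) {
  arr <- frames(stack)
  if (is.null(background)) background <- estimateBackground(stack)
  out <- lapply(seq_len(dim(arr)[3]), function(f)
    segmentFrame(arr[, , f], background, params, frameIndex = f))
  do.call(rbind, out)
}
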