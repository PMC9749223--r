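# Shared geometry helpers for midlines and posture angles.

#' Wrap angles to (-pi, pi]
#' @param x angles in radians
#' @return wrapped angles
#' @keywords internal
wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Intersegment angles of an ordered midline
#'
#' Given an ordered midline of n points (head to tail), forms the n-1 chord
#' vectors and returns the n-2 signed planar angles between consecutive
#' chords (positive = counter-clockwise in image coordinates). A midline of
#' 26 points yields the standard 24-angle posture vector.
#'
#' @param midline numeric matrix (n x 2) of ordered (x, y) points.
#' @return numeric vector of n-2 signed angles in radians.
#' @examples
#' straight <- cbind(seq(0, 25), 0)
#' all(chordAngles(straight) == 0)
#' @export
chordAngles <- function(midline) {
  midline <- as.matrix(midline)
  if (nrow(midline) < 3) stop("midline must have at least 3 points")
  d <- diff(midline)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("degenerate (zero-length) chord in midline")
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1], rowSums(a * b))
}

#' Resample an ordered path to equally spaced points by arc length
#'
#' @param path numeric matrix (n x 2) of ordered points.
#' @param nPoints number of output points (default 26).
#' @return matrix (nPoints x 2); first and last input points are preserved.
#' @export
resamplePath <- function(path, nPoints = 26L) {
  path <- as.matrix(path)
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) stop("path has zero length")
  keep <- c(TRUE, seg > 0)              # drop duplicated points for approx()
  s <- s[keep]; path <- path[keep, , drop = FALSE]
  target <- seq(0, s[length(s)], length.out = nPoints)
  cbind(approx(s, path[, 1], xout = target)$y,
        approx(s, path[, 2], xout = target)$y)
}

# centered moving average that keeps endpoints
movingAverage <- function(x, window = 3L) {
  n <- length(x)
  if (n < window) return(x)
  k <- window %/% 2
  out <- x
  cs <- cumsum(c(0, x))
  i <- (k + 1):(n - k)
  out[i] <- (cs[i + k + 1] - cs[i - k]) / window
  out
}

#' Run-length encode / decode a binary mask
#'
#' Masks are serialized in result tables as `"ny,nx:v1xl1;v2xl2;..."` in
#' column-major order, a compact plain-text representation.
#'
#' @param mask logical or 0/1 matrix.
#' @return `encodeMask`: a single string; `decodeMask`: a logical matrix.
#' @export
encodeMask <- function(mask) {
  r <- rle(as.integer(mask))
  paste0(nrow(mask), ",", ncol(mask), ":",
         paste(r$values, r$lengths, sep = "x", collapse = ";"))
}

#' @rdname encodeMask
#' @param code a string produced by `encodeMask`
#' @export
decodeMask <- function(code) {
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  dims <- as.integer(strsplit(parts[1], ",", fixed = TRUE)[[1]])
  runs <- do.call(rbind, strsplit(strsplit(parts[2], ";", fixed = TRUE)[[1]],
                                  "x", fixed = TRUE))
  matrix(as.logical(rep(as.integer(runs[, 1]), as.integer(runs[, 2]))),
         dims[1], dims[2])
}

# serialize an ordered pixel path as "x:y;x:y;..."
encodePath <- function(path) {
  paste(sprintf("%g:%g", path[, 1], path[, 2]), collapse = ";")
}

decodePath <- function(code) {
  xy <- do.call(rbind, strsplit(strsplit(code, ";", fixed = TRUE)[[1]],
                                ":", fixed = TRUE))
  cbind(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]))
}
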