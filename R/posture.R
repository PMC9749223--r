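# Eigenworm decomposition and posture-syntax libraries.

#' Eligibility filter for eigenworm / posture analysis
#'
#' Posture analysis is restricted to moving worms: a kinematics bin (or
#' track summary) qualifies when the track duration is at least 5 s, speed
#' exceeds 0.01 mm/s and angular velocity is below 50 deg/s.
#'
#' @param durationS track duration in seconds.
#' @param speed speed in mm/s.
#' @param angvel angular velocity in deg/s.
#' @return logical vector.
#' @export
eligibleForEigenworms <- function(durationS, speed, angvel) {
  durationS >= 5 & speed > 0.01 & angvel < 50
}

#' Eigenworm basis from posture vectors
#'
#' Mean-centers the posture vectors and eigendecomposes their covariance
#' matrix; the eigenvectors (eigenworms) are the principal bend modes, in
#' decreasing order of explained posture variance.
#'
#' @param postures numeric matrix (n x 24) of intersegment-angle vectors.
#' @return an [EigenwormBasis-class].
#' @export
computeEigenworms <- function(postures) {
  postures <- as.matrix(postures)
  n <- nrow(postures); p <- ncol(postures)
  if (n < p)
    warning("fewer posture vectors than dimensions: basis is rank deficient")
  ctr <- colMeans(postures)
  cv <- cov(postures)
  if (all(cv == 0)) {
    warning("identical posture vectors: covariance is zero, no meaningful basis")
    return(new("EigenwormBasis", vectors = matrix(numeric(), p, 0),
               values = numeric(), center = ctr, nPostures = as.integer(n)))
  }
  e <- eigen(cv, symmetric = TRUE)
  m <- min(n - 1, p)
  vals <- pmax(e$values, 0)[seq_len(m)]
  new("EigenwormBasis", vectors = e$vectors[, seq_len(m), drop = FALSE],
      values = vals, center = ctr, nPostures = as.integer(n))
}

#' Project posture vectors onto an eigenworm basis (and back)
#'
#' @param basis an [EigenwormBasis-class].
#' @param postures matrix (n x 24).
#' @param nModes number of leading modes to use (default all).
#' @return `projectPostures`: n x nModes score matrix;
#'   `reconstructPostures`: n x 24 matrix rebuilt from the scores.
#' @export
projectPostures <- function(basis, postures, nModes = ncol(basis@vectors)) {
  sweep(as.matrix(postures), 2, basis@center) %*%
    basis@vectors[, seq_len(nModes), drop = FALSE]
}

#' @rdname projectPostures
#' @param scores score matrix from `projectPostures`
#' @export
reconstructPostures <- function(basis, scores) {
  nModes <- ncol(scores)
  sweep(scores %*% t(basis@vectors[, seq_len(nModes), drop = FALSE]),
        2, -basis@center)
}

#' Identify mirrored posture pairs among centroids
#'
#' A worm bent to the left and its right-bent reflection produce negated
#' angle vectors but are the same posture. Candidate pairs `(i, j)` are
#' ranked by the mirror distance `|c_i - (-c_j)|` and matched greedily
#' (smallest distance first, each centroid used once). A match is accepted
#' only when its distance is at most the `matchQuantile` quantile of
#' nearest-neighbor distances among the centroids (a scale-free gate) and
#' clearly smaller than the pair's direct distance -- the evidence that the
#' two centroids are related by reflection rather than merely close.
#' A symmetric posture (`c ~ -c` within the gate) is a fixed point and
#' stays self-paired, as do centroids with no acceptable partner.
#'
#' @param centroids numeric matrix (k x 24).
#' @param matchQuantile quantile of inter-centroid nearest-neighbor
#'   distances used as the acceptance gate.
#' @return integer(k) mirror-pair map: index of each centroid's partner
#'   (self when unpaired).
#' @export
findMirrorPairs <- function(centroids, matchQuantile = 0.75) {
  k <- nrow(centroids)
  if (k < 2) return(seq_len(k))
  D <- as.matrix(stats::dist(rbind(centroids, -centroids)))
  toNeg <- D[seq_len(k), k + seq_len(k), drop = FALSE]  # dist(c_i, -c_j)
  inter <- D[seq_len(k), seq_len(k)]
  diag(inter) <- Inf
  gate <- quantile(apply(inter, 1, min), matchQuantile)
  pair <- seq_len(k)
  # symmetric postures (c ~ -c) are fixed points: lock them first so a
  # marginally closer cross-match cannot claim them
  free <- diag(toNeg) > gate
  for (idx in order(toNeg)) {
    i <- (idx - 1) %% k + 1L
    j <- (idx - 1) %/% k + 1L
    if (toNeg[i, j] > gate) break
    # a genuine mirror pair is much closer under negation than directly
    if (i != j && free[i] && free[j] && toNeg[i, j] < 0.5 * inter[i, j]) {
      pair[i] <- j; pair[j] <- i
      free[c(i, j)] <- FALSE
    }
  }
  as.integer(pair)
}

#' Build a posture library for one condition
#'
#' k-means clustering (k = 200 by default, seeded, multiple random
#' restarts) of eligible posture vectors pooled across experimental repeats
#' of one condition, followed by mirror-pair identification and merging:
#' each mirrored pair is treated as a single posture class, which reduces
#' the library size by roughly half.
#'
#' @param postures numeric matrix (n x 24) of posture vectors.
#' @param k number of k-means clusters.
#' @param condition condition label stored in the library.
#' @param seed RNG seed for clustering.
#' @param nstart k-means random restarts.
#' @param matchQuantile see [findMirrorPairs()].
#' @return a [PostureLibrary-class].
#' @export
buildPostureLibrary <- function(postures, k = 200L, condition = "default",
                                seed = 1L, nstart = 10L,
                                matchQuantile = 0.75) {
  postures <- as.matrix(postures)
  if (nrow(postures) < k)
    stop("fewer posture vectors (", nrow(postures), ") than clusters (", k, ")")
  set.seed(seed)
  # the Hartigan-Wong Quick-TRANSfer cap is a benign notice on large n
  # (restarts still deliver a converged solution); other warnings pass
  km <- withCallingHandlers(
    kmeans(postures, centers = k, nstart = nstart, iter.max = 50),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pair <- findMirrorPairs(km$centers, matchQuantile)
  classId <- .pairsToClasses(pair)
  new("PostureLibrary", condition = condition, centroids = km$centers,
      pairMap = pair, classId = classId,
      counts = as.integer(km$size), seed = as.integer(seed))
}

.pairsToClasses <- function(pair) {
  k <- length(pair)
  classId <- integer(k)
  nextClass <- 0L
  for (i in seq_len(k)) {
    if (classId[i] > 0L) next
    nextClass <- nextClass + 1L
    classId[i] <- nextClass
    if (pair[i] != i) classId[pair[i]] <- nextClass
  }
  classId
}

#' Assign posture vectors to merged library classes
#'
#' Each posture is assigned to the nearest centroid (Euclidean distance in
#' 24-angle space) and reported as that centroid's merged class.
#'
#' @param library a [PostureLibrary-class].
#' @param postures numeric matrix (n x 24).
#' @return integer vector of merged class ids.
#' @export
assignPostures <- function(library, postures) {
  postures <- as.matrix(postures)
  cen <- centroids(library)
  # squared distances via the expansion trick
  d2 <- outer(rowSums(postures^2), rowSums(cen^2), "+") -
    2 * postures %*% t(cen)
  postureClasses(library)[max.col(-d2)]
}

#' Meta-posture groups: second-round clustering of pooled libraries
#'
#' Pools the merged-class representative angle vectors of one or more
#' posture libraries (all experimental conditions) and k-means-clusters
#' them into `k` coarse groups. With the default `k = 3` the groups
#' typically separate the stiff low-curvature postures from progressively
#' more bent ones.
#'
#' @param libraries a [PostureLibrary-class] or list of them.
#' @param k number of meta-posture groups.
#' @param seed RNG seed.
#' @return a [MetaPostureGroups-class].
#' @export
assignMetaPostures <- function(libraries, k = 3L, seed = 1L) {
  if (is(libraries, "PostureLibrary")) libraries <- list(libraries)
  reps <- do.call(rbind, lapply(libraries, classRepresentatives))
  cond <- unlist(lapply(libraries, function(l)
    rep(l@condition, nClasses(l))))
  if (nrow(reps) < k) stop("fewer pooled posture classes than groups")
  set.seed(seed)
  km <- if (nrow(reps) == k)                  # trivial: one class per group
    list(cluster = seq_len(k), centers = reps)
  else kmeans(reps, centers = k, nstart = 10L, iter.max = 50)
  # relabel groups by increasing mean absolute curvature for stable reporting
  ord <- order(rowMeans(abs(km$centers)))
  relabel <- match(seq_len(k), ord)
  new("MetaPostureGroups", group = relabel[km$cluster],
      centers = km$centers[ord, , drop = FALSE],
      representatives = reps, condition = cond)
}

#' Time-resolved posture-class abundance
#'
#' Bins assigned postures by hours-after-transfer, computes per-bin
#' relative class frequencies (rows sum to 1), and z-scores each class
#' (column) across time bins. Empty time bins yield rows of `NA` and are
#' flagged.
#'
#' @param classes integer vector of merged class ids (see
#'   [assignPostures()]).
#' @param hat numeric vector of hours after transfer, parallel to
#'   `classes`.
#' @param binHours width of the time bins (default 1 h).
#' @param nClasses total number of classes (defaults to `max(classes)`).
#' @return list with `raw` (bins x classes relative frequencies), `zscore`
#'   (per-class z-scores across bins), `n` (postures per bin), `binStart`
#'   (h.a.t. of each bin's left edge) and `empty` (logical flag per bin).
#' @export
abundanceOverTime <- function(classes, hat, binHours = 1,
                              nClasses = max(classes)) {
  bin <- floor(hat / binHours)
  binLevels <- seq(min(bin), max(bin))
  counts <- matrix(0, length(binLevels), nClasses,
                   dimnames = list(binLevels * binHours, seq_len(nClasses)))
  tab <- table(factor(bin, levels = binLevels),
               factor(classes, levels = seq_len(nClasses)))
  counts[] <- as.numeric(tab)
  n <- rowSums(counts)
  raw <- counts / ifelse(n > 0, n, NA)
  z <- apply(raw, 2, function(col) {
    s <- sd(col, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(col)) else
      (col - mean(col, na.rm = TRUE)) / s
  })
  z[is.na(raw)] <- NA
  list(raw = raw, zscore = z, n = n,
       binStart = binLevels * binHours, empty = n == 0)
}

#' Meta-posture relative occurrence over time
#'
#' Per-group occurrence per time bin, both raw (fraction of postures in the
#' bin belonging to the group) and normalized to the condition-wide mean
#' occurrence of that group across all time points.
#'
#' @param groups integer vector of meta-posture group ids per posture
#'   observation.
#' @param hat hours after transfer, parallel to `groups`.
#' @param binHours time-bin width in hours.
#' @param k number of groups.
#' @return list with `raw` and `normalized` (bins x groups matrices) and
#'   `binStart`.
#' @export
metaAbundanceOverTime <- function(groups, hat, binHours = 1, k = 3L) {
  ab <- abundanceOverTime(groups, hat, binHours, nClasses = k)
  colMean <- colMeans(ab$raw, na.rm = TRUE)
  norm <- sweep(ab$raw, 2, ifelse(colMean > 0, colMean, NA), "/")
  list(raw = ab$raw, normalized = norm, binStart = ab$binStart)
}
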