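# Eigenworms, posture libraries, mirror merging, meta-postures, abundance.

test_that("eigenworm eligibility applies the moving-worm filters", {
  expect_true(eligibleForEigenworms(6, 0.02, 10))
  expect_false(eligibleForEigenworms(6, 0.005, 10))   # speed must exceed 0.01
  expect_false(eligibleForEigenworms(4, 0.02, 10))    # at least 5 s
  expect_false(eligibleForEigenworms(6, 0.02, 50))    # angvel strictly below 50
  expect_true(eligibleForEigenworms(5, 0.011, 49.9))
})

test_that("two planted bend modes are recovered by the eigenworm basis", {
  X <- samplePostures(600, noiseSd = 0.01, seed = 2)
  ew <- computeEigenworms(X)
  expect_gte(varianceExplained(ew)[2], 0.99)
  expect_equal(sort(eigenvalues(ew), decreasing = TRUE), eigenvalues(ew))
  # principal angle between the top-2 subspace and the planted modes
  sv <- svd(crossprod(eigenworms(ew)[, 1:2], bendModes()))$d
  expect_lt(acos(min(pmin(sv, 1))) * 180 / pi, 10)
})

test_that("degenerate posture sets are flagged", {
  X <- matrix(0.3, 30, 24)
  expect_warning(ew <- computeEigenworms(X), "identical")
  expect_equal(ncol(eigenworms(ew)), 0)
  expect_warning(computeEigenworms(samplePostures(10, seed = 1)),
                 "rank deficient")
})

test_that("posture reconstruction from the full basis is exact", {
  X <- samplePostures(200, noiseSd = 0.3, seed = 3)
  ew <- computeEigenworms(X)
  scores <- projectPostures(ew, X)
  back <- reconstructPostures(ew, scores)
  expect_lt(max(abs(back - X)), 1e-9)
})

test_that("k-means recovers well-separated posture clusters", {
  set.seed(9)
  means <- rbind(0.8 * sin(2 * pi * (1:24) / 24),
                 0.8 * cos(2 * pi * (1:24) / 24),
                 rep(0.5, 24))
  lab <- sample(1:3, 900, replace = TRUE)
  X <- means[lab, ] + matrix(rnorm(900 * 24, 0, 0.05), 900, 24)
  lib <- buildPostureLibrary(X, k = 3, seed = 4, matchQuantile = 0)
  cen <- centroids(lib)
  # brute-force oracle: assign each point to the nearest true mean
  oracle <- apply(X, 1, function(v) which.min(colSums((t(means) - v)^2)))
  fit <- assignPostures(lib, X)
  agreement <- max(vapply(1:6, function(p) {
    perm <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))[p, ]
    mean(perm[fit] == oracle)
  }, numeric(1)))
  expect_gte(agreement, 0.99)
  for (j in 1:3)
    expect_lt(min(sqrt(colSums((t(cen) - means[j, ])^2))), 0.05)
  expect_error(buildPostureLibrary(X, k = 2000), "fewer posture vectors")
})

test_that("mirror pairing handles planted, degenerate and symmetric cases", {
  v <- sin(2 * pi * (1:24) / 24)
  w <- c(rep(1, 24))                          # far from its own negation
  pair <- findMirrorPairs(rbind(v, -v, w), matchQuantile = 0.999)
  expect_equal(pair, c(2L, 1L, 3L))

  nearZero <- matrix(rnorm(5 * 24, 0, 1e-4), 5, 24)
  expect_equal(findMirrorPairs(nearZero), 1:5)   # symmetric: all self-paired
})

test_that("mirror merging halves a negation-symmetric posture library", {
  X <- symmetricPostures(3000, seed = 6)
  counts <- vapply(1:3, function(s) {
    lib <- buildPostureLibrary(X, k = 60, seed = s, nstart = 5)
    paired <- sum(mirrorPairs(lib) != seq_along(mirrorPairs(lib)))
    expect_gte(paired / 60, 0.6)              # most centroids find a partner
    nClasses(lib)
  }, numeric(1))
  # merged class count stays within +-10% of k/2 across seeds
  expect_true(all(abs(counts - 30) <= 6))
})

test_that("mirror merging is involution-consistent under dataset negation", {
  X <- symmetricPostures(1500, seed = 8)
  a <- buildPostureLibrary(X, k = 40, seed = 2, nstart = 5)
  b <- buildPostureLibrary(-X, k = 40, seed = 2, nstart = 5)
  expect_equal(nClasses(a), nClasses(b))
})

test_that("library construction is reproducible under a fixed seed", {
  X <- samplePostures(800, seed = 10)
  a <- buildPostureLibrary(X, k = 25, seed = 3, nstart = 3)
  b <- buildPostureLibrary(X, k = 25, seed = 3, nstart = 3)
  expect_identical(centroids(a), centroids(b))
  expect_identical(postureClasses(a), postureClasses(b))
})

test_that("meta-postures recover planted curvature regimes", {
  set.seed(12)
  base <- abs(sin(2 * pi * (1:24) / 24))
  amps <- c(0.15, 0.8, 2.0)                   # low / medium / high curvature
  regime <- sample(1:3, 120, replace = TRUE)
  reps <- t(vapply(regime, function(g)
    amps[g] * base + rnorm(24, 0, 0.03 * amps[g] + 0.01), numeric(24)))
  lib <- new("PostureLibrary", condition = "pooled", centroids = reps,
             pairMap = seq_len(nrow(reps)), classId = seq_len(nrow(reps)),
             counts = rep(1L, nrow(reps)), seed = 1L)
  meta <- assignMetaPostures(lib, k = 3, seed = 5)
  expect_equal(length(unique(meta@group)), 3)
  agreement <- mean(meta@group == regime)     # groups ordered by curvature
  expect_gte(agreement, 0.9)
  # the low-curvature group has the tightest angle distribution
  iqrs <- vapply(1:3, function(g)
    IQR(meta@representatives[meta@group == g, ]), numeric(1))
  expect_equal(which.min(iqrs), 1L)
})

test_that("k = 3 meta-clustering of exactly 3 postures separates them", {
  reps <- rbind(rep(0.1, 24), rep(1, 24), rep(2.5, 24))
  lib <- new("PostureLibrary", condition = "x", centroids = reps,
             pairMap = 1:3, classId = 1:3, counts = rep(1L, 3), seed = 1L)
  meta <- assignMetaPostures(lib, k = 3, seed = 1)
  expect_setequal(meta@group, 1:3)
})

test_that("abundance matrices are conserved, z-scored and flag empty bins", {
  cls <- c(1, 2, 1, 2)
  hat <- c(0.2, 0.3, 1.4, 1.6)
  ab <- abundanceOverTime(cls, hat, binHours = 1)
  expect_equal(unname(ab$raw), matrix(0.5, 2, 2))
  expect_equal(unname(ab$zscore), matrix(0, 2, 2))
  expect_true(all(abs(rowSums(ab$raw, na.rm = TRUE) - 1) < 1e-12))

  # class present only in the first of four bins: positive z there only
  cls2 <- c(1, 2, 2, 2, 2)
  hat2 <- c(0.5, 0.6, 1.5, 2.5, 3.5)
  ab2 <- abundanceOverTime(cls2, hat2, binHours = 1)
  expect_gt(ab2$zscore[1, 1], 0)
  expect_true(all(ab2$zscore[2:4, 1] < 0))

  # empty middle bin is NA and flagged
  ab3 <- abundanceOverTime(c(1, 1), c(0.1, 2.5), binHours = 1, nClasses = 1)
  expect_true(ab3$empty[2])
  expect_true(is.na(ab3$raw[2, 1]))
})

test_that("a scripted posture-regime switch flips abundance z-scores", {
  set.seed(14)
  # classes 1 and 2 swap dominance at hour 3 of 6
  hat <- runif(4000, 0, 6)
  cls <- ifelse(hat < 3,
                ifelse(runif(4000) < 0.9, 1, 2),
                ifelse(runif(4000) < 0.9, 2, 1))
  ab <- abundanceOverTime(cls, hat, binHours = 1)
  expect_true(all(ab$zscore[1:3, 1] > 0) && all(ab$zscore[4:6, 1] < 0))
  expect_true(all(ab$zscore[1:3, 2] < 0) && all(ab$zscore[4:6, 2] > 0))

  meta <- metaAbundanceOverTime(cls, hat, binHours = 1, k = 2)
  expect_true(all(abs(colMeans(meta$normalized, na.rm = TRUE) - 1) < 1e-9))
})
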