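# Thinning, skeleton validation, head assignment and posture angles.

test_that("thinning a rectangle yields a straight unbranched path", {
  bar <- matrix(FALSE, 20, 50)
  bar[9:11, 5:45] <- TRUE
  sk <- skeletonizeMask(bar)
  v <- validateSkeleton(sk)
  expect_true(v$valid)
  expect_gte(v$arcLength, 36)
  expect_lte(v$arcLength, 41)
  expect_true(all(v$path[, 2] %in% 9:11))
  expect_error(skeletonizeMask(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton validation rejects short, branched and looped skeletons", {
  short <- matrix(FALSE, 10, 40); short[5, 8:32] <- TRUE   # 25 px arc 24
  v <- validateSkeleton(skeletonizeMask(short))
  expect_false(v$valid)
  expect_equal(v$reason, "too_short")

  ys <- matrix(FALSE, 60, 60)                 # Y: three 20-px arms
  ys[30, 10:30] <- TRUE
  for (i in 1:15) { ys[30 - i, 30 + i] <- TRUE; ys[30 + i, 30 + i] <- TRUE }
  vy <- validateSkeleton(ys)
  expect_false(vy$valid)
  expect_equal(vy$reason, "branched")

  arc <- matrix(FALSE, 50, 50)                # simple diagonal-ish arc, 30 px
  for (i in 0:29) arc[10 + round(i * 0.5), 10 + i] <- TRUE
  va <- validateSkeleton(arc)
  expect_true(va$valid)

  omega <- renderTurnShape(2 * pi)            # self-overlapping: loop or branch
  vo <- validateSkeleton(skeletonizeMask(omega$mask))
  expect_false(vo$valid)
})

test_that("motion-based head assignment follows the direction of movement", {
  path <- cbind(x = 10:40, y = 5)
  a <- assignHead(path, displacement = c(2, 0))
  expect_equal(a$source, "motion")
  expect_equal(unname(a$path[1, 1]), 40)      # head = endpoint at x = 40

  b <- assignHead(path, displacement = c(0.2, 0))   # below confidence floor
  expect_equal(b$source, "unresolved")

  c2 <- assignHead(path, displacement = c(0, 3))    # motion orthogonal to body
  expect_equal(c2$source, "unresolved")
})

test_that("unresolved frames inherit orientation from adjacent frames", {
  paths <- list(cbind(x = 10:40, y = 5), cbind(x = 11:41, y = 5),
                cbind(x = 12:42, y = 5))
  centroids <- cbind(c(25, 26, 27), c(5, 5, 5))  # 1 px/frame: below floor...
  centroids <- cbind(c(25, 28, 31), c(5, 5, 5))  # 3 px/frame: resolvable
  out <- orientTrackSkeletons(paths, centroids)
  expect_true(all(vapply(out, function(o) o$keep, logical(1))))
  # now a stationary middle frame between oriented ones
  out2 <- orientTrackSkeletons(
    list(cbind(x = 10:40, y = 5), cbind(x = c(40:10), y = 5.5),
         cbind(x = 12:42, y = 5)),
    cbind(c(25, 25.05, 27), c(5, 5.5, 5)))
  expect_equal(out2[[2]]$source, "adjacent_frame")
  expect_equal(unname(out2[[2]]$path[1, 1]), 40)  # end nearest the known head
  # isolated stationary track: discarded
  out3 <- orientTrackSkeletons(list(cbind(x = 10:40, y = 5)),
                               cbind(25, 5))
  expect_false(out3[[1]]$keep)
})

test_that("posture vectors have 24 angles, zero for straight worms", {
  straight <- cbind(seq(0, 59, length.out = 40), 0)
  a <- postureAngles(straight)
  expect_length(a, 24)
  expect_true(all(abs(a) < 1e-9))
  expect_true(all(abs(a) < pi))
})

test_that("a semicircular arc gives uniform analytic intersegment angles", {
  # 26 equally spaced points on a semicircle: consecutive equal chords
  # subtend pi/25 each, so every intersegment angle is 180/25 = 7.2 deg
  th <- seq(0, pi, length.out = 26)
  semi <- cbind(100 * cos(th), 100 * sin(th))
  a <- postureAngles(semi, smoothing = "none")
  expect_equal(a, rep(pi / 25, 24), tolerance = 1e-9)
  expect_equal(sum(a) * 180 / pi, 172.8, tolerance = 1e-6)
})

test_that("mirrored bitmasks give exactly negated posture vectors", {
  sh <- renderTurnShape(1.8, wormLength = 50)  # bent but not self-contacting
  sk <- skeletonizeMask(sh$mask)
  v <- validateSkeleton(sk)
  expect_true(v$valid)
  a <- postureAngles(v$path, mask = sh$mask)

  mmask <- sh$mask[, rev(seq_len(ncol(sh$mask)))]       # left-right flip
  skm <- skeletonizeMask(mmask)
  vm <- validateSkeleton(skm)
  pm <- vm$path
  # keep the same head end after mirroring (match by mirrored x)
  if (abs((ncol(sh$mask) + 1 - vm$path[1, 1]) - v$path[1, 1]) >
      abs((ncol(sh$mask) + 1 - vm$path[nrow(vm$path), 1]) - v$path[1, 1]))
    pm <- pm[rev(seq_len(nrow(pm))), ]
  am <- postureAngles(pm, mask = mmask)
  expect_equal(am, -a, tolerance = 1e-8)
})

test_that("posture angles are invariant to translation and rotation", {
  set.seed(3)
  th <- cumsum(c(0.3, rnorm(39, 0, 0.08)))
  path <- cbind(cumsum(cos(th)), cumsum(sin(th)))     # continuous coordinates
  a0 <- postureAngles(path)
  for (ang in runif(10, -pi, pi)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    moved <- sweep(path %*% R, 2, c(-17, 230), "+")
    expect_equal(postureAngles(moved), a0, tolerance = 1e-6)
  }
})

test_that("rotating a rendered worm changes pixel-path angles only slightly", {
  bend <- seq(-0.45, 0.45, length.out = 25)
  angsAt <- function(rot) {
    ml <- wormplate:::.midlineFromBend(c(70, 70), rot, bend, 60)
    mask <- wormplate:::.renderMidline(matrix(1, 140, 140), ml, 5, 0) == 0
    v <- validateSkeleton(skeletonizeMask(mask))
    a <- postureAngles(v$path, mask = mask)
    if (sum(a) < 0) -rev(a) else a            # canonical orientation
  }
  a0 <- angsAt(0)
  set.seed(8)
  for (rot in runif(4, -pi, pi)) {
    d <- abs(angsAt(rot) - a0)
    expect_lt(median(d), 0.05)                # pixelation-level tolerance
    expect_lt(max(d), 0.2)
  }
})

test_that("summed angles telescope to the total heading change", {
  set.seed(5)
  th <- cumsum(c(0.2, rnorm(39, 0, 0.1)))
  path <- cbind(cumsum(cos(th)), cumsum(sin(th)))
  pts <- resamplePath(path, 26)
  a <- chordAngles(pts)
  d <- diff(pts)
  h <- atan2(d[, 2], d[, 1])
  expect_equal(sum(a), wormplate:::wrapAngle(h[25] - h[1]), tolerance = 1e-9)
})

test_that("recovered posture vectors track ground truth on simulated worms", {
  cfg <- sceneConfig(nWorms = 3, duration = 30, imageSize = 360, seed = 11,
                     bendScalePerState = c(quiescent = 0.4, dispersal = 1.0,
                                           dwelling = 1.0))
  sim <- simulatePlate(cfg)
  det <- segmentStack(sim$frames)
  tr <- filterTracks(linkTracks(det, 60), 20)
  po <- do.call(rbind, lapply(split(tr, tr$track_id), function(td) {
    td <- td[order(td$frame), ]
    cbind(track_id = td$track_id[1], trackPostures(td))
  }))
  ok <- po[po$valid, ]
  expect_gt(nrow(ok), 20)
  cors <- vapply(seq_len(nrow(ok)), function(i) {
    r <- ok[i, ]
    td <- tr[tr$track_id == r$track_id & tr$frame == r$frame, ]
    tt <- sim$truth[sim$truth$frame == r$frame, ]
    w <- which.min((tt$x - td$x)^2 + (tt$y - td$y)^2)
    if (!tt$visible[w]) return(NA_real_)
    cor(as.numeric(tt[w, paste0("a", 1:24)]),
        as.numeric(r[paste0("a", 1:24)]))
  }, numeric(1))
  cors <- cors[!is.na(cors)]
  # binary masks of 5-px-wide worms limit per-frame fidelity; the bulk of
  # frames must still recover the posture faithfully, head included
  expect_gt(median(cors), 0.9)
  expect_gt(mean(cors > 0), 0.95)             # orientation almost always right
})
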