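# Track linking, filtering and kinematics.

test_that("two distant worms give exactly two full-length tracks", {
  det <- syntheticDetections(list(
    data.frame(frame = 1:100, x = 10 + (1:100) * 0.5, y = 20),
    data.frame(frame = 1:100, x = 300 - (1:100) * 0.5, y = 280)))
  tr <- linkTracks(det, maxLinkDistance = 30)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 100))
})

test_that("a one-frame disappearance splits the track (no gap closing)", {
  det <- data.frame(frame = c(1:10, 12:20), x = 50, y = 50, area = 300)
  tr <- linkTracks(det, maxLinkDistance = 30)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("empty detection input gives an empty track list", {
  det <- syntheticDetections(list())[0, ]
  det <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                    area = numeric())
  tr <- linkTracks(det)
  expect_equal(nrow(tr), 0)
  expect_true("track_id" %in% names(tr))
})

test_that("crossing-distance gate starts a new track", {
  det <- data.frame(frame = 1:2, x = c(10, 200), y = 10, area = 300)
  tr <- linkTracks(det, maxLinkDistance = 50)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("track filter enforces the 20-frame minimum and moving-only rule", {
  short <- data.frame(track_id = 1L, frame = 1:19, x = 1:19 * 3, y = 0)
  long <- data.frame(track_id = 2L, frame = 1:20, x = 1:20 * 6, y = 0)
  still <- data.frame(track_id = 3L, frame = 1:100, x = 50, y = 50)
  tracks <- rbind(short, long, still)
  kept <- filterTracks(tracks, minFrames = 20)
  expect_setequal(unique(kept$track_id), c(2L, 3L))
  kept2 <- filterTracks(tracks, minFrames = 20, movingOnly = TRUE,
                        wormLength = 60)
  expect_equal(unique(kept2$track_id), 2L)    # displacement 114 px > 30 px
})

test_that("a straight mover recovers speed exactly and near-zero turning", {
  # 2 px/frame at 2 fps and 6.25 um/px -> 0.025 mm/s
  tr <- data.frame(track_id = 1L, frame = 1:40, x = (1:40) * 2, y = 7)
  kin <- computeKinematics(tr, pixelSize = 6.25, frameRate = 2)
  expect_equal(nrow(kin), 2)
  expect_equal(kin$speed, c(0.025, 0.025), tolerance = 1e-12)
  expect_equal(kin$angvel, c(0, 0), tolerance = 1e-9)
})

test_that("a circular path recovers the analytic angular velocity", {
  # heading rotates 10 deg/frame at 2 fps -> 20 deg/s
  theta <- (1:40) * 10 * pi / 180
  r <- 2 / (2 * sin(5 * pi / 180))            # radius for 2 px steps
  tr <- data.frame(track_id = 1L, frame = 1:40,
                   x = r * cos(theta), y = r * sin(theta))
  kin <- computeKinematics(tr, pixelSize = 6.25, frameRate = 2)
  expect_equal(kin$angvel, rep(20, nrow(kin)), tolerance = 1e-9)
  expect_equal(kin$speed, rep(0.025, nrow(kin)), tolerance = 1e-12)
})

test_that("a stationary track reports zero speed and a flagged angvel", {
  tr <- data.frame(track_id = 1L, frame = 1:20, x = 5, y = 5)
  kin <- computeKinematics(tr)
  expect_equal(kin$speed, 0)
  expect_equal(kin$angvel, 0)
  expect_false(kin$angvelDefined)
})

test_that("reported speed is linear in the pixel calibration", {
  tr <- data.frame(track_id = 1L, frame = 1:20, x = (1:20) * 1.7, y = 0)
  k1 <- computeKinematics(tr, pixelSize = 6.25)
  k2 <- computeKinematics(tr, pixelSize = 12.5)
  expect_equal(k2$speed, 2 * k1$speed)
})

test_that("kinematics on ground-truth centroids recover state speeds within 5%", {
  for (state in c("dispersal", "dwelling")) {
    cfg <- simConfig(imageSize = 3000, nWorms = 4, duration = 120,
                     wormLength = 40, rngSeed = 21, turnProbability = 0,
                     stateSchedule = data.frame(time = 0, state = state))
    truth <- simulatePlate(cfg, render = FALSE)$truth
    kin <- computeKinematics(groundTruthTracks(truth))
    m <- mean(kin$speed[kin$nFrames == 20])
    expect_lt(abs(m - cfg@speedPerState[state]) / cfg@speedPerState[state],
              0.05)
  }
})

test_that("track purity is 1 for well-separated simulated worms", {
  cfg <- sceneConfig(nWorms = 4, duration = 30, imageSize = 420, seed = 17)
  sim <- simulatePlate(cfg)
  det <- segmentStack(sim$frames)
  tr <- filterTracks(linkTracks(det, maxLinkDistance = 60), minFrames = 20)
  for (id in unique(tr$track_id)) {
    ti <- tr[tr$track_id == id, ]
    worms <- vapply(seq_len(nrow(ti)), function(j) {
      tt <- sim$truth[sim$truth$frame == ti$frame[j], ]
      tt$worm[which.min((tt$x - ti$x[j])^2 + (tt$y - ti$y[j])^2)]
    }, numeric(1))
    expect_equal(length(unique(worms)), 1)    # no identity swaps
  }
})

test_that("settling-period discard drops bins before 0.5 h inclusive boundary", {
  bins <- data.frame(track_id = 1, bin = 1:3, speed = 0, angvel = 0,
                     hat = c(0.4, 0.5, 0.6))
  out <- discardSettlingPeriod(bins)
  expect_equal(out$hat, c(0.5, 0.6))
  expect_equal(nrow(discardSettlingPeriod(bins[0, ])), 0)
})

test_that("frame decimation resamples 5 fps to 2 fps by nearest timestamp", {
  arr <- array(rep(seq(0, 1, length.out = 50), each = 4), c(2, 2, 50))
  fs <- frameStack(arr, pixelSize = 6.25, frameRate = 5)
  dec <- decimateFrames(fs, 2)
  expect_equal(frameRate(dec), 2)
  # nearest-timestamp decimation of a 0.2-s grid onto a 0.5-s grid
  # alternates 0.4/0.6-s gaps around the exact mean of 0.5 s
  expect_equal(mean(diff(timestamps(dec))), 0.5, tolerance = 0.05)
  expect_lt(abs(nFrames(dec) - 20), 2)
  expect_error(decimateFrames(dec, 5), "exceeds")
})
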