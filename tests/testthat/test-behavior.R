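# Dispersal classification, kinematic densities, turn detection.

test_that("dispersal truth table matches the printed thresholds", {
  expect_equal(classifyDispersal(0.02, 5), "dispersal")
  expect_equal(classifyDispersal(0.005, 5), "non_dispersal")
  expect_equal(classifyDispersal(0.02, 20), "non_dispersal")
  expect_equal(classifyDispersal(0.005, 20), "non_dispersal")
  # boundaries: speed floor inclusive, angvel ceiling strict
  expect_equal(classifyDispersal(0.01, 5), "dispersal")
  expect_equal(classifyDispersal(0.01, 15), "non_dispersal")
  expect_equal(classifyDispersal(0.009999, 14.9), "non_dispersal")
  expect_true(isQuiescent(0.005))
  expect_false(isQuiescent(0.02))
})

test_that("speed/angular-velocity density is a normalized histogram", {
  one <- speedAngvelDensity(0.012, 7)
  expect_equal(sum(one$density), 1)
  expect_equal(max(one$density), 1)           # single bin, single cell
  expect_error(speedAngvelDensity(numeric(0), numeric(0)), "at least one")

  set.seed(3)
  n <- 400
  speed <- c(abs(rnorm(n, 0.002, 0.001)), rnorm(n, 0.03, 0.004))
  angvel <- c(runif(n, 40, 90), abs(rnorm(n, 7, 3)))
  d <- speedAngvelDensity(speed, angvel)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  # bimodal: mass concentrated in low-speed/high-angvel and
  # high-speed/low-angvel corners
  lowS <- d$speedBreaks[-length(d$speedBreaks)] < 0.01
  lowA <- d$angvelBreaks[-length(d$angvelBreaks)] < 15
  expect_gt(sum(d$density[lowS, !lowA]), 0.4)
  expect_gt(sum(d$density[!lowS, lowA]), 0.4)
})

test_that("shape features separate straight from self-contacting shapes", {
  straight <- renderTurnShape(0.3)
  omega <- renderTurnShape(2 * pi)
  fs <- extractTurnFeatures(straight$mask)
  fo <- extractTurnFeatures(omega$mask)
  expect_length(fs, 17)
  expect_named(fs)
  expect_true(all(is.finite(fs)) && all(is.finite(fo)))
  expect_gt(fs["eccentricity"], 0.9)
  expect_lt(fo["solidity"], fs["solidity"])
  expect_gt(fs["endToEndRatio"], fo["endToEndRatio"])
  expect_identical(fs, extractTurnFeatures(straight$mask))  # deterministic
  expect_error(extractTurnFeatures(matrix(FALSE, 4, 4)), "empty")
})

test_that("turn classifier reaches high held-out accuracy and is seeded", {
  shapes <- makeTurnShapeSet(150, 150, seed = 21)
  fm <- turnFeatureMatrix(shapes$masks)
  clf <- trainTurnClassifier(fm, shapes$turn, nTrees = 300, seed = 7)
  expect_gte(clf@heldOutAccuracy, 0.9)
  p1 <- predictTurns(clf, fm)
  clf2 <- trainTurnClassifier(fm, shapes$turn, nTrees = 300, seed = 7)
  expect_identical(p1, predictTurns(clf2, fm))
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_error(trainTurnClassifier(fm, rep(TRUE, nrow(fm))), "both")
})

test_that("turn classifier precision and recall hold across training seeds", {
  shapes <- makeTurnShapeSet(150, 150, seed = 22)
  fm <- turnFeatureMatrix(shapes$masks)
  for (seed in 1:5) {
    clf <- trainTurnClassifier(fm, shapes$turn, nTrees = 300, seed = seed)
    set.seed(100 + seed)                      # fresh shapes as held-out set
    test <- makeTurnShapeSet(60, 60, seed = 100 + seed)
    pred <- predictTurns(clf, turnFeatureMatrix(test$masks))$turn == 1
    precision <- sum(pred & test$turn) / sum(pred)
    recall <- sum(pred & test$turn) / sum(test$turn)
    expect_gte(precision, 0.85)
    expect_gte(recall, 0.85)
  }
})

test_that("uninformative features are flagged as no-signal", {
  fm <- matrix(1, 60, 17, dimnames = list(NULL, paste0("f", 1:17)))
  labels <- rep(c(TRUE, FALSE), 30)
  expect_warning(clf <- trainTurnClassifier(fm, labels, nTrees = 50, seed = 1),
                 "little signal")
  expect_lt(abs(clf@heldOutAccuracy - 0.5), 0.3)
})

test_that("turn flags are counted once per 10-s window", {
  expect_equal(binTurns(c(rep(1, 7), rep(0, 13)), frameRate = 2), 1L)
  expect_equal(binTurns(rep(0, 40), frameRate = 2), c(0L, 0L))
  flags <- rep(0, 60)
  flags[3] <- 1; flags[45] <- 1               # windows 1 and 3 of 3
  expect_equal(binTurns(flags, frameRate = 2), c(1L, 0L, 1L))
})

test_that("condition summaries aggregate dispersal, speed and turns", {
  rec <- data.frame(track_id = rep(1:2, each = 3),
                    speed = c(0.01, 0.01, 0.01, 0.03, 0.03, 0.03),
                    angvel = 5, hat = rep(c(0.5, 1.5, 2.5), 2),
                    turn = c(0, 1, 0, 0, 0, 0))
  s <- summarizeCondition(rec, gridHours = 1)
  expect_equal(s$timeSeries$dispersalFraction, c(1, 1, 1))
  expect_equal(sort(s$trackMeanSpeed$meanSpeed), c(0.01, 0.03))
  expect_equal(s$timeSeries$turnFrequency[2], 0.5)
})

test_that("recovered dispersal fraction matches the simulated state mixture", {
  cfg <- simConfig(imageSize = 5000, nWorms = 30, duration = 180,
                   wormLength = 40, rngSeed = 31)
  truth <- simulatePlate(cfg, render = FALSE)$truth
  kin <- computeKinematics(groundTruthTracks(truth))
  kin <- kin[kin$nFrames == 20, ]
  expect_gt(nrow(kin), 500)
  state <- classifyDispersal(kin$speed, kin$angvel)
  # oracle: fraction of 10-s windows whose dominant true state is dispersal
  truth$bin <- (truth$frame - 1) %/% 20
  q <- mean(vapply(split(truth$state, paste(truth$worm, truth$bin)),
                   function(s) mean(s == "dispersal") > 0.5, logical(1)))
  pHat <- mean(state == "dispersal")
  se <- sqrt(q * (1 - q) / nrow(kin))
  # mixed-state windows blur the margin beyond pure binomial error
  expect_lt(abs(pHat - q), max(2 * se, 0.04))
})

test_that("Mann-Whitney speed comparisons are calibrated under the null", {
  set.seed(41)
  pvals <- vapply(1:200, function(i) {
    a <- rexp(30, 50); b <- rexp(30, 50)      # equal speed distributions
    wilcox.test(a, b)$p.value
  }, numeric(1))
  rejection <- mean(pvals < 0.05)
  expect_lt(abs(rejection - 0.05), 0.03)
  # normal-approximation p-values tie occasionally; the KS check is
  # indicative of uniformity, ties only make it conservative
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})
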