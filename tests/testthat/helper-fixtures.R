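# Shared fixtures: synthetic posture clouds and small simulator scenes.

# two orthonormal smooth bend modes in 24-angle space
bendModes <- function() {
  qr.Q(qr(cbind(sin(2 * pi * 1.5 * (1:24) / 24),
                sin(2 * pi * 2.5 * (1:24) / 24))))
}

# posture vectors sampled from a 2-mode mixture with additive noise
samplePostures <- function(n, noiseSd = 0.1, modeSd = c(1.2, 0.8), seed = 1) {
  set.seed(seed)
  modes <- bendModes()
  scores <- matrix(rnorm(n * 2), n, 2) %*% diag(modeSd)
  scores %*% t(modes) + matrix(rnorm(n * 24, 0, noiseSd), n, 24)
}

# negation-symmetric posture set: every vector accompanied by its negation
symmetricPostures <- function(n, noiseSd = 0.1, seed = 1) {
  X <- samplePostures(n, noiseSd, seed = seed)
  rbind(X, -X)
}

# single-state rendered scene used by segmentation/tracking/skeleton tests
sceneConfig <- function(state = "dispersal", nWorms = 4, duration = 30,
                        imageSize = 360, wormLength = 60, seed = 5, ...) {
  simConfig(imageSize = imageSize, nWorms = nWorms, duration = duration,
            wormLength = wormLength, rngSeed = seed,
            stateSchedule = data.frame(time = 0, state = state), ...)
}

# synthetic detection table for linking tests: one row per worm per frame
syntheticDetections <- function(paths) {
  do.call(rbind, lapply(seq_along(paths), function(w) {
    p <- paths[[w]]
    data.frame(frame = p$frame, x = p$x, y = p$y, area = 300)
  }))
}
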