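# End-to-end orchestration, configuration and file I/O.

#' Build a pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the standard
#' analysis: 6.25 um/px at 2 fps, 20-frame minimum gap-free tracks (10 s),
#' 10-s kinematics bins, 30-min settling discard, 26-px minimum skeletons,
#' k = 200 posture clusters with k = 3 meta-postures, and dispersal
#' thresholds of 0.01 mm/s and 15 deg/s. The configuration round-trips
#' losslessly through YAML ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param input `NULL` (simulate) or path to a multi-page TIFF / directory
#'   of numbered PNGs.
#' @param sim a [SimConfig-class] used when `input` is `NULL`.
#' @param pixelSize,frameRate calibration of the input frames.
#' @param wormLength,wormWidth expected worm geometry (px), used for
#'   segmentation bounds and link distance.
#' @param thresholdSd,smoothingSigma segmentation parameters.
#' @param maxLinkDistance linking gate (px); default one body length.
#' @param minTrackSeconds minimum gap-free track duration (s); the frame
#'   minimum is `minTrackSeconds * frameRate` (20 frames at 2 fps).
#' @param binSeconds kinematics bin width (s).
#' @param settlingMinutes initial period to discard (min).
#' @param skeletonMinLength minimum skeleton arc length (px).
#' @param postureK,metaK clustering sizes.
#' @param dispersalMinSpeed,dispersalMaxAngvel dispersal thresholds.
#' @param turnTrees,turnThreshold turn-classifier parameters.
#' @param noPosture skip the posture stages.
#' @param condition condition label.
#' @param seed run seed.
#' @return named list of class `wormplateRunConfig`.
#' @export
runConfig <- function(input = NULL, sim = simConfig(),
                      pixelSize = 6.25, frameRate = 2,
                      wormLength = 60, wormWidth = 5,
                      thresholdSd = 5, smoothingSigma = 1,
                      maxLinkDistance = wormLength,
                      minTrackSeconds = 10, binSeconds = 10,
                      settlingMinutes = 30, skeletonMinLength = 26,
                      postureK = 200L, metaK = 3L,
                      dispersalMinSpeed = 0.01, dispersalMaxAngvel = 15,
                      turnTrees = 500L, turnThreshold = 0.5,
                      noPosture = FALSE, condition = "default", seed = 1L) {
  cfg <- list(input = input, sim = sim, pixelSize = pixelSize,
              frameRate = frameRate, wormLength = wormLength,
              wormWidth = wormWidth, thresholdSd = thresholdSd,
              smoothingSigma = smoothingSigma,
              maxLinkDistance = maxLinkDistance,
              minTrackSeconds = minTrackSeconds,
              minTrackFrames = as.integer(round(minTrackSeconds * frameRate)),
              binSeconds = binSeconds, settlingMinutes = settlingMinutes,
              skeletonMinLength = skeletonMinLength,
              postureK = as.integer(postureK), metaK = as.integer(metaK),
              dispersalMinSpeed = dispersalMinSpeed,
              dispersalMaxAngvel = dispersalMaxAngvel,
              turnTrees = as.integer(turnTrees),
              turnThreshold = turnThreshold, noPosture = noPosture,
              condition = condition, seed = as.integer(seed))
  class(cfg) <- "wormplateRunConfig"
  cfg
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config a run configuration from [runConfig()].
#' @param path file path.
#' @return `readRunConfig` returns the restored configuration.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  if (is(cfg$sim, "SimConfig")) {
    s <- cfg$sim
    cfg$sim <- lapply(setNames(slotNames(s), slotNames(s)), function(n) {
      v <- slot(s, n)
      if (is.matrix(v)) list(.matrix = as.numeric(v), .nrow = nrow(v),
                             .names = rownames(v))
      else if (is.atomic(v) && !is.null(names(v))) as.list(v)
      else v
    })
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    s <- cfg$sim
    fix <- function(v) {
      if (is.list(v) && !is.null(v$.matrix))
        matrix(v$.matrix, v$.nrow, dimnames = list(v$.names, v$.names))
      else if (is.list(v)) unlist(v) else v
    }
    cfg$sim <- simConfig(
      imageSize = s$imageSize, pixelSize = s$pixelSize,
      frameRate = s$frameRate, nWorms = s$nWorms, duration = s$duration,
      wormLength = s$wormLength, wormWidth = s$wormWidth,
      backgroundLevel = s$backgroundLevel, noiseSd = s$noiseSd,
      contrast = s$contrast, transitionRates = fix(s$transitionRates),
      speedPerState = fix(s$speedPerState),
      headingPersistence = fix(s$headingPersistence),
      bendModeAmplitudes = fix(s$bendModeAmplitudes),
      bendScalePerState = fix(s$bendScalePerState),
      waveSpeed = s$waveSpeed, turnProbability = s$turnProbability,
      turnDuration = s$turnDuration,
      stateSchedule = if (is.null(s$stateSchedule)) NULL else
        as.data.frame(s$stateSchedule),
      startTime = s$startTime, rngSeed = s$rngSeed)
  }
  cfg$minTrackFrames <- as.integer(cfg$minTrackFrames)
  for (n in c("postureK", "metaK", "turnTrees", "seed"))
    cfg[[n]] <- as.integer(cfg[[n]])
  class(cfg) <- "wormplateRunConfig"
  cfg
}

#' Read a calibrated frame stack from disk
#'
#' Supports a multi-page TIFF file or a directory of consecutively numbered
#' PNG frames (`<name><number>.png`); a gap in the numbering is an error
#' naming the missing index.
#'
#' @param path TIFF file or PNG directory.
#' @param pixelSize micrometres per pixel (required).
#' @param frameRate frames per second (required).
#' @param startTime seconds after transfer of the first frame.
#' @return a [FrameStack-class].
#' @export
readFrames <- function(path, pixelSize, frameRate, startTime = 0) {
  if (missing(pixelSize) || is.null(pixelSize))
    stop("missing calibration: pixelSize (um/px) is required")
  if (missing(frameRate) || is.null(frameRate))
    stop("missing calibration: frameRate (frames/s) is required")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (!length(files)) stop("no PNG frames found in ", path)
    nums <- as.integer(gsub("\\D", "", basename(files)))
    o <- order(nums)
    files <- files[o]; nums <- nums[o]
    expected <- seq(nums[1], nums[length(nums)])
    missingIdx <- setdiff(expected, nums)
    if (length(missingIdx))
      stop("gap in PNG numbering: missing index ",
           paste(missingIdx, collapse = ", "))
    imgs <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3) im <- im[, , 1]
      im
    })
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    imgs <- lapply(imgs, function(im) if (length(dim(im)) == 3) im[, , 1] else im)
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed image sizes across frames")
  arr <- array(unlist(imgs), c(dims[1, 1], dims[2, 1], length(imgs)))
  frameStack(arr, pixelSize = pixelSize, frameRate = frameRate,
             startTime = startTime)
}

#' Write a frame stack to disk
#'
#' @param stack a [FrameStack-class].
#' @param path output path: `.tif`/`.tiff` writes a multi-page TIFF, a
#'   directory writes numbered PNGs.
#' @return invisibly, the written path.
#' @export
writeFrames <- function(stack, path) {
  arr <- frames(stack)
  if (grepl("\\.tiff?$", path)) {
    tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(i)
      pmin(pmax(arr[, , i], 0), 1)), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(dim(arr)[3]))
      png::writePNG(pmin(pmax(arr[, , i], 0), 1),
                    file.path(path, sprintf("frame%05d.png", i)))
  }
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate (or read) -> background -> segment -> link -> filter ->
#' kinematics -> skeletonize/orient/postures -> posture library ->
#' behavior summary, with no user intervention. All stages honor the run
#' configuration and the run seed; a rerun with identical inputs and seed
#' produces identical outputs.
#'
#' @param config from [runConfig()].
#' @param outDir optional output directory; when given, [writeResults()] is
#'   called on the bundle.
#' @return a result bundle (list): config, truth (simulations only),
#'   detections, tracks, kinematics, postures, library, eigenworms,
#'   abundance, behavior.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "wormplateRunConfig"))
  set.seed(config$seed)
  truth <- NULL
  if (is.null(config$input)) {
    sim <- simulatePlate(config$sim)
    stack <- sim$frames
    truth <- sim$truth
  } else {
    stack <- readFrames(config$input, pixelSize = config$pixelSize,
                        frameRate = config$frameRate)
  }
  params <- segmentParams(config$wormLength, config$wormWidth,
                          config$thresholdSd, config$smoothingSigma)
  detections <- segmentStack(stack, params = params)
  tracks <- linkTracks(detections, maxLinkDistance = config$maxLinkDistance)
  tracks <- filterTracks(tracks, minFrames = config$minTrackFrames,
                         movingOnly = FALSE, wormLength = config$wormLength)
  kin <- computeKinematics(tracks, pixelSize = pixelSize(stack),
                           frameRate = frameRate(stack),
                           binSeconds = config$binSeconds,
                           startTime = timestamps(stack)[1])
  kin <- discardSettlingPeriod(kin, config$settlingMinutes)

  postures <- NULL; library <- NULL; basis <- NULL; abundance <- NULL
  if (!config$noPosture && nrow(tracks)) {
    postures <- do.call(rbind, lapply(split(tracks, tracks$track_id),
      function(td) {
        td <- td[order(td$frame), , drop = FALSE]
        cbind(track_id = td$track_id[1],
              trackPostures(td, minLength = config$skeletonMinLength))
      }))
    rownames(postures) <- NULL
    ok <- postures[postures$valid, , drop = FALSE]
    if (nrow(ok)) {
      X <- as.matrix(ok[, paste0("a", 1:24)])
      basis <- computeEigenworms(X)
      if (nrow(X) >= config$postureK) {
        library <- buildPostureLibrary(X, k = config$postureK,
                                       condition = config$condition,
                                       seed = config$seed)
        cls <- assignPostures(library, X)
        hat <- (timestamps(stack)[1] + (ok$frame - 1) / frameRate(stack)) / 3600
        abundance <- abundanceOverTime(cls, hat,
                                       binHours = max(1 / 60, config$binSeconds / 3600),
                                       nClasses = nClasses(library))
      }
    }
  }

  behavior <- if (nrow(kin)) summarizeCondition(kin, gridHours = 1 / 6) else NULL
  bundle <- list(config = config, truth = truth, detections = detections,
                 tracks = tracks, kinematics = kin, postures = postures,
                 eigenworms = basis, library = library,
                 abundance = abundance, behavior = behavior)
  if (!is.null(outDir)) writeResults(bundle, outDir)
  bundle
}

#' Write a result bundle to CSV files
#'
#' Emits per-video result tables (one row per tracked worm per frame with
#' ID, position, track statistics, RLE-encoded bitmask and skeleton), the
#' kinematics bins, posture vectors, library centroids, abundance matrices,
#' behavior summary, the run configuration (YAML) and a provenance sidecar
#' (config hash, seed, package version).
#'
#' @param bundle result list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeResults <- function(bundle, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  cfgPath <- file.path(dir, "run_config.yaml")
  writeRunConfig(bundle$config, cfgPath)

  tr <- bundle$tracks
  if (!is.null(tr) && nrow(tr)) {
    tr2 <- tr
    tr2$mask <- vapply(tr$mask, encodeMask, character(1))
    write.csv(tr2, file.path(dir, "result_table.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$kinematics))
    write.csv(bundle$kinematics, file.path(dir, "kinematics.csv"),
              row.names = FALSE)
  if (!is.null(bundle$truth))
    write.csv(bundle$truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  if (!is.null(bundle$postures))
    write.csv(bundle$postures, file.path(dir, "postures.csv"),
              row.names = FALSE)
  if (!is.null(bundle$library)) {
    lib <- bundle$library
    libDf <- data.frame(centroid = seq_len(nrow(centroids(lib))),
                        mirrorPartner = mirrorPairs(lib),
                        classId = postureClasses(lib), count = lib@counts,
                        centroids(lib))
    write.csv(libDf, file.path(dir, "posture_library.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$eigenworms)) {
    ew <- bundle$eigenworms
    write.csv(data.frame(eigenvalue = eigenvalues(ew),
                         cumVariance = varianceExplained(ew),
                         t(eigenworms(ew))),
              file.path(dir, "eigenworms.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$abundance)) {
    write.csv(data.frame(hat = bundle$abundance$binStart,
                         bundle$abundance$raw, check.names = FALSE),
              file.path(dir, "posture_abundance.csv"), row.names = FALSE)
    write.csv(data.frame(hat = bundle$abundance$binStart,
                         bundle$abundance$zscore, check.names = FALSE),
              file.path(dir, "posture_abundance_zscore.csv"),
              row.names = FALSE)
  }
  if (!is.null(bundle$behavior))
    write.csv(bundle$behavior$timeSeries,
              file.path(dir, "behavior_summary.csv"), row.names = FALSE)

  meta <- list(configHash = unname(tools::md5sum(cfgPath)),
               seed = bundle$config$seed,
               package = as.character(utils::packageVersion("wormplate")),
               rVersion = R.version.string,
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
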