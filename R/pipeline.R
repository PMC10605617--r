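# End-to-end pipeline runners.

#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration for the synthetic
#' SRUS pipeline and the micro-CT branch as a plain named list (YAML
#' round-trippable). Override any entry via `modifyList()` semantics by
#' passing replacements in `...`.
#'
#' @param ... named overrides, e.g.
#'   `defaultPipelineConfig(scene = list(nRootVessels = 10))` (partial
#'   sub-lists are merged).
#' @return named list.
#' @export
defaultPipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    scene = list(nRootVessels = 14L, branchingDepth = 1L,
                 tortuosityAmp = 0.08, dims = 2L, keepFraction = 1.0),
    acquisition = list(frameRate = 55, nFrames = 550L, pixelSize = 0.05,
                       psfSigma = 0.15, mbInfluxRate = 8, noiseSigma = 0.02,
                       motionAmplitude = 0.2, motionPeriod = 1.2,
                       motionAngleDeg = 70),
    detection = list(relThreshold = 0.3, minSeparationMm = 0.2,
                     windowPx = 15L, minAmplitude = 0.25),
    motion = list(referenceIndex = 1L, blockSizeMm = 1.5,
                  searchRadiusMm = 0.45, blockGrid = 3L),
    tracker = list(maxSpeed = 20, minTrackLength = 3L,
                   nHierarchyPasses = 2L, passGateScale = 2,
                   processNoise = 1, measurementNoise = 1e-4),
    quant = list(gridPixelSize = 0.025, patchSide = 2.0, overlap = 0.5,
                 regions = c("CO", "OM", "IM")),
    uct = list(voxelSizeUm = 26.5, noiseSigma = 0.05,
               vesselThreshold = 0.45, cortexRadiusThresholdVox = 10,
               medullaRadiusThresholdVox = 6)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  cfg
}

#' Run the full SRUS pipeline
#'
#' Simulation (or input stacks) -> detection -> motion estimation ->
#' position correction -> Kalman linking -> track accumulation ->
#' per-region patch density and tortuosity. All intermediates, the
#' per-region summary and the resolved configuration (with an md5
#' content hash echoed into every output's header comment sidecar) are
#' written under `outDir`. Identical config + seed gives byte-identical
#' outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir output directory, created if missing.
#' @param stacks optional list with `contrast` and `bmode`
#'   [FrameStack-class] objects plus `roi`/`origin`/`extent`; when NULL
#'   a synthetic scene is simulated from `config$scene`.
#' @return invisible list: `summary` data.frame (one row per region:
#'   `region`, `mean_density_pct`, `n_patches`, `mean_tortuosity`,
#'   `n_tracks_region`, `n_tracks_total`), `trackset`, `srus`,
#'   `groundTruth` (NULL for real inputs), `configHash`.
#' @export
runSrusPipeline <- function(config = defaultPipelineConfig(), outDir,
                            stacks = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  gt <- NULL
  if (is.null(stacks)) {
    sc <- config$scene
    tree <- generateVesselTree(sc$nRootVessels, sc$branchingDepth,
                               sc$tortuosityAmp, sc$dims,
                               seed = config$seed)
    if (!is.null(sc$keepFraction) && sc$keepFraction < 1)
      tree <- subsetVesselTree(tree, sc$keepFraction,
                               seed = config$seed + 1L)
    acq <- do.call(acquisitionParams,
                   c(config$acquisition, list(seed = config$seed + 2L)))
    sim <- simulateMbMovie(tree, acq)
    gt <- sim$groundTruth
    bb <- boundingBox(tree)
    origin <- bb[1L, 1:2]
    extent <- bb[2L, 1:2] - bb[1L, 1:2]
    roi <- regionBandMask(extent, config$quant$gridPixelSize, origin)
    stacks <- list(contrast = sim$contrast, bmode = sim$bmode,
                   roi = roi, origin = origin, extent = extent)
  }
  stage <- "detect"
  res <- tryCatch({
    det <- detectStack(stacks$contrast,
                       relThreshold = config$detection$relThreshold,
                       minSeparation = config$detection$minSeparationMm,
                       window = config$detection$windowPx,
                       origin = stacks$origin,
                       minAmplitude = config$detection$minAmplitude)
    writeDetectionsCsv(det, file.path(outDir, "detections.csv"))

    stage <- "motion"
    mf <- estimateMotion(stacks$bmode, config$motion$referenceIndex,
                         config$motion$blockSizeMm,
                         config$motion$searchRadiusMm,
                         config$motion$blockGrid)
    mdf <- data.frame(frame = seq_len(nrow(displacement(mf))),
                      dx_mm = displacement(mf)[, 1L],
                      dz_mm = displacement(mf)[, 2L],
                      confidence = motionConfidence(mf))
    writeTable(mdf, file.path(outDir, "motion.csv"))

    stage <- "correct"
    detc <- correctPositions(det, mf)

    stage <- "track"
    tp <- do.call(trackerParams, config$tracker)
    ts <- trackMicrobubbles(detc, tp, frameRate(stacks$contrast))
    writeTracksCsv(ts, file.path(outDir, "tracks.csv"))

    stage <- "accumulate"
    srus <- accumulateTracks(ts, config$quant$gridPixelSize,
                             stacks$extent, stacks$origin)
    writeSrusPng(srus, file.path(outDir, "srus.png"))

    stage <- "quantify"
    nTot <- nTracks(ts)
    rows <- lapply(config$quant$regions, function(g) {
      dres <- computePatchDensity(srus, stacks$roi, g,
                                  config$quant$patchSide,
                                  config$quant$overlap)
      tres <- computeTortuosity(ts, stacks$roi, g,
                                config$quant$gridPixelSize, stacks$origin)
      writeTable(dres$patches,
                 file.path(outDir, sprintf("patches_%s.csv", g)))
      writeTable(tres$perTrack,
                 file.path(outDir, sprintf("tortuosity_%s.csv", g)))
      data.frame(region = g, mean_density_pct = dres$meanDensityPct,
                 n_patches = dres$nPatches,
                 mean_tortuosity = tres$meanTortuosity,
                 n_tracks_region = nrow(tres$perTrack),
                 n_tracks_total = nTot)
    })
    summary <- do.call(rbind, rows)
    writeTable(summary, file.path(outDir, "summary.csv"))
    list(summary = summary, trackset = ts, srus = srus, groundTruth = gt,
         configHash = hash)
  }, error = function(e) {
    stop(sprintf("SRUS pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  config$resolved_hash <- hash
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  invisible(res)
}

#' Synthetic 3D region masks for the micro-CT branch
#'
#' An ellipsoidal "kidney" inscribed in the volume with an inner
#' ellipsoidal "medulla" (half the semi-axes); the cortex is the exact
#' set difference.
#'
#' @param dims integer(3) volume shape.
#' @return A [RegionMasks3D-class].
#' @export
syntheticRegionMasks <- function(dims) {
  ctr <- (dims + 1) / 2
  ax <- dims / 2 - 1
  ix <- slice.index(array(0, dims), 1L)
  iy <- slice.index(array(0, dims), 2L)
  iz <- slice.index(array(0, dims), 3L)
  rr <- ((ix - ctr[1L]) / ax[1L])^2 + ((iy - ctr[2L]) / ax[2L])^2 +
    ((iz - ctr[3L]) / ax[3L])^2
  RegionMasks3D(kidney = rr <= 1, medulla = rr <= 0.25)
}

#' Run the micro-CT quantification pipeline
#'
#' Renders (or loads) a vessel volume, segments vessels by explicit
#' intensity threshold inside the kidney mask, estimates local radii,
#' partitions small/large vessels at the per-region radius thresholds
#' (cortex 10 voxels, medulla 6 by default) and reports per-region
#' small-vessel density. The medulla read-out uses the combined
#' medullary mask.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir output directory.
#' @param volume optional [Volume3D-class]; when NULL a synthetic 3D
#'   tree is rendered from `config$scene`.
#' @param masks optional [RegionMasks3D-class]; defaults to
#'   [syntheticRegionMasks()] of the volume shape.
#' @return invisible list: `densities` data.frame, `radiusMap`,
#'   `configHash`.
#' @export
runUctPipeline <- function(config = defaultPipelineConfig(), outDir,
                           volume = NULL, masks = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  if (is.null(volume)) {
    sc <- config$scene
    tree <- generateVesselTree(sc$nRootVessels, sc$branchingDepth,
                               sc$tortuosityAmp, dims = 3L,
                               seed = config$seed)
    rnd <- renderUctVolume(tree, config$uct$voxelSizeUm,
                           config$uct$noiseSigma, seed = config$seed + 3L)
    volume <- rnd$volume
  }
  d <- dim(volumeData(volume))
  if (is.null(masks)) masks <- syntheticRegionMasks(d)
  stage <- "segment-vessels"
  res <- tryCatch({
    vm <- segmentVessels(volume, kidneyMask(masks),
                         config$uct$vesselThreshold)
    writeVolume(array(as.numeric(vm), dim = d),
                file.path(outDir, "vessel_mask.nii.gz"),
                voxelSize(volume))
    stage <- "radius"
    rmap <- estimateLocalRadius(vm, voxelSize(volume))
    writeVolume(rmap, file.path(outDir, "radius_map.nii.gz"))
    stage <- "density"
    rows <- list()
    for (g in c("cortex", "medulla")) {
      thr <- if (g == "cortex") config$uct$cortexRadiusThresholdVox
             else config$uct$medullaRadiusThresholdVox
      pp <- partitionByRadius(rmap, thr)
      reg <- if (g == "cortex") cortexMask(masks) else medullaMask(masks)
      rows[[g]] <- computeRegionDensity(pp$small, pp$large, reg, g, thr)
    }
    dens <- do.call(rbind, rows)
    rownames(dens) <- NULL
    dens$density_pct <- 100 * dens$density
    writeTable(dens, file.path(outDir, "uct_density.csv"))
    list(densities = dens, radiusMap = rmap, configHash = hash)
  }, error = function(e) {
    stop(sprintf("uCT pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  config$resolved_hash <- hash
  writePipelineConfig(config, file.path(outDir, "uct_config.yaml"))
  invisible(res)
}
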