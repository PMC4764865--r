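# Validation experiments on phantoms with known ground truth. These
# reproduce, at desk scale, the validation protocol used to qualify
# the segmentation workflow: between-method agreement, test-retest
# repeatability, and tissue-peak recovery under noise.

# deterministic ladder of smooth (sphere/ellipsoid) phantom specs
smoothPhantomSpec <- function(i, n, seed) {
  r <- 13 + 5 * (i - 1) / max(n - 1, 1)
  if (i %% 2L == 1L) {
    D <- as.integer(2 * ceiling(r) + 12)
    st <- phantomStructure("smooth", "unpaired", "sphere",
                           rep((D - 1) / 2, 3), r)
    phantomSpec(c(D, D, D), structures = list(st), noiseSd = "clean",
                seed = seed + i)
  } else {
    rz <- r * 1.15; ry <- r * 0.9; rx <- r * 0.8
    D <- as.integer(2 * ceiling(rz) + 12)
    st <- phantomStructure("smooth", "unpaired", "ellipsoid",
                           rep((D - 1) / 2, 3), c(rz, ry, rx))
    phantomSpec(c(D, D, D), structures = list(st), noiseSd = "clean",
                seed = seed + i)
  }
}

# deterministic ladder of lobed (3-sphere union) phantom specs
lobedPhantomSpec <- function(i, n, seed) {
  r0 <- 9 + 3 * (i - 1) / max(n - 1, 1)
  lobes <- rbind(
    c(0, 0, 0, r0),
    c(0.50 * r0, 0.45 * r0, 0.40 * r0, 0.80 * r0),
    c(-0.45 * r0, 0.30 * r0, -0.50 * r0, 0.75 * r0))
  span <- max(abs(lobes[, 1:3])) + max(lobes[, 4])
  D <- as.integer(2 * ceiling(span) + 12)
  st <- phantomStructure("lobed", "unpaired", "lobed",
                         rep((D - 1) / 2, 3), lobes = lobes)
  phantomSpec(c(D, D, D), structures = list(st), noiseSd = "clean",
              seed = seed + i)
}

# one phantom, segmented by both arms of the method comparison
segmentBothMethods <- function(spec, specimenId, keyframeInterval = 5L,
                               minIslandVoxels = 10L) {
  ph <- generatePhantom(spec)
  s <- spec$structures[[1L]]
  # tracing arm: keyframe contours + a hand-set trace threshold at the
  # midpoint between the background and tissue levels
  traceRange <- thresholdRange(
    round((spec$backgroundMean + spec$tissueMean) / 2), 255L)
  trk <- truthTrack(spec, s$label, s$side, interval = keyframeInterval)
  segA <- removeIslands(buildStructure(trk, ph$stack, traceRange),
                        minIslandVoxels)
  # histogram arm: automatic second-peak threshold applied to the whole
  # stack, islands removed, no contour refinement
  est <- estimateHistogramThreshold(ph$stack)
  maskB <- applyThreshold(ph$stack, averagedRange(est))
  segB <- removeIslands(
    segmentedStructure(s$label, s$side, maskB,
                       list(threshold = averagedRange(est))),
    minIslandVoxels)
  list(tracing = computeVolume(segA, spec$voxelSizeUm, specimenId),
       histogram = computeVolume(segB, spec$voxelSizeUm, specimenId),
       truth = ph$truth)
}

#' Between-method agreement experiment on phantom cohorts
#'
#' Segments each phantom twice -- once with the tracing-style workflow
#' (ground-truth keyframe contours at the given interval plus a
#' hand-set trace threshold) and once with the pixel-intensity-
#' histogram workflow (automatic second-peak threshold over the whole
#' stack plus island removal, no contour refinement) -- and summarises
#' the per-phantom percent differences with [methodAgreement()]. The
#' tracing arm inherits contour-interpolation error, which grows with
#' shape complexity; the histogram arm inherits threshold-inclusion
#' error. Run on a smooth cohort and a lobed cohort to compare simple
#' against complex morphology.
#'
#' @param nPhantoms phantoms per shape class (default 10).
#' @param shapes which phantom ladders to run (\code{"smooth"},
#'   \code{"lobed"}).
#' @param seed base RNG seed.
#' @return named list (per shape class) of [methodAgreement()] results.
#' @export
methodAgreementExperiment <- function(nPhantoms = 10L,
                                      shapes = c("smooth", "lobed"),
                                      seed = 1L) {
  out <- list()
  for (shape in shapes) {
    mk <- if (shape == "smooth") smoothPhantomSpec else lobedPhantomSpec
    recA <- list(); recB <- list()
    for (i in seq_len(nPhantoms)) {
      both <- segmentBothMethods(mk(i, nPhantoms, seed),
                                 sprintf("phantom%02d", i))
      recA[[i]] <- both$tracing
      recB[[i]] <- both$histogram
    }
    out[[shape]] <- methodAgreement(do.call(rbind, recA),
                                    do.call(rbind, recB))
  }
  out
}

#' Test-retest repeatability experiment
#'
#' Re-segments one phantom \code{nReps} times with independent Gaussian
#' jitter on every keyframe contour node, emulating the manual node
#' placement variability of repeated tracing sessions, and summarises
#' the volumes with [repeatability()].
#'
#' @param nReps number of repeat segmentations (default 4).
#' @param jitterSd node jitter sd in pixels (default 0.5).
#' @param radius sphere phantom radius in voxels.
#' @param seed base RNG seed.
#' @return [repeatability()] result plus the per-repeat volumes.
#' @export
repeatabilityExperiment <- function(nReps = 4L, jitterSd = 0.5,
                                    radius = 13, seed = 1L) {
  D <- as.integer(2 * ceiling(radius) + 12)
  st <- phantomStructure("Me", "unpaired", "sphere",
                         rep((D - 1) / 2, 3), radius)
  sp <- phantomSpec(c(D, D, D), structures = list(st),
                    noiseSd = "clean", seed = seed)
  ph <- generatePhantom(sp)
  rng <- thresholdRange(round((sp$backgroundMean + sp$tissueMean) / 2),
                        255L)
  vols <- vapply(seq_len(nReps), function(k) {
    set.seed(seed * 100L + k)
    trk <- truthTrack(sp, "Me", "unpaired", jitterSd = jitterSd)
    seg <- removeIslands(buildStructure(trk, ph$stack, rng), 10L)
    computeVolume(seg, sp$voxelSizeUm)$volume_mm3
  }, numeric(1))
  c(repeatability(vols), list(volumes_mm3 = vols))
}

#' Tissue-peak recovery experiment under noise
#'
#' Generates bimodal phantoms (background mean 20, tissue mean 180)
#' over a ladder of noise levels and checks how often the histogram
#' threshold estimator recovers the tissue peak within +/- 2 grey
#' levels.
#'
#' @param nPhantoms number of phantoms (default 20).
#' @param noiseSds noise sigmas cycled across phantoms.
#' @param radius sphere radius in voxels (default 30).
#' @param stackSide cubic stack edge in voxels (default 80).
#' @param tolerance acceptance band in grey levels (default 2).
#' @param seed base RNG seed.
#' @return list with \code{hits}, \code{n}, and a per-phantom
#'   \code{data.frame} of noise level and estimated base.
#' @export
secondPeakExperiment <- function(nPhantoms = 20L,
                                 noiseSds = c(10, 15, 20, 25),
                                 radius = 30, stackSide = 80L,
                                 tolerance = 2L, seed = 1L) {
  res <- data.frame(phantom = seq_len(nPhantoms),
                    noise_sd = rep_len(noiseSds, nPhantoms),
                    base = NA_integer_)
  D <- as.integer(stackSide)
  st <- phantomStructure("Me", "unpaired", "sphere",
                         rep((D - 1) / 2, 3), radius)
  for (k in seq_len(nPhantoms)) {
    sp <- phantomSpec(c(D, D, D), structures = list(st),
                      noiseSd = res$noise_sd[k], seed = seed * 100L + k)
    est <- tryCatch(estimateHistogramThreshold(generatePhantom(sp)$stack),
                    error = function(e) NULL)
    if (!is.null(est)) res$base[k] <- baseLevel(averagedRange(est))
  }
  hits <- sum(!is.na(res$base) & abs(res$base - 180L) <= tolerance)
  list(hits = hits, n = nPhantoms, results = res)
}

#' Full-pipeline sphere recovery experiment
#'
#' Runs the complete workflow (histogram threshold estimation,
#' ground-truth keyframe contours at the given interval, contour
#' interpolation and masking, island removal, voxel-count volume) on a
#' clean sphere phantom and reports the volume error against the
#' analytic sphere volume.
#'
#' @param radius sphere radius in voxels (default 15).
#' @param keyframeInterval keyframe spacing (default 5).
#' @param seed RNG seed.
#' @return list with the segmented and analytic voxel volumes and the
#'   signed percent error.
#' @export
spherePipelineExperiment <- function(radius = 15, keyframeInterval = 5L,
                                     seed = 1L) {
  D <- as.integer(2 * ceiling(radius) + 10)
  st <- phantomStructure("Me", "unpaired", "sphere",
                         rep((D - 1) / 2, 3), radius)
  sp <- phantomSpec(c(D, D, D), structures = list(st),
                    noiseSd = "clean", seed = seed)
  ph <- generatePhantom(sp)
  est <- estimateHistogramThreshold(ph$stack)
  trk <- truthTrack(sp, "Me", "unpaired", interval = keyframeInterval)
  seg <- removeIslands(buildStructure(trk, ph$stack,
                                      averagedRange(est)), 10L)
  analytic <- 4 / 3 * pi * radius^3
  list(segmented_vox = voxelCount(seg), analytic_vox = analytic,
       truth_vox = unname(ph$truth$voxel_counts),
       error_pct = 100 * (voxelCount(seg) - analytic) / analytic)
}
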