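# Synthetic phantom stacks with analytic ground truth.
#
# Emulates the imaging situation of a PTA-stained micro-CT scan: a dark
# background peak, a bright stained-tissue peak, optional additive
# Gaussian noise (clamped to [0, 255]), bilateral mirrored structure
# pairs and non-convex "lobed" solids built from overlapping spheres.
# All geometry uses 0-based continuous voxel-centre coordinates
# (z, y, x), matching contour space.

#' Describe one phantom structure
#'
#' @param label structure name.
#' @param side \code{"L"}, \code{"R"} or \code{"unpaired"}.
#' @param primitive \code{"sphere"}, \code{"ellipsoid"} or
#'   \code{"lobed"} (union of overlapping spheres).
#' @param centre numeric \code{c(z, y, x)} in 0-based voxel-centre
#'   coordinates.
#' @param radii sphere: scalar radius; ellipsoid: \code{c(rz, ry, rx)}
#'   semi-axes (voxels).
#' @param lobes for \code{primitive = "lobed"}: numeric matrix with
#'   columns \code{(dz, dy, dx, r)}, one row per lobe sphere, offsets
#'   relative to \code{centre}. Lobes must overlap enough that every
#'   cross-section is connected and star-shaped about the lobe-centre
#'   mean (satisfied by keeping offsets below the smaller of the two
#'   radii involved).
#' @return a classed list used by [phantomSpec()].
#' @export
phantomStructure <- function(label, side = "unpaired",
                             primitive = c("sphere", "ellipsoid", "lobed"),
                             centre, radii = NULL, lobes = NULL) {
  primitive <- match.arg(primitive)
  if (length(centre) != 3L)
    stop("centre must be c(z, y, x)", call. = FALSE)
  if (primitive == "sphere" &&
      (length(radii) != 1L || radii <= 0))
    stop("sphere needs a single positive radius", call. = FALSE)
  if (primitive == "ellipsoid" &&
      (length(radii) != 3L || any(radii <= 0)))
    stop("ellipsoid needs radii c(rz, ry, rx) > 0", call. = FALSE)
  if (primitive == "lobed") {
    lobes <- as.matrix(lobes)
    if (ncol(lobes) != 4L || nrow(lobes) < 1L || any(lobes[, 4L] <= 0))
      stop("lobed needs a matrix of (dz, dy, dx, r) rows with r > 0",
           call. = FALSE)
  }
  structure(list(label = label, side = side, primitive = primitive,
                 centre = as.numeric(centre), radii = as.numeric(radii),
                 lobes = lobes),
            class = "phantomStructure")
}

#' Mirror a phantom structure across the mid-sagittal plane
#'
#' Reflects the centre (and lobe offsets) across the plane
#' \code{x = (width - 1) / 2} and swaps the side label, producing the
#' exactly symmetric partner of a bilateral pair. Mirrored pairs have
#' identical radii, hence exactly equal truth voxel counts.
#'
#' @param struct a [phantomStructure()].
#' @param width stack width in voxels.
#' @return the mirrored [phantomStructure()].
#' @export
mirrorStructure <- function(struct, width) {
  m <- struct
  m$centre[3L] <- (width - 1) - struct$centre[3L]
  if (!is.null(m$lobes)) m$lobes[, 3L] <- -m$lobes[, 3L]
  m$side <- switch(struct$side, L = "R", R = "L", "unpaired")
  m
}

#' Specify a synthetic phantom stack
#'
#' @param shape integer \code{c(nSlices, height, width)}.
#' @param voxelSizeUm isotropic voxel size (default 4.6 um, the
#'   standardised export size of the source scans).
#' @param backgroundMean,tissueMean mean intensities of background and
#'   stained tissue; \code{tissueMean > backgroundMean}.
#' @param noiseSd additive Gaussian noise sigma, or a preset name:
#'   \code{"clean"} (0), \code{"moderate"} (10), \code{"hard"} (25).
#' @param structures list of [phantomStructure()] objects.
#' @param distractors optional list of sphere structures (bright tissue
#'   belonging to no labelled structure), same format as
#'   [phantomStructure()] with primitive \code{"sphere"} or
#'   \code{"lobed"}.
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @return a classed list for [generatePhantom()].
#' @export
phantomSpec <- function(shape, voxelSizeUm = 4.6, backgroundMean = 20,
                        tissueMean = 180, noiseSd = "clean",
                        structures = list(), distractors = list(),
                        seed = 1L) {
  if (is.character(noiseSd))
    noiseSd <- switch(match.arg(noiseSd, c("clean", "moderate", "hard")),
                      clean = 0, moderate = 10, hard = 25)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be positive c(nSlices, height, width)", call. = FALSE)
  if (tissueMean <= backgroundMean)
    stop("tissueMean must exceed backgroundMean", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  mid <- (shape[3L] - 1) / 2
  for (s in structures) {
    if (!inherits(s, "phantomStructure"))
      stop("structures must be phantomStructure objects", call. = FALSE)
    if (s$side %in% c("L", "R")) {
      ext <- structureXExtent(s)
      crosses <- (s$side == "L" && ext[2L] >= mid) ||
                 (s$side == "R" && ext[1L] <= mid)
      if (crosses)
        stop(sprintf("structure '%s' (%s) crosses the midline x = %.1f",
                     s$label, s$side, mid), call. = FALSE)
    }
  }
  structure(list(shape = as.integer(shape), voxelSizeUm = voxelSizeUm,
                 backgroundMean = backgroundMean, tissueMean = tissueMean,
                 noiseSd = noiseSd, structures = structures,
                 distractors = distractors, seed = as.integer(seed)),
            class = "phantomSpec")
}

structureXExtent <- function(s) {
  switch(s$primitive,
    sphere = s$centre[3L] + c(-1, 1) * s$radii,
    ellipsoid = s$centre[3L] + c(-1, 1) * s$radii[3L],
    lobed = {
      x <- s$centre[3L] + s$lobes[, 3L]
      c(min(x - s$lobes[, 4L]), max(x + s$lobes[, 4L]))
    })
}

# logical membership of voxel centres in the solid, as a full 3D array
structureMembership <- function(s, shape) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  zc <- (0:(nz - 1)) - s$centre[1L]
  yc <- (0:(ny - 1)) - s$centre[2L]
  xc <- (0:(nx - 1)) - s$centre[3L]
  m <- array(FALSE, shape)
  if (s$primitive == "sphere") {
    r2 <- s$radii^2
    d2 <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`)
    m[] <- d2 <= r2
  } else if (s$primitive == "ellipsoid") {
    d2 <- outer(outer((zc / s$radii[1L])^2, (yc / s$radii[2L])^2, `+`),
                (xc / s$radii[3L])^2, `+`)
    m[] <- d2 <= 1
  } else {
    for (i in seq_len(nrow(s$lobes))) {
      lb <- s$lobes[i, ]
      d2 <- outer(outer((zc - lb[1L])^2, (yc - lb[2L])^2, `+`),
                  (xc - lb[3L])^2, `+`)
      m <- m | d2 <= lb[4L]^2
    }
  }
  m
}

# analytic volume in voxel^3 units; lobed solids use fine-grid numeric
# integration (supersampled voxel centres) as the truth oracle
analyticVoxelVolume <- function(s, supersample = 3L) {
  if (s$primitive == "sphere") return(4 / 3 * pi * s$radii^3)
  if (s$primitive == "ellipsoid") return(4 / 3 * pi * prod(s$radii))
  lb <- s$lobes
  if (nrow(lb) == 1L) return(4 / 3 * pi * lb[1L, 4L]^3)
  if (nrow(lb) == 2L) {
    # inclusion-exclusion with the two-sphere lens overlap
    r1 <- lb[1L, 4L]; r2 <- lb[2L, 4L]
    d <- sqrt(sum((lb[1L, 1:3] - lb[2L, 1:3])^2))
    v <- 4 / 3 * pi * (r1^3 + r2^3)
    if (d >= r1 + r2) return(v)
    if (d <= abs(r1 - r2)) return(4 / 3 * pi * max(r1, r2)^3)
    lens <- pi * (r1 + r2 - d)^2 *
      (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
    return(v - lens)
  }
  # >= 3 lobes: supersampled grid over the bounding box
  lo <- apply(lb[, 1:3, drop = FALSE] - lb[, 4L], 2L, min) - 1
  hi <- apply(lb[, 1:3, drop = FALSE] + lb[, 4L], 2L, max) + 1
  step <- 1 / supersample
  zs <- seq(lo[1L] + step / 2, hi[1L], by = step)
  ys <- seq(lo[2L] + step / 2, hi[2L], by = step)
  xs <- seq(lo[3L] + step / 2, hi[3L], by = step)
  count <- 0
  for (z in zs) {
    inz <- matrix(FALSE, length(ys), length(xs))
    for (i in seq_len(nrow(lb))) {
      rz2 <- lb[i, 4L]^2 - (z - lb[i, 1L])^2
      if (rz2 <= 0) next
      inz <- inz | outer((ys - lb[i, 2L])^2, (xs - lb[i, 3L])^2,
                         `+`) <= rz2
    }
    count <- count + sum(inz)
  }
  count * step^3
}

#' Generate a phantom stack with ground truth
#'
#' Builds the 8-bit stack (background intensity outside all solids,
#' tissue intensity inside any structure or distractor, plus clamped
#' rounded Gaussian noise) together with the ground truth needed to
#' validate every pipeline stage: per-structure voxel masks, exact
#' voxel counts, and analytic volumes. Deterministic given the spec's
#' seed.
#'
#' @param spec a [phantomSpec()].
#' @return list with elements \code{stack} ([ImageStack-class]) and
#'   \code{truth}: a list with \code{masks} (named \code{label.side}),
#'   \code{voxel_counts}, \code{analytic_volumes_vox},
#'   \code{analytic_volumes_mm3} and \code{records} (truth
#'   [volumeRecord()] rows, specimen \code{"phantom"}).
#' @seealso [truthTrack()], [generateCohort()]
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  shape <- spec$shape
  tissue <- array(FALSE, shape)
  masks <- list()
  for (s in spec$structures) {
    m <- structureMembership(s, shape)
    masks[[paste(s$label, s$side, sep = ".")]] <- m
    tissue <- tissue | m
  }
  for (s in spec$distractors) tissue <- tissue | structureMembership(s, shape)
  intens <- ifelse(tissue, spec$tissueMean, spec$backgroundMean)
  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    intens <- intens + stats::rnorm(length(intens), 0, spec$noiseSd)
  }
  vox <- array(pmin(pmax(round(intens), 0), 255), shape)
  stack <- imageStack(vox, spec$voxelSizeUm)
  counts <- vapply(masks, sum, numeric(1))
  avox <- vapply(spec$structures, analyticVoxelVolume, numeric(1))
  names(avox) <- names(masks)
  mm3 <- (spec$voxelSizeUm / 1000)^3
  sides <- vapply(spec$structures, `[[`, character(1), "side")
  labels <- vapply(spec$structures, `[[`, character(1), "label")
  records <- volumeRecord("phantom", labels, sides, counts,
                          spec$voxelSizeUm)
  list(stack = stack,
       truth = list(masks = masks, voxel_counts = counts,
                    analytic_volumes_vox = avox,
                    analytic_volumes_mm3 = avox * mm3,
                    records = records, spec = spec))
}

# circles (cx, cy, r) making up the structure's cross-section at
# (0-based) slice z; empty list when the slice misses the solid
crossSectionCircles <- function(s, z) {
  if (s$primitive == "sphere") {
    r2 <- s$radii^2 - (z - s$centre[1L])^2
    if (r2 <= 0) return(list())
    return(list(c(s$centre[3L], s$centre[2L], sqrt(r2))))
  }
  if (s$primitive == "ellipsoid") {
    f2 <- 1 - ((z - s$centre[1L]) / s$radii[1L])^2
    if (f2 <= 0) return(list())
    # elliptical section handled as its own case by truthContour
    return(list(c(s$centre[3L], s$centre[2L], sqrt(f2))))
  }
  out <- list()
  for (i in seq_len(nrow(s$lobes))) {
    lb <- s$lobes[i, ]
    r2 <- lb[4L]^2 - (z - (s$centre[1L] + lb[1L]))^2
    if (r2 > 0)
      out[[length(out) + 1L]] <- c(s$centre[3L] + lb[3L],
                                   s$centre[2L] + lb[2L], sqrt(r2))
  }
  out
}

# polygonal cross-section contour at slice z with nNodes nodes and an
# outward margin (px). Spheres/lobed: radial ray casting from the
# area-weighted circle centre (exact for star-shaped sections);
# ellipsoids: parametric ellipse.
truthContour <- function(s, z, nNodes = 64L, marginPx = 0.5) {
  th <- 2 * pi * (seq_len(nNodes) - 1L) / nNodes
  if (s$primitive == "ellipsoid") {
    f2 <- 1 - ((z - s$centre[1L]) / s$radii[1L])^2
    if (f2 <= 0) return(NULL)
    a <- s$radii[3L] * sqrt(f2) + marginPx
    b <- s$radii[2L] * sqrt(f2) + marginPx
    return(contour(cbind(s$centre[3L] + a * cos(th),
                         s$centre[2L] + b * sin(th))))
  }
  circ <- crossSectionCircles(s, z)
  if (!length(circ)) return(NULL)
  cc <- do.call(rbind, circ)
  w <- cc[, 3L]^2
  c0 <- c(sum(cc[, 1L] * w), sum(cc[, 2L] * w)) / sum(w)
  rr <- vapply(th, function(a) {
    u <- c(cos(a), sin(a))
    tmax <- 0
    for (i in seq_len(nrow(cc))) {
      dc <- c(cc[i, 1L], cc[i, 2L]) - c0
      b <- sum(u * dc)
      disc <- b^2 - sum(dc^2) + cc[i, 3L]^2
      if (disc >= 0) tmax <- max(tmax, b + sqrt(disc))
    }
    tmax
  }, numeric(1))
  if (all(rr <= 0)) return(NULL)
  contour(cbind(c0[1L] + (rr + marginPx) * cos(th),
                c0[2L] + (rr + marginPx) * sin(th)))
}

#' Ground-truth keyframe track for a phantom structure
#'
#' Builds the [StructureTrack-class] a careful annotator would draw:
#' polygonal cross-sections of the analytic solid on every
#' \code{interval}-th visible slice (first and last visible slices are
#' always keyframed), with nodes placed a half pixel outside the
#' surface by default -- a loop traced around the active pixels
#' encloses whole pixels, so its path runs outside the pixel centres.
#' The outward margin never admits extra tissue because the structure
#' mask is the intersection of the contour mask with the thresholded
#' stack.
#'
#' @param spec a [phantomSpec()].
#' @param label,side select the structure.
#' @param interval keyframe spacing in slices (default 5).
#' @param nNodes nodes per contour (default 64).
#' @param marginPx outward node offset in pixels (default 0.5).
#' @param jitterSd optional Gaussian node jitter (px), emulating manual
#'   node placement variability for repeatability studies; uses the
#'   current RNG state.
#' @return a [StructureTrack-class] (slices are 1-based).
#' @export
truthTrack <- function(spec, label, side = "unpaired", interval = 5L,
                       nNodes = 64L, marginPx = 0.5, jitterSd = 0) {
  hit <- vapply(spec$structures, function(s)
    s$label == label && s$side == side, logical(1))
  if (sum(hit) != 1L)
    stop(sprintf("spec has %d structures labelled '%s' (%s)",
                 sum(hit), label, side), call. = FALSE)
  s <- spec$structures[[which(hit)]]
  nz <- spec$shape[1L]
  visible <- which(vapply(0:(nz - 1), function(z)
    !is.null(truthContour(s, z, 8L, 0)), logical(1))) - 1L
  if (!length(visible))
    stop("structure is not visible on any slice", call. = FALSE)
  zmin <- min(visible); zmax <- max(visible)
  kz <- unique(c(seq(zmin, zmax, by = interval), zmax))
  kfs <- lapply(kz, function(z) {
    ct <- truthContour(s, z, nNodes, marginPx)
    if (jitterSd > 0) {
      nd <- ct@nodes + matrix(stats::rnorm(2L * nrow(ct@nodes), 0,
                                           jitterSd), ncol = 2L)
      ct <- contour(nd)
    }
    ct
  })
  ok <- !vapply(kfs, is.null, logical(1))
  structureTrack(label, side, kfs[ok], slices = kz[ok] + 1L,
                 keyframeInterval = interval)
}

#' Generate a cohort of phantoms with a known allometric slope
#'
#' Emulates a multi-specimen study: each specimen i receives a
#' body-size covariate w_i (thorax width, mm) drawn uniformly from
#' \code{widthRangeMm}, and one bilateral structure pair whose total
#' analytic volume is \code{baseVolumeMm3 + sizeSlope * w_i}, split
#' equally between mirrored L and R solids. Optional relative noise
#' (sd \code{relNoiseSd}, applied per side) emulates segmentation
#' error. The emitted records and covariates feed [pairedSymmetry()]
#' and [allometry()] directly; each specimen also carries a sphere-pair
#' [phantomSpec()] in case full stacks are wanted via
#' [generatePhantom()].
#'
#' @param nSpecimens number of specimens (>= 3; 19 matches the source
#'   study's cohort).
#' @param baseVolumeMm3 intercept a of the true allometric line. The
#'   defaults give pair totals of 0.06-0.18 mm^3 across the default
#'   width range: centred on the observed medulla pair total
#'   (~0.15 mm^3) with a ~3x spread between the smallest and largest
#'   brain, matching the strong allometry such cohorts show.
#' @param sizeSlope slope b (mm^3 per mm thorax width).
#' @param relNoiseSd relative (fractional) noise sd per side volume;
#'   0 gives exact volumes.
#' @param widthRangeMm range of thorax widths (default 4-6 mm).
#' @param label structure label (default \code{"Me"}).
#' @param voxelSizeUm voxel size for the voxel-count column.
#' @param seed RNG seed.
#' @return list with \code{records} (volume rows, one L and one R per
#'   specimen), \code{covariates} (\code{specimen_id,
#'   thorax_width_mm}), \code{true_totals_mm3} and \code{specs}.
#' @export
generateCohort <- function(nSpecimens = 19L, baseVolumeMm3 = -0.18,
                           sizeSlope = 0.06, relNoiseSd = 0,
                           widthRangeMm = c(4, 6), label = "Me",
                           voxelSizeUm = 4.6, seed = 1L) {
  if (nSpecimens < 3L) stop("need >= 3 specimens", call. = FALSE)
  set.seed(seed)
  w <- sort(stats::runif(nSpecimens, widthRangeMm[1L], widthRangeMm[2L]))
  totals <- baseVolumeMm3 + sizeSlope * w
  if (any(totals <= 0))
    stop("slope/intercept produce non-positive volumes", call. = FALSE)
  ids <- sprintf("bee%02d", seq_len(nSpecimens))
  mm3 <- (voxelSizeUm / 1000)^3
  recs <- list()
  specs <- list()
  for (i in seq_len(nSpecimens)) {
    half <- totals[i] / 2
    vl <- half * (1 + if (relNoiseSd > 0) stats::rnorm(1, 0, relNoiseSd) else 0)
    vr <- half * (1 + if (relNoiseSd > 0) stats::rnorm(1, 0, relNoiseSd) else 0)
    if (vl <= 0 || vr <= 0)
      stop("noise produced a non-positive volume", call. = FALSE)
    recs[[i]] <- volumeRecord(ids[i], label, c("L", "R"),
                              round(c(vl, vr) / mm3), voxelSizeUm)
    r <- (half / mm3 * 3 / (4 * pi))^(1 / 3)
    # stack sized to hold the mirrored sphere pair with clearance
    shp <- as.integer(ceiling(c(2 * r + 9, 2 * r + 9, 4 * r + 18)))
    cL <- c((shp[1L] - 1) / 2, (shp[2L] - 1) / 2, (shp[3L] - 1) / 4)
    sL <- phantomStructure(label, "L", "sphere", cL, r)
    specs[[ids[i]]] <- phantomSpec(
      shp, voxelSizeUm, structures = list(sL,
        mirrorStructure(sL, shp[3L])), seed = seed + i)
  }
  list(records = do.call(rbind, recs),
       covariates = data.frame(specimen_id = ids, thorax_width_mm = w),
       true_totals_mm3 = totals, specs = specs)
}
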