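#' Label connected components of a 3D binary mask
#'
#' Breadth-first labelling over a zero-padded copy of the mask, with
#' face (6), face+edge (18) or face+edge+corner (26) neighbourhoods.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array of the same dimensions: 0 for background,
#'   1..k for the k components (labelled in first-voxel order).
#' @seealso [removeIslands()]
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array", call. = FALSE)
  offs <- neighbourOffsets(dim(mask), connectivity)
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  lab <- integer(prod(dp))
  active <- which(padded)
  nextLab <- 0L
  for (seed in active) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    lab[seed] <- nextLab
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[padded[nb] & lab[nb] == 0L]
      lab[nb] <- nextLab
      frontier <- nb
    }
  }
  dim(lab) <- dp
  lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

# linear-index offsets of the chosen 3D neighbourhood in a padded array
neighbourOffsets <- function(d, connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  dp <- d + 2L
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  ord <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  g <- g[ord <= switch(as.character(connectivity),
                       "6" = 1L, "18" = 2L, "26" = 3L), ]
  as.integer(g$dz + g$dy * dp[1L] + g$dx * dp[1L] * dp[2L])
}

#' Remove small disconnected components ("islands") from a structure
#'
#' Deletes every connected component whose voxel count is below
#' \code{minIslandVoxels}, the cleanup applied after masking to strip
#' artefactual extraneous tissue before volume reporting. Components at
#' or above the threshold are untouched; the operation is idempotent
#' and never increases the voxel count.
#'
#' @param structure a [SegmentedStructure-class].
#' @param minIslandVoxels non-negative integer; 0 is the identity.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a [SegmentedStructure-class]; provenance gains a
#'   \code{cleanup} record listing component sizes found and removed.
#' @seealso [labelComponents()], [smoothMask()]
#' @export
setMethod("removeIslands", "SegmentedStructure",
  function(structure, minIslandVoxels, connectivity = 26L) {
    if (minIslandVoxels < 0L)
      stop("minIslandVoxels must be >= 0", call. = FALSE)
    if (minIslandVoxels == 0L || !any(structure@mask)) {
      sizes <- integer(0)
      if (any(structure@mask)) {
        lab <- labelComponents(structure@mask, connectivity)
        sizes <- tabulate(lab[lab > 0L])
      }
      prov <- structure@provenance
      prov$cleanup <- list(min_island_voxels = as.integer(minIslandVoxels),
                           connectivity = as.integer(connectivity),
                           component_sizes = sizes,
                           removed_sizes = integer(0))
      return(segmentedStructure(structure@label, structure@side,
                                structure@mask, prov))
    }
    lab <- labelComponents(structure@mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minIslandVoxels)
    mask <- array(lab %in% keep & lab > 0L, dim(structure@mask))
    prov <- structure@provenance
    prov$cleanup <- list(min_island_voxels = as.integer(minIslandVoxels),
                         connectivity = as.integer(connectivity),
                         component_sizes = sizes,
                         removed_sizes = sizes[sizes < minIslandVoxels])
    segmentedStructure(structure@label, structure@side, mask, prov)
  })

#' Smooth a structure mask (Gaussian blur and re-binarize)
#'
#' Blurs the 0/1 mask with an isotropic 3D Gaussian of the given sigma
#' (in voxels) and re-binarizes at 0.5. Half-space boundaries are
#' preserved exactly by symmetry; convex corners erode and concave
#' corners fill slightly, which is the intended visual smoothing.
#' \code{sigma = 0} is the identity.
#'
#' Volumes are conventionally reported on the unsmoothed
#' (island-removed) mask -- smoothing here mirrors the viewer-side
#' rendering step -- so this returns a new object rather than
#' replacing anything; pass its result to [computeVolume()] explicitly
#' if a smoothed-volume sensitivity analysis is wanted.
#'
#' @param structure a [SegmentedStructure-class].
#' @param smoothingSigma Gaussian sigma in voxels, >= 0.
#' @return a [SegmentedStructure-class].
#' @seealso [removeIslands()]
#' @export
setMethod("smoothMask", "SegmentedStructure",
  function(structure, smoothingSigma) {
    if (smoothingSigma < 0)
      stop("smoothingSigma must be >= 0", call. = FALSE)
    if (smoothingSigma == 0) return(structure)
    blurred <- gaussianBlur3d(structure@mask * 1, smoothingSigma)
    mask <- array(blurred >= 0.5, dim(structure@mask))
    prov <- structure@provenance
    prov$smoothing <- list(sigma = smoothingSigma)
    segmentedStructure(structure@label, structure@side, mask, prov)
  })

# separable 3D Gaussian blur with replicate (edge-clamp) padding, so a
# half-space boundary is preserved exactly up to the array edges
gaussianBlur3d <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  blurAxis <- function(a, axis) {
    out <- array(0, d)
    n <- d[axis]
    for (s in seq(-r, r)) {
      w <- k[s + r + 1L]
      src <- pmin(pmax(seq_len(n) - s, 1L), n)
      if (axis == 1L) out <- out + w * a[src, , , drop = FALSE]
      else if (axis == 2L) out <- out + w * a[, src, , drop = FALSE]
      else out <- out + w * a[, , src, drop = FALSE]
    }
    out
  }
  blurAxis(blurAxis(blurAxis(arr, 1L), 2L), 3L)
}
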