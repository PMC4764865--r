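#' @import methods
NULL

#' ImageStack: an 8-bit greyscale slice stack
#'
#' A 3D grid of integer intensities in \code{[0, 255]} indexed
#' \code{[z, y, x]} (slice, row, column), with an isotropic voxel edge
#' length in micrometres. Slice \code{z = 1} corresponds to the first
#' file of the exported stack; \code{y} increases downward and \code{x}
#' rightward, following raster image convention.
#'
#' Only isotropic voxels are supported: scans are assumed to have been
#' exported (re-sliced) at a single standardised voxel size, e.g. the
#' 4.6 um used for the bumblebee brain scans this workflow was built
#' around.
#'
#' @slot voxels integer array of dimension \code{c(nSlices, height, width)}
#'   with values in \code{[0, 255]}.
#' @slot voxelSizeUm positive numeric scalar, isotropic voxel edge (um).
#'
#' @seealso [imageStack()], [loadStack()], [reslice()]
#' @export
setClass("ImageStack",
  representation(voxels = "array", voxelSizeUm = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L)
      return("voxels must be a 3D array (z, y, x)")
    if (!is.numeric(v) && !is.integer(v))
      return("voxels must be numeric")
    if (anyNA(v))
      return("voxels must not contain NA")
    if (any(v != trunc(v)))
      return("voxel intensities must be integers")
    if (min(v) < 0 || max(v) > 255)
      return("voxel intensities must lie in [0, 255] (8-bit)")
    if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
        object@voxelSizeUm <= 0)
      return("voxelSizeUm must be a single positive number")
    TRUE
  })

#' ThresholdRange: base/top intensity bounds
#'
#' The pair of grey levels defining which voxels are "active": a voxel
#' is active iff \code{base <= intensity <= top} on the 0 (black) to
#' 255 (white) scale. Both bounds are inclusive.
#'
#' @slot base integer in \code{[0, 255]}.
#' @slot top integer in \code{[0, 255]}, \code{>= base}.
#'
#' @seealso [thresholdRange()], [applyThreshold()]
#' @export
setClass("ThresholdRange",
  representation(base = "integer", top = "integer"),
  validity = function(object) {
    b <- object@base; t <- object@top
    if (length(b) != 1L || length(t) != 1L || is.na(b) || is.na(t))
      return("base and top must be single non-NA integers")
    if (b < 0L || t > 255L)
      return("base and top must lie in [0, 255]")
    if (b > t)
      return("base must not exceed top")
    TRUE
  })

#' HistogramEstimate: automatic threshold estimate from slice histograms
#'
#' Result of the pixel-intensity-histogram threshold method: the base
#' level is read off as the apex of the second histogram peak on each of
#' a set of sampled slices, and the per-slice bases are averaged
#' (arithmetic mean, rounded half-up) into a single range applied to the
#' whole stack.
#'
#' @slot sampledSlices integer vector of slice indices actually used.
#' @slot perSliceBase integer vector, same length, the per-slice bases.
#' @slot averagedRange a [ThresholdRange-class] with the rounded mean base.
#'
#' @seealso [estimateHistogramThreshold()]
#' @export
setClass("HistogramEstimate",
  representation(sampledSlices = "integer", perSliceBase = "integer",
                 averagedRange = "ThresholdRange"),
  validity = function(object) {
    if (length(object@sampledSlices) != length(object@perSliceBase))
      return("sampledSlices and perSliceBase must have equal length")
    if (length(object@perSliceBase) &&
        object@averagedRange@base !=
          floor(mean(object@perSliceBase) + 0.5))
      return("averagedRange base must equal the rounded mean of perSliceBase")
    TRUE
  })

#' Contour: a closed polygonal loop in slice coordinates
#'
#' An ordered ring of nodes in continuous pixel coordinates (pixel
#' centres at integers; x rightward, y downward) describing the looped
#' spline drawn around a structure on one slice. Stored closed
#' implicitly (last node connects to first) and normalised to a fixed
#' orientation (positive shoelace signed area) so contour interpolation
#' is well defined.
#'
#' @slot nodes numeric matrix with >= 3 rows and columns \code{(x, y)}.
#'
#' @seealso [contourNodes()], [rasterizeContour()], [alignContours()]
#' @export
setClass("Contour",
  representation(nodes = "matrix"),
  validity = function(object) {
    n <- object@nodes
    if (!is.numeric(n) || ncol(n) != 2L)
      return("nodes must be a numeric matrix with columns (x, y)")
    if (nrow(n) < 3L)
      return("a contour needs at least 3 nodes")
    if (anyNA(n) || any(!is.finite(n)))
      return("nodes must be finite")
    TRUE
  })

#' StructureTrack: keyframe contours of one structure across slices
#'
#' The keyframe annotation of a single (one-sided) structure: closed
#' contours on a subset of slices (every fifth slice in the original
#' workflow), to be interpolated across the intervening slices. All
#' keyframes must use the same number of nodes so node-to-node
#' interpolation is defined, and keyframe slice indices are strictly
#' increasing.
#'
#' @slot label character, structure name (e.g. \code{"Me"}, \code{"MB_calyx"}).
#' @slot side character, one of \code{"L"}, \code{"R"}, \code{"unpaired"}.
#' @slot keyframeSlices integer vector of slice indices (1-based).
#' @slot keyframes list of [Contour-class], parallel to \code{keyframeSlices}.
#' @slot keyframeInterval integer, nominal slice spacing (default 5).
#'
#' @seealso [structureTrack()], [interpolateTrack()], [buildStructure()]
#' @export
setClass("StructureTrack",
  representation(label = "character", side = "character",
                 keyframeSlices = "integer", keyframes = "list",
                 keyframeInterval = "integer"),
  validity = function(object) {
    if (length(object@label) != 1L || !nzchar(object@label))
      return("label must be a non-empty string")
    if (!object@side %in% c("L", "R", "unpaired"))
      return("side must be 'L', 'R' or 'unpaired'")
    z <- object@keyframeSlices
    if (length(z) != length(object@keyframes))
      return("keyframeSlices and keyframes must have equal length")
    if (length(z) < 1L)
      return("at least one keyframe is required")
    if (any(diff(z) <= 0L))
      return("keyframe slice indices must be strictly increasing")
    if (!all(vapply(object@keyframes, is, logical(1), "Contour")))
      return("keyframes must all be Contour objects")
    nn <- vapply(object@keyframes, function(k) nrow(k@nodes), integer(1))
    if (length(unique(nn)) > 1L)
      return("all keyframe contours must have the same node count")
    if (object@keyframeInterval < 1L)
      return("keyframeInterval must be >= 1")
    TRUE
  })

#' SegmentedStructure: a binary 3D mask of one structure
#'
#' The result of masking a thresholded stack with interpolated keyframe
#' contours (and optionally of subsequent cleanup). Carries a
#' provenance list recording the threshold range, track and cleanup
#' parameters that produced it.
#'
#' @slot label character, structure name.
#' @slot side character, \code{"L"}, \code{"R"} or \code{"unpaired"}.
#' @slot mask logical 3D array aligned with the source [ImageStack-class].
#' @slot provenance list of processing parameters.
#'
#' @seealso [buildStructure()], [removeIslands()], [smoothMask()],
#'   [computeVolume()]
#' @export
setClass("SegmentedStructure",
  representation(label = "character", side = "character",
                 mask = "array", provenance = "list"),
  validity = function(object) {
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      return("mask must be a logical 3D array")
    if (anyNA(object@mask))
      return("mask must not contain NA")
    if (!object@side %in% c("L", "R", "unpaired"))
      return("side must be 'L', 'R' or 'unpaired'")
    TRUE
  })
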