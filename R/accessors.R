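#' @rdname ImageStack-class
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname ImageStack-class
#' @export
setMethod("voxelSizeUm", "ImageStack", function(x) x@voxelSizeUm)

#' @rdname ImageStack-class
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@voxels)[1L])

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@voxels))

#' @rdname SegmentedStructure-class
#' @export
setMethod("structureMask", "SegmentedStructure", function(x) x@mask)

#' @rdname SegmentedStructure-class
#' @export
setMethod("voxelCount", "SegmentedStructure", function(x) sum(x@mask))

#' @rdname SegmentedStructure-class
#' @export
setMethod("provenance", "SegmentedStructure", function(x) x@provenance)

#' @rdname SegmentedStructure-class
#' @export
setMethod("dim", "SegmentedStructure", function(x) dim(x@mask))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ImageStack: %d slices x %d rows x %d cols, %.3g um voxels (8-bit)\n",
    d[1L], d[2L], d[3L], object@voxelSizeUm))
  cat(sprintf("  intensity range: [%d, %d]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "ThresholdRange", function(object) {
  cat(sprintf("ThresholdRange: base = %d, top = %d (inclusive)\n",
              object@base, object@top))
})

setMethod("show", "HistogramEstimate", function(object) {
  cat(sprintf(
    "HistogramEstimate: base %d from %d slices (per-slice range %d-%d)\n",
    object@averagedRange@base, length(object@sampledSlices),
    if (length(object@perSliceBase)) min(object@perSliceBase) else NA_integer_,
    if (length(object@perSliceBase)) max(object@perSliceBase) else NA_integer_))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d nodes, area %.2f px^2\n",
              nrow(object@nodes), contourArea(object)))
})

setMethod("show", "StructureTrack", function(object) {
  cat(sprintf(
    "StructureTrack '%s' (%s): %d keyframes on slices %d-%d (interval %d)\n",
    object@label, object@side, length(object@keyframes),
    min(object@keyframeSlices), max(object@keyframeSlices),
    object@keyframeInterval))
})

setMethod("show", "SegmentedStructure", function(object) {
  d <- dim(object@mask)
  cat(sprintf("SegmentedStructure '%s' (%s): %d voxels in %dx%dx%d grid\n",
              object@label, object@side, sum(object@mask),
              d[1L], d[2L], d[3L]))
})
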