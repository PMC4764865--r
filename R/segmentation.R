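#' Build a segmented structure from a track, stack and threshold
#'
#' The core masking step: keyframe contours are interpolated across the
#' track's slice span, rasterized per slice, and intersected with the
#' thresholded ("active white pixel") voxels of the stack. Only active
#' voxels inside the contour mask belong to the structure; slices
#' outside the keyframe span contribute nothing.
#'
#' @param track a [StructureTrack-class]; keyframe slices must lie
#'   within the stack.
#' @param stack an [ImageStack-class].
#' @param range a [ThresholdRange-class]; use
#'   \code{thresholdRange(0, 255)} to make the threshold an identity
#'   and obtain the pure contour mask.
#' @return a [SegmentedStructure-class] whose provenance records the
#'   threshold range and keyframe slices.
#' @seealso [interpolateTrack()], [rasterizeContour()],
#'   [applyThreshold()], [removeIslands()], [computeVolume()]
#' @export
buildStructure <- function(track, stack, range) {
  d <- dim(stack@voxels)
  zs <- track@keyframeSlices
  if (min(zs) < 1L || max(zs) > d[1L])
    stop(sprintf("keyframe slices %d-%d outside stack (1-%d)",
                 min(zs), max(zs), d[1L]), call. = FALSE)
  contours <- interpolateTrack(track)
  mask <- array(FALSE, d)
  for (zc in names(contours)) {
    z <- as.integer(zc)
    cm <- rasterizeContour(contours[[zc]], d[2L], d[3L])
    if (!any(cm)) next
    img <- stack@voxels[z, , ]
    mask[z, , ] <- cm & img >= range@base & img <= range@top
  }
  segmentedStructure(
    label = track@label, side = track@side, mask = mask,
    provenance = list(
      threshold = c(base = range@base, top = range@top),
      keyframe_slices = zs,
      keyframe_interval = track@keyframeInterval,
      n_nodes = nrow(track@keyframes[[1L]]@nodes)))
}
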