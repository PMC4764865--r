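#' @rdname ImageStack-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageStack-class
#' @export
setGeneric("voxelSizeUm", function(x) standardGeneric("voxelSizeUm"))

#' @rdname ImageStack-class
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname SegmentedStructure-class
#' @export
setGeneric("structureMask", function(x) standardGeneric("structureMask"))

#' @rdname SegmentedStructure-class
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname SegmentedStructure-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Apply a base/top threshold to a stack
#'
#' Marks a voxel active ("on", white) iff its intensity lies in the
#' inclusive range \code{[base, top]}. This is the binary "threshold
#' view" from which structures are traced.
#'
#' @param stack an [ImageStack-class].
#' @param range a [ThresholdRange-class].
#' @return logical array with the same dimensions as the stack.
#' @examples
#' s <- imageStack(array(100L, c(2, 4, 4)), 4.6)
#' all(applyThreshold(s, thresholdRange(90, 255)))  # TRUE
#' @export
setGeneric("applyThreshold",
  function(stack, range) standardGeneric("applyThreshold"))

#' @rdname removeIslands
#' @export
setGeneric("removeIslands",
  function(structure, minIslandVoxels, connectivity = 26L)
    standardGeneric("removeIslands"))

#' @rdname smoothMask
#' @export
setGeneric("smoothMask",
  function(structure, smoothingSigma) standardGeneric("smoothMask"))

#' @rdname computeVolume
#' @export
setGeneric("computeVolume",
  function(structure, voxelSizeUm, specimenId = "specimen")
    standardGeneric("computeVolume"))
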