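#' Construct an ImageStack
#'
#' @param voxels 3D numeric array indexed \code{[z, y, x]} with integer
#'   values in \code{[0, 255]}.
#' @param voxelSizeUm positive isotropic voxel edge length in micrometres.
#' @return an [ImageStack-class].
#' @examples
#' s <- imageStack(array(0L, c(1, 10, 10)), 4.6)
#' nSlices(s)
#' @export
imageStack <- function(voxels, voxelSizeUm) {
  storage.mode(voxels) <- "integer"
  new("ImageStack", voxels = voxels, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' Construct a ThresholdRange
#'
#' @param base,top inclusive intensity bounds, integers in \code{[0, 255]}.
#' @return a [ThresholdRange-class].
#' @examples
#' thresholdRange(100, 255)
#' @export
thresholdRange <- function(base, top = 255L) {
  if (length(base) != 1L || length(top) != 1L ||
      !is.finite(base) || !is.finite(top) ||
      base != trunc(base) || top != trunc(top))
    stop("base and top must be single integer values", call. = FALSE)
  new("ThresholdRange", base = as.integer(base), top = as.integer(top))
}

#' @rdname ThresholdRange-class
#' @param x a \code{ThresholdRange}.
#' @export
baseLevel <- function(x) x@base

#' @rdname ThresholdRange-class
#' @export
topLevel <- function(x) x@top

#' Construct a Contour
#'
#' Nodes are stored with the orientation normalised so the shoelace
#' signed area is positive; duplicated closing nodes (first == last) are
#' dropped.
#'
#' @param nodes numeric matrix (or two-column object coercible to one)
#'   with columns \code{(x, y)} in continuous pixel coordinates.
#' @return a [Contour-class].
#' @examples
#' sq <- contour(cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5)))
#' contourArea(sq)
#' @export
contour <- function(nodes) {
  nodes <- as.matrix(nodes)
  colnames(nodes) <- c("x", "y")
  n <- nrow(nodes)
  if (n >= 4L && all(nodes[1L, ] == nodes[n, ]))
    nodes <- nodes[-n, , drop = FALSE]
  if (shoelace(nodes) < 0)
    nodes <- nodes[rev(seq_len(nrow(nodes))), , drop = FALSE]
  new("Contour", nodes = nodes)
}

#' @rdname Contour-class
#' @param x a \code{Contour}.
#' @export
contourNodes <- function(x) x@nodes

#' Polygon area of a contour (shoelace formula)
#'
#' @param x a [Contour-class].
#' @return non-negative numeric area in pixel^2 units.
#' @export
contourArea <- function(x) abs(shoelace(x@nodes))

# signed shoelace area of an open ring (matrix of (x, y) rows)
shoelace <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Test whether a contour is a simple (non-self-intersecting) polygon
#'
#' Checks every pair of non-adjacent edges for crossing. O(n^2); meant
#' for validating hand-edited or interpolated contours, not for inner
#' loops.
#'
#' @param x a [Contour-class].
#' @return logical scalar.
#' @export
isSimpleContour <- function(x) {
  p <- x@nodes
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1L], 1L)
  seg_int <- function(a, b, c, d) {
    d1 <- cross2(c, d, a); d2 <- cross2(c, d, b)
    d3 <- cross2(a, b, c); d4 <- cross2(a, b, d)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    FALSE
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (seg_int(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

#' Construct a StructureTrack
#'
#' @param label structure name, e.g. \code{"Me"} (medulla) or
#'   \code{"MB_calyx"}.
#' @param side \code{"L"}, \code{"R"} or \code{"unpaired"}.
#' @param keyframes named list of [Contour-class] objects; names are the
#'   1-based keyframe slice indices (or pass \code{slices}).
#' @param slices optional integer vector of keyframe slice indices,
#'   parallel to \code{keyframes}; overrides list names.
#' @param keyframeInterval nominal keyframe spacing in slices; 5 in the
#'   original workflow.
#' @return a [StructureTrack-class].
#' @export
structureTrack <- function(label, side = "unpaired", keyframes,
                           slices = NULL, keyframeInterval = 5L) {
  if (is.null(slices)) {
    if (is.null(names(keyframes)))
      stop("provide keyframe slice indices via 'slices' or list names",
           call. = FALSE)
    slices <- as.integer(names(keyframes))
  }
  o <- order(slices)
  new("StructureTrack", label = label, side = side,
      keyframeSlices = as.integer(slices[o]),
      keyframes = unname(keyframes[o]),
      keyframeInterval = as.integer(keyframeInterval))
}

#' @rdname StructureTrack-class
#' @param x a \code{StructureTrack}.
#' @export
keyframeSlices <- function(x) x@keyframeSlices

#' @rdname StructureTrack-class
#' @export
keyframes <- function(x) {
  k <- x@keyframes
  names(k) <- x@keyframeSlices
  k
}

#' Construct a SegmentedStructure
#'
#' Usually produced by [buildStructure()]; the constructor is exported
#' for tests and for importing externally produced masks.
#'
#' @param label structure name.
#' @param side \code{"L"}, \code{"R"} or \code{"unpaired"}.
#' @param mask logical 3D array.
#' @param provenance list of processing parameters.
#' @return a [SegmentedStructure-class].
#' @export
segmentedStructure <- function(label, side = "unpaired", mask,
                               provenance = list()) {
  new("SegmentedStructure", label = label, side = side,
      mask = mask, provenance = provenance)
}
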