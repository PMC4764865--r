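#' Align one contour's node indexing to another's
#'
#' Node-to-node interpolation between keyframes requires a node
#' correspondence. This uses index correspondence after the best cyclic
#' rotation: \code{b}'s nodes are cyclically re-indexed so the sum of
#' squared node-to-node distances to \code{a} is minimal (orientation
#' is already normalised by the [Contour-class] constructor).
#'
#' @param a,b [Contour-class] objects with equal node counts.
#' @return \code{b} with re-indexed nodes.
#' @examples
#' a <- contour(cbind(cos(2 * pi * 0:7 / 8), sin(2 * pi * 0:7 / 8)))
#' b <- contour(contourNodes(a)[c(4:8, 1:3), ])
#' all.equal(contourNodes(alignContours(a, b)), contourNodes(a))
#' @export
alignContours <- function(a, b) {
  pa <- a@nodes; pb <- b@nodes
  n <- nrow(pa)
  if (nrow(pb) != n)
    stop(sprintf("node counts differ (%d vs %d); no correspondence",
                 n, nrow(pb)), call. = FALSE)
  costs <- vapply(seq_len(n) - 1L, function(s) {
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    sum((pa - pb[idx, , drop = FALSE])^2)
  }, numeric(1))
  s <- which.min(costs) - 1L
  idx <- ((seq_len(n) - 1L + s) %% n) + 1L
  new("Contour", nodes = pb[idx, , drop = FALSE])
}

#' Interpolate keyframe contours across all intervening slices
#'
#' Reproduces the keyframe workflow: contours are stored on every
#' keyframe slice and linearly interpolated node-by-node on the slices
#' in between, after aligning each keyframe pair with
#' [alignContours()]. At keyframe slices the stored contour is
#' returned exactly.
#'
#' Degenerate interpolated polygons (area collapsing below
#' \code{1e-9}) are flagged with a warning and yield an empty mask for
#' that slice downstream.
#'
#' @param track a [StructureTrack-class] with >= 1 keyframe.
#' @return named list mapping slice index (as name) to
#'   [Contour-class], covering every slice in the keyframe span. A
#'   single-keyframe track returns only that slice.
#' @seealso [buildStructure()]
#' @export
interpolateTrack <- function(track) {
  zs <- track@keyframeSlices
  kfs <- track@keyframes
  out <- list()
  if (length(zs) == 1L) {
    out[[as.character(zs)]] <- kfs[[1L]]
    return(out)
  }
  degenerate <- integer(0)
  for (i in seq_len(length(zs) - 1L)) {
    z0 <- zs[i]; z1 <- zs[i + 1L]
    c0 <- kfs[[i]]
    c1 <- alignContours(c0, kfs[[i + 1L]])
    for (z in z0:(z1 - 1L)) {
      t <- (z - z0) / (z1 - z0)
      nodes <- (1 - t) * c0@nodes + t * c1@nodes
      cz <- new("Contour", nodes = nodes)
      if (abs(shoelace(nodes)) < 1e-9) degenerate <- c(degenerate, z)
      out[[as.character(z)]] <- cz
    }
  }
  out[[as.character(zs[length(zs)])]] <- kfs[[length(kfs)]]
  if (length(degenerate))
    warning("degenerate interpolated contour on slice(s) ",
            paste(degenerate, collapse = ", "),
            "; these slices will rasterize empty", call. = FALSE)
  out
}

#' Rasterize a closed contour to a pixel mask
#'
#' A pixel \code{(y, x)} is active iff its centre (at integer
#' coordinates \code{x - 1, y - 1} in contour space, which is 0-based)
#' lies inside the polygon by the even-odd rule; a centre exactly on
#' the boundary counts as inside. Contours lying partly or fully
#' outside the frame are clipped silently.
#'
#' @param contour a [Contour-class].
#' @param height,width frame dimensions in pixels.
#' @return logical matrix \code{[height, width]}.
#' @examples
#' sq <- contour(cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5)))
#' sum(rasterizeContour(sq, 20, 20))  # 100
#' @export
rasterizeContour <- function(contour, height, width) {
  poly <- contour@nodes
  m <- matrix(FALSE, height, width)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  x0 <- max(0L, floor(min(xs))); x1 <- min(width - 1L, ceiling(max(xs)))
  y0 <- max(0L, floor(min(ys))); y1 <- min(height - 1L, ceiling(max(ys)))
  if (x1 < x0 || y1 < y0) return(m)
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  px <- rep(x0:x1, times = ny)
  py <- rep(y0:y1, each = nx)
  n <- nrow(poly)
  crossings <- integer(length(px))
  onEdge <- logical(length(px))
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    xa <- xs[i]; ya <- ys[i]; xb <- xs[j]; yb <- ys[j]
    spans <- (ya > py) != (yb > py)
    if (any(spans)) {
      xint <- xa + (py - ya) * (xb - xa) / (yb - ya)
      crossings <- crossings + as.integer(spans & (px < xint))
    }
    # boundary-on-centre: distance from pixel centre to segment
    dx <- xb - xa; dy <- yb - ya
    L2 <- dx * dx + dy * dy
    if (L2 < eps) next
    tt <- pmin(pmax(((px - xa) * dx + (py - ya) * dy) / L2, 0), 1)
    d2 <- (px - (xa + tt * dx))^2 + (py - (ya + tt * dy))^2
    onEdge <- onEdge | d2 < eps
  }
  inside <- (crossings %% 2L == 1L) | onEdge
  m[cbind(py + 1L, px + 1L)] <- inside
  m
}

#' Insert interpolated nodes along a contour
#'
#' Splits every edge into \code{factor} equal parts. Useful for
#' approximating smooth looped splines with denser polygons: mask and
#' volume differences against a smooth curve vanish as the node count
#' grows.
#'
#' @param x a [Contour-class].
#' @param factor integer >= 1; 1 returns the contour unchanged.
#' @return a [Contour-class] with \code{factor * n} nodes.
#' @export
densifyContour <- function(x, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(x)
  p <- x@nodes
  n <- nrow(p)
  nxt <- p[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  t <- (seq_len(factor) - 1L) / factor
  nodes <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(p[i, 1L] + t * (nxt[i, 1L] - p[i, 1L]),
          p[i, 2L] + t * (nxt[i, 2L] - p[i, 2L]))
  }))
  new("Contour", nodes = nodes)
}

#' Write a track project file
#'
#' Serialises one or more [StructureTrack-class] objects to the JSON
#' project format: an array of
#' \code{\{label, side, keyframe_interval, keyframes: [\{z, nodes:
#' [[x, y], ...]\}]\}} records. Slice indices are stored 0-based on
#' disk (image-stack convention) and converted back on read.
#'
#' @param tracks a [StructureTrack-class] or list of them.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @seealso [readTrack()]
#' @export
writeTrack <- function(tracks, path) {
  if (is(tracks, "StructureTrack")) tracks <- list(tracks)
  rec <- lapply(tracks, function(tr) {
    list(label = tr@label, side = tr@side,
         keyframe_interval = tr@keyframeInterval,
         keyframes = lapply(seq_along(tr@keyframeSlices), function(i) {
           list(z = tr@keyframeSlices[i] - 1L,
                nodes = unname(apply(tr@keyframes[[i]]@nodes, 1L,
                                     function(r) c(r[1L], r[2L]),
                                     simplify = FALSE)))
         }))
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a track project file
#'
#' @param path JSON project file written by [writeTrack()] (or by
#'   hand in the same format).
#' @return list of [StructureTrack-class] objects.
#' @seealso [writeTrack()]
#' @export
readTrack <- function(path) {
  rec <- jsonlite::read_json(path)
  lapply(rec, function(tr) {
    kfs <- lapply(tr$keyframes, function(k)
      contour(do.call(rbind, lapply(k$nodes, unlist))))
    zs <- vapply(tr$keyframes, function(k) as.integer(k$z), integer(1)) + 1L
    structureTrack(tr$label, tr$side, kfs, slices = zs,
                   keyframeInterval = tr$keyframe_interval)
  })
}
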