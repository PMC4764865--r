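#' @rdname applyThreshold
#' @export
setMethod("applyThreshold", signature("ImageStack", "ThresholdRange"),
  function(stack, range) {
    v <- stack@voxels
    m <- v >= range@base & v <= range@top
    dim(m) <- dim(v)
    m
  })

#' Pixel-intensity histogram of one slice
#'
#' Tabulates the 256 grey-level counts of a slice and a smoothed copy
#' (centred moving average; edge bins are averaged over the available
#' window). Peak detection for automatic threshold selection runs on
#' the smoothed histogram.
#'
#' @param stack an [ImageStack-class].
#' @param z slice index, 1-based.
#' @param smoothingWindow odd integer >= 1; window 1 leaves the
#'   histogram unchanged.
#' @param roi optional rectangular working region
#'   \code{c(y0, y1, x0, x1)} (1-based, inclusive); default full slice.
#' @return list with integer vector \code{raw} and numeric vector
#'   \code{smoothed}, both of length 256 (bins 0-255).
#' @seealso [findSecondPeak()], [estimateHistogramThreshold()]
#' @export
sliceHistogram <- function(stack, z, smoothingWindow = 5L, roi = NULL) {
  d <- dim(stack@voxels)
  if (length(z) != 1L || z < 1L || z > d[1L])
    stop("slice index out of range: ", z, call. = FALSE)
  if (smoothingWindow < 1L || smoothingWindow %% 2L == 0L)
    stop("smoothingWindow must be an odd integer >= 1", call. = FALSE)
  img <- stack@voxels[z, , ]
  if (!is.null(roi)) {
    if (length(roi) != 4L || roi[1L] < 1L || roi[3L] < 1L ||
        roi[2L] > d[2L] || roi[4L] > d[3L] ||
        roi[1L] > roi[2L] || roi[3L] > roi[4L])
      stop("roi must be c(y0, y1, x0, x1) within the slice", call. = FALSE)
    img <- img[roi[1L]:roi[2L], roi[3L]:roi[4L]]
  }
  raw <- tabulate(as.integer(img) + 1L, nbins = 256L)
  list(raw = raw, smoothed = movingAverage(raw, smoothingWindow))
}

movingAverage <- function(h, w) {
  if (w == 1L) return(as.numeric(h))
  r <- (w - 1L) %/% 2L
  n <- length(h)
  cs <- cumsum(c(0, h))
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the second peak of a smoothed intensity histogram
#'
#' Finds the grey level at the apex of the second histogram peak --
#' the automatic base-threshold rule for stained-tissue stacks, where
#' the first peak is the dark background/extraneous material and the
#' second is the bright stained tissue.
#'
#' Local maxima separated by fewer than \code{minSeparation} grey
#' levels are treated as one peak (the taller apex wins; ties go to the
#' lower intensity): features closer than that are not resolvable as
#' distinct tissue classes, and this folds artefacts such as the spike
#' that intensity clamping at 0 carves off the background peak back
#' into the peak they ride on. A surviving maximum then counts as a
#' peak only if (i) its topographic prominence is at least
#' \code{minProminence} times the histogram maximum, and (ii) its
#' prominence is at least \code{valleyRatio} times its own height,
#' i.e. the saddle separating it from any taller neighbour must drop
#' below half its apex. Plateau maxima report their midpoint (rounded
#' toward the lower intensity); peaks are ordered by ascending
#' intensity (optionally by descending count).
#'
#' The reported grey level is, by default, the rounded centroid of the
#' peak's upper half (the contiguous bins at or above half the apex
#' height) -- the standard robust localisation of a noisy peak's top.
#' For clean or plateau peaks this coincides with the apex;
#' \code{refine = "apex"} returns the raw apex bin instead.
#'
#' @param histogram numeric vector of 256 non-negative bin counts
#'   (typically the \code{smoothed} element of [sliceHistogram()]).
#' @param minProminence minimum prominence as a fraction of the maximum
#'   bin; default 0.01.
#' @param valleyRatio minimum prominence as a fraction of the peak's own
#'   height; default 0.5.
#' @param minSeparation minimum grey-level distance between distinct
#'   peaks; default 32 (one eighth of the 8-bit scale).
#' @param refine \code{"centroid"} (default) or \code{"apex"}.
#' @param ordering \code{"intensity"} (default): second peak by
#'   ascending grey level; \code{"count"}: second-tallest peak.
#' @return integer grey level in \code{[0, 255]} of the second peak.
#'   Errors if fewer than two qualifying peaks exist (the caller may
#'   lower \code{minProminence} or fall back to a manual range).
#' @examples
#' h <- 500 * dnorm(0:255, 20, 8) + 200 * dnorm(0:255, 180, 12)
#' findSecondPeak(h)  # 180
#' @export
findSecondPeak <- function(histogram, minProminence = 0.01,
                           valleyRatio = 0.5, minSeparation = 32L,
                           refine = c("centroid", "apex"),
                           ordering = c("intensity", "count")) {
  ordering <- match.arg(ordering)
  refine <- match.arg(refine)
  if (length(histogram) != 256L || anyNA(histogram) || min(histogram) < 0)
    stop("histogram must be 256 non-negative counts", call. = FALSE)
  if (max(histogram) == 0)
    stop("histogram is empty", call. = FALSE)
  pk <- histogramPeaks(histogram, minProminence, valleyRatio,
                       minSeparation)
  if (length(pk) < 2L)
    stop(sprintf(paste0("found %d qualifying peak(s); need 2 ",
                        "(lower minProminence or supply a manual range)"),
                 length(pk)), call. = FALSE)
  if (ordering == "count") pk <- pk[order(-histogram[pk + 1L], pk)]
  if (refine == "apex") return(pk[2L])
  peakCentroid(histogram, pk[2L])
}

# rounded centroid of the contiguous bins at or above half the apex
# height (0-based intensities)
peakCentroid <- function(h, apex) {
  i <- apex + 1L
  half <- h[i] / 2
  lo <- i
  while (lo > 1L && h[lo - 1L] >= half) lo <- lo - 1L
  hi <- i
  n <- length(h)
  while (hi < n && h[hi + 1L] >= half) hi <- hi + 1L
  w <- h[lo:hi]
  as.integer(floor(sum((lo:hi - 1L) * w) / sum(w) + 0.5))
}

# qualifying peak apexes (0-based intensities), ascending
histogramPeaks <- function(h, minProminence, valleyRatio,
                           minSeparation = 32L) {
  n <- length(h)
  gm <- max(h)
  # run-compressed local maxima; a plateau reports its midpoint
  # (rounded down, i.e. ties toward the lower intensity)
  apex <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && h[j + 1L] == h[i]) j <- j + 1L
    leftLower <- i == 1L || h[i - 1L] < h[i]
    rightLower <- j == n || h[j + 1L] < h[i]
    if (leftLower && rightLower && h[i] > 0) apex <- c(apex, (i + j) %/% 2L)
    i <- j + 1L
  }
  # maxima closer than minSeparation are not resolvable as distinct
  # tissue classes: merge each such pair into its taller apex (ties
  # toward the lower intensity). This folds clamp spikes and noise
  # bumps into the peak they ride on.
  while (length(apex) > 1L) {
    seps <- diff(apex)
    if (min(seps) >= minSeparation) break
    i <- which.min(seps)
    drop <- if (h[apex[i + 1L]] > h[apex[i]]) i else i + 1L
    apex <- apex[-drop]
  }
  keep <- logical(length(apex))
  for (k in seq_along(apex)) {
    p <- apex[k]
    ht <- h[p]
    # bases: minimum between the apex and the nearest strictly higher
    # bin on each side (or the edge); prominence above the higher base
    lb <- 0
    if (p > 1L) {
      left <- h[seq_len(p - 1L)]
      higher <- which(left > ht)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      lb <- if (lo <= p - 1L) min(left[lo:(p - 1L)]) else ht
      if (!length(higher)) lb <- min(left)  # edge reachable: base is min
    }
    rb <- 0
    if (p < n) {
      right <- h[(p + 1L):n]
      higher <- which(right > ht)
      hi <- if (length(higher)) min(higher) - 1L else length(right)
      rb <- if (hi >= 1L) min(right[seq_len(hi)]) else ht
      if (!length(higher)) rb <- min(right)
    }
    prom <- ht - max(lb, rb)
    keep[k] <- prom >= minProminence * gm && prom >= valleyRatio * ht
  }
  apex[keep] - 1L
}

#' Estimate a stack threshold from slice intensity histograms
#'
#' The pixel-intensity-histogram threshold method: the base level is
#' determined independently on a subsample of slices as the apex of the
#' second histogram peak, and the per-slice bases are averaged
#' (arithmetic mean, rounded half-up) into a single
#' [ThresholdRange-class] applied to every slice. By default 15 slices
#' at 10-slice intervals, centred on the middle of the stack; for
#' stacks (or structures) spanning fewer slices the interval is reduced
#' proportionally, mirroring the interval adjustment used for smaller
#' structures.
#'
#' Sampled slices on which no second peak qualifies (e.g. featureless
#' slices beyond the structure) are dropped; at least 3 slices must
#' yield a peak.
#'
#' @param stack an [ImageStack-class].
#' @param nSlices number of slices to sample (default 15).
#' @param interval slice spacing (default 10), reduced automatically to
#'   \code{floor(nSlices(stack) / nSlices)} when the stack is too short.
#' @param top fixed top level of the returned range (default 255).
#' @param smoothingWindow,minProminence,valleyRatio,minSeparation,roi
#'   passed to [sliceHistogram()] / [findSecondPeak()].
#' @return a [HistogramEstimate-class].
#' @seealso [findSecondPeak()], [applyThreshold()]
#' @export
estimateHistogramThreshold <- function(stack, nSlices = 15L, interval = 10L,
                                       top = 255L, smoothingWindow = 5L,
                                       minProminence = 0.01,
                                       valleyRatio = 0.5,
                                       minSeparation = 32L, roi = NULL) {
  nz <- dim(stack@voxels)[1L]
  if (nSlices < 1L || interval < 1L)
    stop("nSlices and interval must be >= 1", call. = FALSE)
  if (nz < nSlices * interval)
    interval <- max(1L, nz %/% nSlices)
  mid <- (nz + 1L) %/% 2L
  zsel <- mid + (seq_len(nSlices) - (nSlices + 1L) %/% 2L) * interval
  zsel <- zsel[zsel >= 1L & zsel <= nz]
  bases <- integer(0)
  used <- integer(0)
  for (z in zsel) {
    h <- sliceHistogram(stack, z, smoothingWindow, roi)
    b <- tryCatch(findSecondPeak(h$smoothed, minProminence, valleyRatio,
                                 minSeparation),
                  error = function(e) NA_integer_)
    if (!is.na(b)) { bases <- c(bases, b); used <- c(used, z) }
  }
  if (length(bases) < 3L)
    stop(sprintf(paste0("second peak found on only %d of %d sampled ",
                        "slices; cannot estimate a threshold"),
                 length(bases), length(zsel)), call. = FALSE)
  base <- floor(mean(bases) + 0.5)
  new("HistogramEstimate", sampledSlices = as.integer(used),
      perSliceBase = as.integer(bases),
      averagedRange = thresholdRange(base, top))
}

#' @rdname HistogramEstimate-class
#' @param x a \code{HistogramEstimate}.
#' @export
averagedRange <- function(x) x@averagedRange

#' @rdname HistogramEstimate-class
#' @export
perSliceEstimates <- function(x) {
  data.frame(slice = x@sampledSlices, base = x@perSliceBase)
}
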