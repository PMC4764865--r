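#' Load a slice-image stack from a directory
#'
#' Reads a sequence of 8-bit greyscale slice images (BMP or TIFF) into
#' an [ImageStack-class]. Files are ordered by natural numeric sort of
#' their names (\code{s2.bmp} before \code{s10.bmp}), so exported CT
#' stacks load in export order regardless of zero padding; slice 1 is
#' the first file.
#'
#' @param directory directory containing the slice images.
#' @param pattern filename glob (e.g. \code{"*.bmp"}); matched
#'   case-insensitively against the file extension.
#' @param voxelSizeUm isotropic voxel edge length in micrometres
#'   (anisotropic stacks are not supported).
#' @return an [ImageStack-class].
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeBMP(matrix(0L, 10, 10), file.path(d, "slice_000.bmp"))
#' s <- loadStack(d, "*.bmp", 4.6)
#' dim(s)  # 1 10 10
#' @seealso [saveStack()], [readBMP()]
#' @export
loadStack <- function(directory, pattern = "*", voxelSizeUm) {
  if (!dir.exists(directory))
    stop("directory not found: ", directory, call. = FALSE)
  files <- list.files(directory, pattern = utils::glob2rx(pattern),
                      ignore.case = TRUE)
  files <- files[grepl("\\.(bmp|tif|tiff)$", files, ignore.case = TRUE)]
  if (length(files) == 0L)
    stop("no BMP/TIFF slice images matching '", pattern, "' in ",
         directory, call. = FALSE)
  files <- files[naturalOrder(files)]
  slices <- lapply(file.path(directory, files), readSliceImage)
  h <- vapply(slices, nrow, integer(1))
  w <- vapply(slices, ncol, integer(1))
  bad <- which(h != h[1L] | w != w[1L])
  if (length(bad))
    stop(sprintf("slice '%s' is %dx%d but '%s' is %dx%d",
                 files[bad[1L]], h[bad[1L]], w[bad[1L]],
                 files[1L], h[1L], w[1L]), call. = FALSE)
  vox <- array(0L, c(length(slices), h[1L], w[1L]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
  imageStack(vox, voxelSizeUm)
}

readSliceImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(readBMP(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      chan <- dim(img)[3L]
      flat <- matrix(img, ncol = chan)
      if (!all(flat[, 1L] == flat))
        stop("non-greyscale TIFF: ", path, call. = FALSE)
      img <- img[, , 1L]
    }
    if (max(img) > 255L || min(img) < 0L)
      stop("TIFF is not 8-bit: ", path, call. = FALSE)
    storage.mode(img) <- "integer"
    return(img)
  }
  stop("unsupported slice format: ", path, call. = FALSE)
}

# order of filenames under natural numeric sort: digit runs compare as
# numbers, everything else lexicographically
naturalOrder <- function(x) {
  # pad every digit run to fixed width so lexicographic order is numeric
  pad <- vapply(x, function(s) {
    m <- gregexpr("\\d+", s)[[1L]]
    if (m[1L] == -1L) return(tolower(s))
    res <- ""
    last <- 1L
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      res <- paste0(res, substr(s, last, m[i] - 1L),
                    sprintf("%020.0f",
                            as.numeric(substr(s, m[i], m[i] + len[i] - 1L))))
      last <- m[i] + len[i]
    }
    tolower(paste0(res, substr(s, last, nchar(s))))
  }, character(1), USE.NAMES = FALSE)
  order(pad, x)
}

#' Save a stack as a numbered slice-image sequence
#'
#' Writes one image per slice with zero-padded filenames
#' (\code{slice_000.bmp}, ...) plus a JSON metadata sidecar
#' (\code{stack_meta.json}) recording the voxel size and slice order.
#' The written sequence reloads bit-exactly with [loadStack()].
#'
#' @param stack an [ImageStack-class].
#' @param directory output directory (created if missing).
#' @param format \code{"bmp"} or \code{"tiff"}.
#' @return character vector of the files written, invisibly.
#' @seealso [loadStack()]
#' @export
saveStack <- function(stack, directory, format = c("bmp", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  d <- dim(stack@voxels)
  digits <- max(3L, nchar(as.character(d[1L] - 1L)))
  ext <- if (format == "bmp") "bmp" else "tif"
  files <- sprintf("slice_%0*d.%s", digits, seq_len(d[1L]) - 1L, ext)
  for (i in seq_len(d[1L])) {
    img <- stack@voxels[i, , ]
    p <- file.path(directory, files[i])
    if (format == "bmp") writeBMP(img, p)
    else tiff::writeTIFF(img / 255, p, bits.per.sample = 8L)
  }
  meta <- list(voxel_size_um = stack@voxelSizeUm,
               n_slices = d[1L], height = d[2L], width = d[3L],
               format = format, slice_files = files)
  jsonlite::write_json(meta, file.path(directory, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(directory, files))
}

#' Axis-aligned re-slicing of a stack
#'
#' Permutes and/or flips the stack axes, e.g. to view a coronal export
#' sagittally. Restricted to axis-aligned operations: the voxel
#' multiset is preserved exactly, and applying the inverse permutation
#' and flips returns the original stack bit-exactly. Oblique
#' (free-angle) re-slicing is out of scope; stacks are assumed to have
#' been exported along the optimum orientation plane already.
#'
#' @param stack an [ImageStack-class].
#' @param axisOrder character permutation of \code{c("z", "y", "x")};
#'   position i names the source axis that becomes output axis i.
#' @param flips logical vector of length 3: whether to reverse each
#'   output axis (applied after permutation).
#' @return an [ImageStack-class] with permuted dimensions and unchanged
#'   voxel size.
#' @examples
#' s <- imageStack(array(sample(0:255, 120, TRUE), c(4, 5, 6)), 4.6)
#' dim(reslice(s, c("y", "z", "x")))  # 5 4 6
#' @export
reslice <- function(stack, axisOrder = c("z", "y", "x"),
                    flips = c(FALSE, FALSE, FALSE)) {
  if (length(axisOrder) != 3L || !setequal(axisOrder, c("z", "y", "x")))
    stop("axisOrder must be a permutation of c('z', 'y', 'x')",
         call. = FALSE)
  if (length(flips) != 3L || !is.logical(flips) || anyNA(flips))
    stop("flips must be 3 logical values", call. = FALSE)
  perm <- match(axisOrder, c("z", "y", "x"))
  v <- aperm(stack@voxels, perm)
  for (ax in which(flips)) {
    idx <- rev(seq_len(dim(v)[ax]))
    v <- switch(ax, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
                v[, , idx, drop = FALSE])
  }
  imageStack(v, stack@voxelSizeUm)
}

#' Invert an axis-aligned re-slicing
#'
#' Returns the \code{axisOrder} and \code{flips} that undo a previous
#' [reslice()] call, so \code{reslice(reslice(s, ao, f),
#' inverseReslice(ao, f)$axisOrder, inverseReslice(ao, f)$flips)} is
#' bit-identical to \code{s}.
#'
#' @param axisOrder,flips the arguments given to [reslice()].
#' @return list with elements \code{axisOrder} and \code{flips}.
#' @export
inverseReslice <- function(axisOrder, flips = c(FALSE, FALSE, FALSE)) {
  perm <- match(axisOrder, c("z", "y", "x"))
  inv <- order(perm)
  list(axisOrder = c("z", "y", "x")[inv], flips = flips[inv])
}
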