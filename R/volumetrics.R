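#' Voxel-count volume of a segmented structure
#'
#' Counts the active voxels of the mask and multiplies by the known
#' voxel volume: \code{volume_mm3 = count * (voxelSizeUm / 1000)^3}.
#'
#' @param structure a [SegmentedStructure-class].
#' @param voxelSizeUm isotropic voxel edge in micrometres (4.6 for the
#'   standardised bumblebee exports).
#' @param specimenId identifier recorded in the output row.
#' @return a one-row volume-record \code{data.frame} with columns
#'   \code{specimen_id, label, side, voxel_count, voxel_size_um,
#'   volume_mm3}.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
#' s <- segmentedStructure("Me", "L", m)
#' computeVolume(s, 4.6)$volume_mm3  # 1000 * 0.0046^3
#' @export
setMethod("computeVolume", "SegmentedStructure",
  function(structure, voxelSizeUm, specimenId = "specimen") {
    if (voxelSizeUm <= 0)
      stop("voxelSizeUm must be positive", call. = FALSE)
    volumeRecord(specimenId, structure@label, structure@side,
                 sum(structure@mask), voxelSizeUm)
  })

#' Construct volume-record rows
#'
#' The tidy exchange format for per-structure volumes used by the
#' validation statistics; vectorised over its arguments.
#'
#' @param specimenId,label,side,voxelCount,voxelSizeUm record fields;
#'   \code{side} must be \code{"L"}, \code{"R"} or \code{"unpaired"}.
#' @return \code{data.frame} with columns \code{specimen_id, label,
#'   side, voxel_count, voxel_size_um, volume_mm3}.
#' @export
volumeRecord <- function(specimenId, label, side, voxelCount, voxelSizeUm) {
  if (!all(side %in% c("L", "R", "unpaired")))
    stop("side must be 'L', 'R' or 'unpaired'", call. = FALSE)
  if (any(voxelCount < 0))
    stop("voxel_count must be non-negative", call. = FALSE)
  data.frame(specimen_id = as.character(specimenId),
             label = as.character(label), side = as.character(side),
             voxel_count = as.numeric(voxelCount),
             voxel_size_um = as.numeric(voxelSizeUm),
             volume_mm3 = as.numeric(voxelCount) * (voxelSizeUm / 1000)^3)
}

#' Symmetric percent difference between two volumes
#'
#' \code{100 * |a - b| / ((a + b) / 2)} by default -- symmetric in its
#' arguments and zero iff they are equal. The one-sided variant
#' \code{100 * |a - b| / a} is available for sensitivity analyses via
#' \code{denominator = "first"}.
#'
#' @param a,b non-negative volumes (vectorised); not both zero.
#' @param denominator \code{"mean"} (default) or \code{"first"}.
#' @return percent difference(s).
#' @examples
#' percentDifference(0.0745, 0.0751)  # ~0.80%
#' @export
percentDifference <- function(a, b, denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  if (any(a < 0 | b < 0))
    stop("volumes must be non-negative", call. = FALSE)
  den <- if (denominator == "mean") (a + b) / 2 else a
  if (any(den == 0))
    stop("percent difference undefined when the denominator is zero",
         call. = FALSE)
  100 * abs(a - b) / den
}

#' Agreement between two segmentation methods
#'
#' Matches two sets of volume records on \code{(specimen_id, label,
#' side)} and summarises the per-pair [percentDifference()] for each
#' structure label: mean, median and interquartile range, the summary
#' used to compare the manual tracing and pixel-intensity-histogram
#' threshold methods. Records present in only one set are reported in
#' the \code{unmatched} element, never silently dropped.
#'
#' @param recordsA,recordsB volume-record \code{data.frame}s (see
#'   [volumeRecord()]).
#' @param denominator passed to [percentDifference()].
#' @return list with \code{summary} (per-label \code{data.frame}:
#'   \code{label, n_pairs, mean_pct, median_pct, q1_pct, q3_pct}),
#'   \code{pairs} (per-pair differences) and \code{unmatched}.
#' @export
methodAgreement <- function(recordsA, recordsB,
                            denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  keyA <- paste(recordsA$specimen_id, recordsA$label, recordsA$side,
                sep = "\r")
  keyB <- paste(recordsB$specimen_id, recordsB$label, recordsB$side,
                sep = "\r")
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    stop("duplicate (specimen, label, side) records", call. = FALSE)
  common <- intersect(keyA, keyB)
  if (length(common) == 0L)
    stop("no records match on (specimen, label, side)", call. = FALSE)
  ia <- match(common, keyA); ib <- match(common, keyB)
  pairs <- data.frame(
    specimen_id = recordsA$specimen_id[ia],
    label = recordsA$label[ia], side = recordsA$side[ia],
    volume_a = recordsA$volume_mm3[ia],
    volume_b = recordsB$volume_mm3[ib])
  pairs$pct_diff <- percentDifference(pairs$volume_a, pairs$volume_b,
                                      denominator)
  summ <- do.call(rbind, lapply(split(pairs, pairs$label), function(p) {
    q <- stats::quantile(p$pct_diff, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = p$label[1L], n_pairs = nrow(p),
               mean_pct = mean(p$pct_diff), median_pct = q[2L],
               q1_pct = q[1L], q3_pct = q[3L])
  }))
  rownames(summ) <- NULL
  unmatched <- rbind(
    cbind(recordsA[!(keyA %in% common),
                   c("specimen_id", "label", "side")],
          set = if (any(!(keyA %in% common))) "A" else character(0)),
    cbind(recordsB[!(keyB %in% common),
                   c("specimen_id", "label", "side")],
          set = if (any(!(keyB %in% common))) "B" else character(0)))
  rownames(unmatched) <- NULL
  list(summary = summ, pairs = pairs, unmatched = unmatched)
}

#' Test-retest repeatability of repeated volume measurements
#'
#' Summarises n repeated, independent segmentations of the same
#' structure: sample mean and standard deviation (n - 1 denominator),
#' coefficient of variation \code{100 * sd / mean}, and the
#' repeatability score \code{2 * sd} (the value below which the
#' difference of two repeat measurements falls with ~95% probability
#' under normality).
#'
#' @param volumes numeric vector of >= 2 repeated volumes (mm^3).
#' @return list with \code{n_reps, mean_mm3, sd_mm3, cv_percent,
#'   repeatability_score}.
#' @examples
#' repeatability(c(1, 1, 3, 3))$cv_percent  # 57.735
#' @export
repeatability <- function(volumes) {
  if (length(volumes) < 2L)
    stop("need at least 2 repeated measurements", call. = FALSE)
  m <- mean(volumes)
  if (m == 0)
    stop("coefficient of variation undefined for zero mean volume",
         call. = FALSE)
  s <- stats::sd(volumes)
  list(n_reps = length(volumes), mean_mm3 = m, sd_mm3 = s,
       cv_percent = 100 * s / m, repeatability_score = 2 * s)
}

#' Left-right paired symmetry of bilateral structures
#'
#' For each paired label, regresses the right-side volume (y) on the
#' left-side volume (x) by ordinary least squares across specimens and
#' reports r^2, slope, intercept and the mean symmetric percent
#' difference per pair. Bilateral structures develop near
#' symmetrically, so slopes near 1 and high r^2 validate that the
#' segmentation measures tissue rather than artefact. Specimens
#' missing one side are excluded per label and listed; labels with
#' fewer than 3 complete pairs are dropped with a warning.
#'
#' @param records volume-record \code{data.frame} (see
#'   [volumeRecord()]); each specimen may contribute at most one L and
#'   one R per label.
#' @return \code{data.frame} with one row per paired label:
#'   \code{label, n_pairs, r_squared, slope, intercept,
#'   mean_percent_diff}; attribute \code{"excluded"} lists specimens
#'   dropped for a missing side.
#' @export
pairedSymmetry <- function(records) {
  paired <- records[records$side %in% c("L", "R"), , drop = FALSE]
  if (nrow(paired) == 0L)
    stop("no L/R records to pair", call. = FALSE)
  excluded <- data.frame(label = character(0), specimen_id = character(0))
  rows <- list()
  for (lab in unique(paired$label)) {
    p <- paired[paired$label == lab, , drop = FALSE]
    key <- paste(p$specimen_id, p$side, sep = "\r")
    if (anyDuplicated(key))
      stop(sprintf("specimen contributes >1 %s record for '%s'",
                   p$side[duplicated(key)][1L], lab), call. = FALSE)
    L <- p[p$side == "L", ]; R <- p[p$side == "R", ]
    both <- intersect(L$specimen_id, R$specimen_id)
    onlyOne <- setdiff(union(L$specimen_id, R$specimen_id), both)
    if (length(onlyOne))
      excluded <- rbind(excluded,
                        data.frame(label = lab, specimen_id = onlyOne))
    if (length(both) < 3L) {
      warning(sprintf("label '%s' has %d complete pair(s); need >= 3",
                      lab, length(both)), call. = FALSE)
      next
    }
    x <- L$volume_mm3[match(both, L$specimen_id)]
    y <- R$volume_mm3[match(both, R$specimen_id)]
    fit <- olsFit(x, y)
    rows[[lab]] <- data.frame(
      label = lab, n_pairs = length(both), r_squared = fit$r_squared,
      slope = fit$slope, intercept = fit$intercept,
      mean_percent_diff = mean(percentDifference(x, y)))
  }
  if (!length(rows))
    stop("no paired label has >= 3 complete pairs", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Allometric regression of structure volume on body size
#'
#' Ordinary least squares of total structure volume on a body-size
#' covariate (thorax width in mm, the standard bumblebee body-size
#' proxy), per structure label. Left and right volumes are summed per
#' specimen when \code{combineSides = TRUE} (the convention for
#' reporting paired structures).
#'
#' @param records volume-record \code{data.frame}.
#' @param bodySize \code{data.frame} with columns \code{specimen_id}
#'   and \code{thorax_width_mm}; replicate width measurements should be
#'   averaged at ingest.
#' @param combineSides sum L + R per specimen (default TRUE); when
#'   FALSE, sides are analysed as separate labels \code{label.side}.
#' @return \code{data.frame} with one row per label: \code{label, n,
#'   r_squared, slope, intercept, ci95_slope_lo, ci95_slope_hi}.
#' @export
allometry <- function(records, bodySize, combineSides = TRUE) {
  if (!all(c("specimen_id", "thorax_width_mm") %in% names(bodySize)))
    stop("bodySize needs columns specimen_id and thorax_width_mm",
         call. = FALSE)
  missing <- setdiff(unique(records$specimen_id), bodySize$specimen_id)
  if (length(missing))
    stop("no body-size covariate for specimen(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lab <- if (combineSides) records$label
         else ifelse(records$side == "unpaired", records$label,
                     paste(records$label, records$side, sep = "."))
  agg <- stats::aggregate(volume_mm3 ~ specimen_id + lab,
                          data = cbind(records, lab = lab), FUN = sum)
  rows <- lapply(split(agg, agg$lab), function(a) {
    if (nrow(a) < 3L)
      stop(sprintf("label '%s' has %d specimens; need >= 3",
                   a$lab[1L], nrow(a)), call. = FALSE)
    w <- bodySize$thorax_width_mm[match(a$specimen_id,
                                        bodySize$specimen_id)]
    fit <- olsFit(w, a$volume_mm3)
    n <- nrow(a)
    # 95% CI of the slope from the usual t-based standard error
    se <- fit$slope_se
    tq <- stats::qt(0.975, df = n - 2L)
    data.frame(label = a$lab[1L], n = n, r_squared = fit$r_squared,
               slope = fit$slope, intercept = fit$intercept,
               ci95_slope_lo = fit$slope - tq * se,
               ci95_slope_hi = fit$slope + tq * se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# closed-form simple OLS; r^2 defined as 0 for a constant response
olsFit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0)
    stop("predictor has zero variance; regression undefined",
         call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  tss <- sum((y - my)^2)
  r2 <- if (tss == 0) 0 else 1 - sum(res^2) / tss
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r_squared = r2,
       slope_se = se)
}

#' Write / read volume records as CSV
#'
#' @param records volume-record \code{data.frame}.
#' @param path CSV file path.
#' @return \code{path} (write) or the records (read).
#' @export
writeVolumeRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVolumeRecords
#' @export
readVolumeRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "label", "side", "voxel_count",
            "voxel_size_um", "volume_mm3")
  if (!all(need %in% names(rec)))
    stop("volume CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rec
}
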