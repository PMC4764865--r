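#' Scatter plot of left vs right paired volumes with fitted line
#'
#' One panel per paired label: left volume on x, right on y, the OLS
#' fit of right on left, the identity line for reference, and the r^2
#' and slope in the legend.
#'
#' @param records volume-record \code{data.frame} (see
#'   [volumeRecord()]).
#' @param labels which labels to plot; default all paired labels with
#'   enough data.
#' @return the [pairedSymmetry()] table, invisibly.
#' @export
plotPairedSymmetry <- function(records, labels = NULL) {
  stats <- pairedSymmetry(records)
  if (!is.null(labels))
    stats <- stats[stats$label %in% labels, , drop = FALSE]
  old <- graphics::par(mfrow = c(1, nrow(stats)))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(stats))) {
    lab <- stats$label[i]
    p <- records[records$label == lab, ]
    L <- p[p$side == "L", ]; R <- p[p$side == "R", ]
    both <- intersect(L$specimen_id, R$specimen_id)
    x <- L$volume_mm3[match(both, L$specimen_id)]
    y <- R$volume_mm3[match(both, R$specimen_id)]
    graphics::plot(x, y, xlab = "left volume (mm^3)",
                   ylab = "right volume (mm^3)", main = lab, pch = 19)
    graphics::abline(0, 1, lty = 3, col = "grey60")
    graphics::abline(stats$intercept[i], stats$slope[i], col = "firebrick")
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "r2 = %.3f\nslope = %.3f", stats$r_squared[i], stats$slope[i]))
  }
  invisible(stats)
}

#' Scatter plot of structure volume against body size with fitted line
#'
#' One panel per label: thorax width on x, total structure volume
#' (left + right) on y, the OLS fit with its 95% confidence band.
#'
#' @param records volume-record \code{data.frame}.
#' @param bodySize covariates \code{data.frame} (\code{specimen_id},
#'   \code{thorax_width_mm}).
#' @param labels which labels to plot; default all.
#' @return the [allometry()] table, invisibly.
#' @export
plotAllometry <- function(records, bodySize, labels = NULL) {
  stats <- allometry(records, bodySize)
  if (!is.null(labels))
    stats <- stats[stats$label %in% labels, , drop = FALSE]
  old <- graphics::par(mfrow = c(1, nrow(stats)))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(stats))) {
    lab <- stats$label[i]
    p <- records[records$label == lab, ]
    tot <- tapply(p$volume_mm3, p$specimen_id, sum)
    w <- bodySize$thorax_width_mm[match(names(tot),
                                        bodySize$specimen_id)]
    graphics::plot(w, as.numeric(tot), xlab = "thorax width (mm)",
                   ylab = "total volume (mm^3)", main = lab, pch = 19)
    fit <- stats::lm(as.numeric(tot) ~ w)
    ws <- seq(min(w), max(w), length.out = 50)
    ci <- stats::predict(fit, data.frame(w = ws), interval = "confidence")
    graphics::lines(ws, ci[, "fit"], col = "firebrick")
    graphics::lines(ws, ci[, "lwr"], lty = 2, col = "firebrick")
    graphics::lines(ws, ci[, "upr"], lty = 2, col = "firebrick")
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "r2 = %.3f\nslope = %.3g", stats$r_squared[i], stats$slope[i]))
  }
  invisible(stats)
}
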