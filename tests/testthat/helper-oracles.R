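# Independent oracles and fixture builders used across the suite.
# Each oracle deliberately uses a different algorithm from the package
# implementation it checks.

# even-odd point-in-polygon by explicit per-pixel ray casting (scalar
# loop over edges; boundary points resolved inside via colinearity test)
oraclePointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    xa <- poly[i, 1]; ya <- poly[i, 2]
    xb <- poly[j, 1]; yb <- poly[j, 2]
    # on-segment check
    d <- abs((xb - xa) * (py - ya) - (yb - ya) * (px - xa))
    L <- sqrt((xb - xa)^2 + (yb - ya)^2)
    if (L > 0 && d / L < 1e-9 &&
        px >= min(xa, xb) - 1e-9 && px <= max(xa, xb) + 1e-9 &&
        py >= min(ya, yb) - 1e-9 && py <= max(ya, yb) + 1e-9)
      return(TRUE)
    if ((ya > py) != (yb > py)) {
      xint <- xa + (py - ya) * (xb - xa) / (yb - ya)
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracleRasterCount <- function(poly, height, width) {
  cnt <- 0L
  for (y in 0:(height - 1L)) for (x in 0:(width - 1L))
    if (oraclePointInPolygon(x, y, poly)) cnt <- cnt + 1L
  cnt
}

# connected-component labelling by iterative min-label propagation to a
# fixed point (independent of the package's BFS labelling)
oracleLabelComponents <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  ord <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[ord <= switch(as.character(connectivity),
                             "6" = 1, "18" = 2, "26" = 3), ]
  shift3 <- function(a, dz, dy, dx, fill) {
    out <- array(fill, d)
    zsrc <- seq_len(d[1]); ysrc <- seq_len(d[2]); xsrc <- seq_len(d[3])
    zdst <- zsrc + dz; ydst <- ysrc + dy; xdst <- xsrc + dx
    okz <- zdst >= 1 & zdst <= d[1]
    oky <- ydst >= 1 & ydst <= d[2]
    okx <- xdst >= 1 & xdst <= d[3]
    out[zdst[okz], ydst[oky], xdst[okx]] <-
      a[zsrc[okz], ysrc[oky], xsrc[okx]]
    out
  }
  big <- sum(mask) + 1L
  lab[!mask] <- big
  lab[mask & lab == 0L] <- big
  repeat {
    nxt <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- shift3(lab, offs$dz[k], offs$dy[k], offs$dx[k], big)
      nxt <- pmin(nxt, sh)
    }
    nxt[!mask] <- big
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab[!mask] <- 0L
  # canonicalize to 1..k in first-voxel order
  u <- unique(lab[lab > 0L])
  out <- array(0L, d)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# same-partition comparison ignoring label numbering
samePartition <- function(labA, labB) {
  if (!identical(labA > 0L, labB > 0L)) return(FALSE)
  a <- labA[labA > 0L]; b <- labB[labB > 0L]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(paste(a, b))) == length(unique(b))
}

# random simple (star-shaped) polygon around a centre
randomPolygon <- function(n = 10L, cx = 20, cy = 20, rmin = 3, rmax = 15) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

randomMask <- function(d = c(20L, 20L, 20L), p = 0.2) {
  array(stats::runif(prod(d)) < p, d)
}

uniformStack <- function(value, d = c(2L, 8L, 8L), voxel = 4.6) {
  imageStack(array(as.integer(value), d), voxel)
}

# bimodal Gaussian test histogram with unit-area peaks scaled by counts
gaussHist <- function(means, sds, weights) {
  x <- 0:255
  h <- numeric(256)
  for (i in seq_along(means))
    h <- h + weights[i] * exp(-(x - means[i])^2 / (2 * sds[i]^2))
  h
}

# brute-force second local maximum by exhaustive scan (no prominence
# logic; suitable for clean constructed histograms)
oracleSecondPeak <- function(h) {
  idx <- which(diff(sign(diff(h))) == -2) + 1L
  (idx - 1L)[2L]
}
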