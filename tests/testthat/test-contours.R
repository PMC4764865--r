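octagon <- function(cx = 0, cy = 0, r = 1) {
  th <- 2 * pi * (0:7) / 8
  contour(cbind(cx + r * cos(th), cy + r * sin(th)))
}

test_that("contours normalise orientation and drop the closing node", {
  cw <- contour(cbind(c(0, 0, 4), c(0, 4, 0)))       # clockwise input
  expect_gt(microCTseg:::shoelace(contourNodes(cw)), 0)
  closed <- contour(cbind(c(0, 4, 0, 0), c(0, 0, 4, 0)))
  expect_equal(nrow(contourNodes(closed)), 3L)
  expect_equal(contourArea(closed), 8)
  expect_error(contour(cbind(c(0, 1), c(0, 1))), "3 nodes")
})

test_that("alignContours recovers cyclic rotations exactly", {
  a <- octagon(r = 5)
  idx <- c(4:8, 1:3)
  b <- new("Contour", nodes = contourNodes(a)[idx, ])
  expect_equal(contourNodes(alignContours(a, b)), contourNodes(a),
               ignore_attr = TRUE)
  expect_equal(contourNodes(alignContours(a, a)), contourNodes(a))
  expect_error(alignContours(a, contour(cbind(0:3, c(0, 2, 3, 1)))),
               "node counts")
})

test_that("alignment cost is minimal over all cyclic rotations", {
  set.seed(41)
  for (rep in 1:10) {
    a <- octagon(r = runif(1, 2, 6))
    b <- octagon(cx = runif(1, -1, 1), cy = runif(1, -1, 1),
                 r = runif(1, 2, 6))
    aligned <- alignContours(a, b)
    cost <- sum((contourNodes(a) - contourNodes(aligned))^2)
    pb <- contourNodes(b)
    n <- nrow(pb)
    allCosts <- vapply(0:(n - 1), function(s) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      sum((contourNodes(a) - pb[idx, ])^2)
    }, numeric(1))
    expect_lte(cost, min(allCosts) + 1e-12)
  }
})

test_that("interpolation is exact at keyframes and linear between", {
  sq <- function(s) contour(cbind(c(-1, 1, 1, -1) * s / 2 + 10,
                                  c(-1, -1, 1, 1) * s / 2 + 10))
  tr <- structureTrack("sq", "unpaired", list(sq(10), sq(20)),
                       slices = c(1L, 6L))
  out <- interpolateTrack(tr)
  expect_equal(length(out), 6L)
  expect_identical(contourNodes(out[["1"]]), contourNodes(sq(10)))
  expect_identical(contourNodes(out[["6"]]), contourNodes(sq(20)))
  expect_equal(contourNodes(out[["3"]]), contourNodes(sq(14)),
               tolerance = 1e-12)  # z = 3 is t = 2/5: side 14
  # identical keyframes stay identical throughout
  tr2 <- structureTrack("sq", "unpaired", list(sq(10), sq(10)),
                        slices = c(1L, 6L))
  out2 <- interpolateTrack(tr2)
  for (k in out2)
    expect_equal(contourNodes(k), contourNodes(sq(10)), tolerance = 1e-12)
})

test_that("rotated-index keyframes interpolate without edge crossings", {
  th <- 2 * pi * (0:2) / 3
  t1 <- contour(cbind(10 + 5 * cos(th), 10 + 5 * sin(th)))
  rot <- contourNodes(t1)[c(2, 3, 1), ]
  t2 <- new("Contour", nodes = rot * 1.5 - 5)
  tr <- structureTrack("t", "unpaired", list(t1, t2), slices = c(1L, 6L))
  out <- interpolateTrack(tr)
  for (k in out) expect_true(isSimpleContour(k))
  # node paths equal brute-force best-rotation interpolation
  pa <- contourNodes(t1)
  pb <- contourNodes(t2)
  costs <- vapply(0:2, function(s) {
    idx <- ((0:2 + s) %% 3) + 1
    sum((pa - pb[idx, ])^2)
  }, numeric(1))
  best <- which.min(costs) - 1
  idx <- ((0:2 + best) %% 3) + 1
  z <- 3; t <- (z - 1) / 5
  expect_equal(contourNodes(out[["3"]]),
               (1 - t) * pa + t * pb[idx, ], ignore_attr = TRUE)
})

test_that("rasterization matches the even-odd oracle", {
  sq <- contour(cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5)))
  expect_equal(sum(rasterizeContour(sq, 20, 20)), 100L)
  tri <- contour(cbind(c(0, 4, 0), c(0, 0, 4)))
  m <- rasterizeContour(tri, 10, 10)
  expect_equal(sum(m), oracleRasterCount(contourNodes(tri), 10, 10))
  # off-frame contour clips to empty
  far <- contour(cbind(c(100, 110, 105), c(100, 100, 110)))
  expect_equal(sum(rasterizeContour(far, 20, 20)), 0L)
})

test_that("rasterized area stays within a perimeter band of shoelace area", {
  set.seed(42)
  for (rep in 1:10) {
    poly <- randomPolygon(n = 12L)
    ct <- contour(poly)
    area <- contourArea(ct)
    per <- sum(sqrt(rowSums((poly - poly[c(2:12, 1), ])^2)))
    cnt <- sum(rasterizeContour(ct, 40, 40))
    expect_gte(cnt, area - per)
    expect_lte(cnt, area + per)
  }
})

test_that("buildStructure intersects contour mask with threshold", {
  img <- array(0L, c(6, 20, 20))
  img[, 5:15, 5:15] <- 200L
  s <- imageStack(img, 4.6)
  sq <- contour(cbind(c(2, 17, 17, 2), c(2, 2, 17, 17)))
  tr <- structureTrack("x", "unpaired", list(sq, sq), slices = c(2L, 5L))
  # full range: structure mask equals the pure contour mask
  seg <- buildStructure(tr, s, thresholdRange(0, 255))
  cm <- rasterizeContour(sq, 20, 20)
  expect_equal(sum(structureMask(seg)), 4L * sum(cm))
  expect_false(any(structureMask(seg)[c(1, 6), , ]))
  # containment: thresholded mask is a subset of the contour mask
  seg2 <- buildStructure(tr, s, thresholdRange(150, 255))
  expect_true(all(structureMask(seg2) <= structureMask(seg)))
  expect_equal(sum(structureMask(seg2)), 4L * 11L * 11L)
  # contour over a dark region: empty structure
  seg3 <- buildStructure(tr, s, thresholdRange(201, 255))
  expect_equal(voxelCount(seg3), 0L)
  expect_error(buildStructure(tr, imageStack(img[1:3, , , drop = FALSE],
                                             4.6), thresholdRange(0, 255)),
               "outside stack")
})

test_that("mirroring stack and track in x preserves the voxel count", {
  st <- phantomStructure("AL", "L", "lobed", c(10, 15, 12),
                         lobes = rbind(c(0, 0, 0, 6), c(3, 2, 2, 5)))
  sp <- phantomSpec(c(22L, 30L, 40L), structures = list(st), seed = 5)
  ph <- generatePhantom(sp)
  trk <- truthTrack(sp, "AL", "L")
  seg <- buildStructure(trk, ph$stack, thresholdRange(100, 255))
  # mirrored phantom
  stm <- mirrorStructure(st, 40L)
  spm <- phantomSpec(c(22L, 30L, 40L), structures = list(stm), seed = 5)
  phm <- generatePhantom(spm)
  trkm <- truthTrack(spm, "AL", "R")
  segm <- buildStructure(trkm, phm$stack, thresholdRange(100, 255))
  expect_equal(voxelCount(segm), voxelCount(seg))
})

test_that("densifying keyframes moves volume toward the analytic value", {
  st <- phantomStructure("Me", "unpaired", "sphere", c(17.5, 17.5, 17.5), 13)
  sp <- phantomSpec(c(36L, 36L, 36L), structures = list(st), seed = 3)
  ph <- generatePhantom(sp)
  va <- ph$truth$voxel_counts  # the contour-defined solid, voxelized
  err <- vapply(c(5L, 2L, 1L), function(iv) {
    trk <- truthTrack(sp, "Me", "unpaired", interval = iv)
    abs(voxelCount(buildStructure(trk, ph$stack,
                                  thresholdRange(100, 255))) - va)
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
})

test_that("track project files round trip through JSON", {
  a <- octagon(10, 12, 4)
  b <- octagon(10, 12, 6)
  tr <- structureTrack("MB_calyx", "L", list(a, b), slices = c(3L, 8L))
  p <- withr::local_tempfile(fileext = ".json")
  writeTrack(tr, p)
  back <- readTrack(p)[[1]]
  expect_equal(keyframeSlices(back), keyframeSlices(tr))
  expect_equal(contourNodes(keyframes(back)[[1]]),
               contourNodes(keyframes(tr)[[1]]), ignore_attr = TRUE)
  expect_equal(back@label, "MB_calyx")
  expect_equal(back@side, "L")
})
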