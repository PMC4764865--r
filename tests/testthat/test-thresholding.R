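test_that("applyThreshold matches a brute-force per-voxel count", {
  expect_true(all(applyThreshold(uniformStack(100L),
                                 thresholdRange(90, 255))))
  expect_true(all(applyThreshold(uniformStack(7L),
                                 thresholdRange(0, 255))))
  expect_error(thresholdRange(0, 256), "0, 255")
  expect_error(thresholdRange(200, 100), "exceed")
  set.seed(31)
  s <- imageStack(array(sample(0:255, 5 * 6 * 7, TRUE), c(5, 6, 7)), 4.6)
  for (case in list(c(50, 200), c(0, 0), c(255, 255), c(128, 128))) {
    m <- applyThreshold(s, thresholdRange(case[1], case[2]))
    brute <- 0L
    v <- voxels(s)
    for (i in seq_along(v))
      if (v[i] >= case[1] && v[i] <= case[2]) brute <- brute + 1L
    expect_equal(sum(m), brute)
  }
})

test_that("raising the base never increases the active count", {
  set.seed(32)
  s <- imageStack(array(sample(0:255, 4 * 8 * 8, TRUE), c(4, 8, 8)), 4.6)
  counts <- vapply(seq(0, 250, by = 25), function(b)
    sum(applyThreshold(s, thresholdRange(b, 255))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sliceHistogram counts, smooths, and respects the ROI", {
  s <- uniformStack(7L, c(2L, 10L, 10L))
  h <- sliceHistogram(s, 1)
  expect_equal(h$raw[8], 100L)
  expect_equal(sum(h$raw), 100L)
  expect_equal(sliceHistogram(s, 1, smoothingWindow = 1)$smoothed,
               as.numeric(h$raw))
  # two-value slice: half 10, half 200
  img <- array(10L, c(1, 10, 10)); img[1, , 6:10] <- 200L
  s2 <- imageStack(img, 4.6)
  h2 <- sliceHistogram(s2, 1)$raw
  expect_equal(h2[c(11, 201)], c(50L, 50L))
  expect_error(sliceHistogram(s, 5), "out of range")
  expect_error(sliceHistogram(s, 1, smoothingWindow = 4), "odd")
  roi <- sliceHistogram(s2, 1, roi = c(1, 10, 1, 5))$raw
  expect_equal(roi[11], 50L)
  expect_equal(sum(roi), 50L)
})

test_that("findSecondPeak picks the second maximum by ascending intensity", {
  bimodal <- gaussHist(c(10, 180), c(5, 12), c(500, 200))
  expect_equal(findSecondPeak(bimodal), oracleSecondPeak(bimodal))
  expect_equal(findSecondPeak(bimodal), 180)
  trimodal <- gaussHist(c(10, 120, 240), c(5, 8, 6), c(500, 300, 200))
  expect_equal(findSecondPeak(trimodal), oracleSecondPeak(trimodal))
  expect_equal(findSecondPeak(trimodal), 120)
  unimodal <- gaussHist(100, 20, 400)
  expect_error(findSecondPeak(unimodal), "1 qualifying")
  expect_error(findSecondPeak(rep(0, 256)), "empty")
  # count ordering returns the second-tallest instead
  expect_equal(findSecondPeak(trimodal, ordering = "count"), 120)
  expect_equal(findSecondPeak(bimodal, ordering = "count"), 180)
})

test_that("clamp spikes merge into the background peak", {
  # histogram of clamped round(N(20, sigma)) background plus a tissue
  # peak: clamping piles the sub-zero mass into bin 0, carving a spike
  # off the background peak that must not count as a separate peak
  for (sigma in c(10, 15, 25)) {
    nbg <- 3000
    h <- numeric(256)
    h[1] <- nbg * pnorm(-19.5, 0, sigma)  # mass clamped to 0
    h[2:256] <- nbg * (pnorm(1:255 + 0.5, 20, sigma) -
                       pnorm(1:255 - 0.5, 20, sigma))
    h <- h + gaussHist(180, sigma, 1000 / sigma)
    expect_equal(findSecondPeak(movingAverage(h, 5)), 180,
                 label = paste("sigma", sigma))
  }
})

test_that("histogram threshold estimation averages per-slice peaks", {
  # constant stack: every slice has its second peak at 180
  img <- array(20L, c(30, 16, 16)); img[, 5:12, 5:12] <- 180L
  s <- imageStack(img, 4.6)
  est <- estimateHistogramThreshold(s, nSlices = 5, interval = 3)
  expect_s4_class(est, "HistogramEstimate")
  expect_equal(baseLevel(averagedRange(est)), 180L)
  expect_true(all(perSliceEstimates(est)$base == 180L))
  expect_equal(topLevel(averagedRange(est)), 255L)
})

test_that("per-slice bases symmetric around 180 average to 180", {
  # vary the tissue level per slice: 177..183 symmetric around 180
  img <- array(20L, c(7, 24, 24))
  for (z in 1:7) img[z, 7:18, 7:18] <- 176L + z
  s <- imageStack(img, 4.6)
  est <- estimateHistogramThreshold(s, nSlices = 7, interval = 1,
                                    smoothingWindow = 1)
  expect_equal(sort(perSliceEstimates(est)$base), 177:183)
  expect_equal(baseLevel(averagedRange(est)), 180L)
})

test_that("the sampling interval shrinks for short stacks", {
  img <- array(20L, c(40, 16, 16)); img[, 5:12, 5:12] <- 180L
  s <- imageStack(img, 4.6)
  est <- estimateHistogramThreshold(s, nSlices = 15, interval = 10)
  zs <- perSliceEstimates(est)$slice
  expect_equal(length(zs), 15L)
  expect_true(all(diff(sort(zs)) == 2L))  # floor(40 / 15) = 2
})

test_that("estimation fails cleanly when too few slices have a peak", {
  s <- uniformStack(20L, c(30L, 12L, 12L))
  expect_error(estimateHistogramThreshold(s, nSlices = 5, interval = 3),
               "cannot estimate")
})

test_that("the estimator recovers the tissue peak under noise", {
  # moderate preset: SNR comfortably above the documented sigma bound
  st <- phantomStructure("Me", "unpaired", "sphere", c(24.5, 24.5, 24.5), 18)
  sp <- phantomSpec(c(50L, 50L, 50L), structures = list(st),
                    noiseSd = "moderate", seed = 99)
  ph <- generatePhantom(sp)
  est <- estimateHistogramThreshold(ph$stack)
  expect_lte(abs(baseLevel(averagedRange(est)) - 180L), 2L)
})
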