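mkRecords <- function(ids, label, side, volumes, voxel = 4.6) {
  mm3 <- (voxel / 1000)^3
  volumeRecord(ids, label, side, round(volumes / mm3), voxel)
}

test_that("voxel-count volumes follow the voxel-size cube law", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
  s <- segmentedStructure("Me", "L", m)
  v <- computeVolume(s, 4.6, "bee01")
  expect_identical(v$volume_mm3, 1000 * (4.6 / 1000)^3)   # 9.7336e-05
  expect_identical(v$voxel_count, 1000)
  expect_equal(computeVolume(s, 9.2)$volume_mm3, 8 * v$volume_mm3)
  empty <- segmentedStructure("Me", "L", array(FALSE, c(2, 2, 2)))
  expect_equal(computeVolume(empty, 4.6)$volume_mm3, 0)
})

test_that("volume is additive over disjoint masks", {
  set.seed(61)
  for (rep in 1:5) {
    a <- randomMask(c(8L, 8L, 8L), 0.3)
    b <- randomMask(c(8L, 8L, 8L), 0.3) & !a
    va <- computeVolume(segmentedStructure("a", "unpaired", a), 4.6)
    vb <- computeVolume(segmentedStructure("b", "unpaired", b), 4.6)
    vu <- computeVolume(segmentedStructure("u", "unpaired", a | b), 4.6)
    expect_equal(vu$volume_mm3, va$volume_mm3 + vb$volume_mm3)
  }
})

test_that("percent difference is symmetric and zero iff equal", {
  expect_equal(percentDifference(5, 5), 0)
  expect_equal(percentDifference(0.0745, 0.0751),
               100 * 0.0006 / 0.0748)   # ~0.802% on the medulla means
  expect_equal(percentDifference(1, 3), 100)
  expect_equal(percentDifference(1, 3), percentDifference(3, 1))
  expect_error(percentDifference(0, 0), "undefined")
  expect_equal(percentDifference(2, 1, denominator = "first"), 50)
})

test_that("method agreement summarises matched pairs per label", {
  ids <- sprintf("b%02d", 1:19)
  a <- mkRecords(ids, "Me", "L", rep(0.075, 19))
  expect_equal(methodAgreement(a, a)$summary$mean_pct, 0)
  expect_equal(methodAgreement(a, a)$summary$q3_pct, 0)
  # one pair differing by exactly 10% (of the pair mean)
  one <- mkRecords("b01", "Me", "L", 1)
  oneB <- one; oneB$volume_mm3 <- 1 * (21 / 19)  # |a-b|/mean = 10%
  r <- methodAgreement(one, oneB)
  expect_equal(r$summary$mean_pct, 10, tolerance = 1e-6)
  # known perturbations recovered exactly
  set.seed(62)
  pert <- runif(19, -0.05, 0.05)
  base <- runif(19, 0.05, 0.1)
  b <- mkRecords(ids, "Me", "L", base * (1 + pert))
  a2 <- mkRecords(ids, "Me", "L", base)
  r2 <- methodAgreement(a2, b)
  expected <- 100 * abs(a2$volume_mm3 - b$volume_mm3) /
    ((a2$volume_mm3 + b$volume_mm3) / 2)
  expect_equal(r2$summary$mean_pct, mean(expected))
  expect_equal(r2$summary$median_pct, median(expected))
  expect_equal(r2$summary$q1_pct, unname(quantile(expected, 0.25)))
  # unmatched records are reported, not dropped
  extra <- rbind(a2, mkRecords("b99", "Me", "L", 0.07))
  r3 <- methodAgreement(extra, b)
  expect_equal(r3$unmatched$specimen_id, "b99")
  expect_error(methodAgreement(a2, mkRecords(ids, "Lo", "L", base)),
               "no records match")
})

test_that("repeatability reports n-1 sd, cv and the 2*sd score", {
  r <- repeatability(c(0.074, 0.074, 0.074, 0.074))
  expect_equal(r$sd_mm3, 0)
  expect_equal(r$cv_percent, 0)
  expect_equal(r$repeatability_score, 0)
  r2 <- repeatability(c(1, 1, 3, 3))
  expect_equal(r2$mean_mm3, 2)
  expect_equal(r2$sd_mm3, sqrt(4 / 3), tolerance = 1e-12)   # 1.1547
  expect_equal(r2$cv_percent, 100 * sqrt(4 / 3) / 2, tolerance = 1e-12)
  expect_equal(r2$repeatability_score, 2 * sqrt(4 / 3))
  expect_error(repeatability(1), "at least 2")
  expect_error(repeatability(c(0, 0)), "zero mean")
})

test_that("paired symmetry recovers exact mirror relationships", {
  ids <- sprintf("b%02d", 1:10)
  set.seed(63)
  vols <- runif(10, 0.05, 0.1)
  recs <- rbind(mkRecords(ids, "Me", "L", vols),
                mkRecords(ids, "Me", "R", vols))
  r <- pairedSymmetry(recs)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$mean_percent_diff, 0)
  # R = 2 L exactly
  recs2 <- rbind(mkRecords(ids, "Me", "L", vols),
                 mkRecords(ids, "Me", "R", 2 * vols))
  r2 <- pairedSymmetry(recs2)
  expect_equal(r2$slope, 2, tolerance = 1e-6)
  expect_equal(r2$r_squared, 1, tolerance = 1e-9)
  # missing sides are excluded and listed; <3 pairs warns
  recs3 <- rbind(mkRecords(ids[1:5], "Me", "L", vols[1:5]),
                 mkRecords(ids[1:4], "Me", "R", vols[1:4]),
                 mkRecords(ids[1:2], "Lo", "L", vols[1:2]),
                 mkRecords(ids[1:2], "Lo", "R", vols[1:2]))
  expect_warning(r3 <- pairedSymmetry(recs3), "Lo")
  expect_equal(r3$n_pairs, 4L)
  expect_equal(attr(r3, "excluded")$specimen_id, ids[5])
})

test_that("simulated 3% left-right noise keeps slope near 1 and high r2", {
  set.seed(64)
  ids <- sprintf("b%02d", 1:19)
  truth <- runif(19, 0.04, 0.12)
  recs <- rbind(
    mkRecords(ids, "Me", "L", truth * (1 + rnorm(19, 0, 0.03))),
    mkRecords(ids, "Me", "R", truth * (1 + rnorm(19, 0, 0.03))))
  r <- pairedSymmetry(recs)
  expect_lte(abs(r$slope - 1), 0.05)
  expect_gte(r$r_squared, 0.95)
})

test_that("allometry fits OLS of total volume on thorax width", {
  ids <- sprintf("b%02d", 1:12)
  w <- seq(4, 6, length.out = 12)
  cov <- data.frame(specimen_id = ids, thorax_width_mm = w)
  # volumes exactly proportional to width (split over two sides)
  recs <- rbind(mkRecords(ids, "Me", "L", 0.01 * w),
                mkRecords(ids, "Me", "R", 0.01 * w))
  r <- allometry(recs, cov)
  expect_equal(r$r_squared, 1, tolerance = 1e-6)
  expect_equal(r$slope, 0.02, tolerance = 1e-4)
  # constant volumes: slope 0, r^2 defined as 0
  recsC <- mkRecords(ids, "CB", "unpaired", rep(0.008, 12))
  rc <- allometry(recsC, cov)
  expect_equal(rc$slope, 0, tolerance = 1e-12)
  expect_equal(rc$r_squared, 0)
  expect_error(allometry(recs, cov[1:5, ]), "bee|b06")
})

test_that("the OLS fit agrees with lm() on random fixtures", {
  set.seed(65)
  for (rep in 1:5) {
    x <- runif(10, 1, 5)
    y <- 2 + 3 * x + rnorm(10)
    fit <- microCTseg:::olsFit(x, y)
    ref <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(ref)[2]))
    expect_equal(fit$intercept, unname(coef(ref)[1]))
    expect_equal(fit$r_squared, summary(ref)$r.squared)
    expect_equal(fit$slope_se, summary(ref)$coefficients[2, 2])
  }
})

test_that("allometry slope lands inside its own CI at the stated rate", {
  set.seed(66)
  hits <- 0L
  for (rep in 1:100) {
    w <- runif(19, 4, 6)
    v <- 0.01 + 0.015 * w + rnorm(19, 0, 0.004)
    ids <- sprintf("s%02d", 1:19)
    recs <- mkRecords(ids, "Me", "unpaired", pmax(v, 1e-4))
    cov <- data.frame(specimen_id = ids, thorax_width_mm = w)
    r <- allometry(recs, cov)
    if (r$ci95_slope_lo <= 0.015 && 0.015 <= r$ci95_slope_hi)
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("volume records round trip through CSV", {
  recs <- mkRecords(c("a", "b"), "Me", "L", c(0.05, 0.06))
  p <- withr::local_tempfile(fileext = ".csv")
  writeVolumeRecords(recs, p)
  back <- readVolumeRecords(p)
  expect_equal(back$volume_mm3, recs$volume_mm3)
  expect_error(readVolumeRecords(writeTrackDummy <- {
    q <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), q, row.names = FALSE); q
  }), "columns")
})
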