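test_that("phantom generation is deterministic and bimodal", {
  st <- phantomStructure("Me", "unpaired", "sphere", c(15.5, 15.5, 15.5), 10)
  sp <- phantomSpec(c(32L, 32L, 32L), structures = list(st),
                    noiseSd = "moderate", seed = 17)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(voxels(a$stack), voxels(b$stack))
  # noiseless: exactly two distinct grey values
  sp0 <- phantomSpec(c(32L, 32L, 32L), structures = list(st),
                     noiseSd = 0, seed = 17)
  v <- voxels(generatePhantom(sp0)$stack)
  expect_setequal(unique(as.vector(v)), c(20L, 180L))
})

test_that("truth voxel counts converge on analytic volumes", {
  st <- phantomStructure("Me", "unpaired", "sphere", c(19.5, 19.5, 19.5), 15)
  sp <- phantomSpec(c(40L, 40L, 40L), structures = list(st), seed = 1)
  tr <- generatePhantom(sp)$truth
  expect_lte(abs(tr$voxel_counts - 4 / 3 * pi * 15^3),
             0.02 * 4 / 3 * pi * 15^3)
  # ellipsoid
  se <- phantomStructure("AL", "unpaired", "ellipsoid",
                         c(19.5, 19.5, 19.5), c(12, 9, 7))
  spe <- phantomSpec(c(40L, 40L, 40L), structures = list(se), seed = 1)
  tre <- generatePhantom(spe)$truth
  va <- 4 / 3 * pi * 12 * 9 * 7
  expect_lte(abs(tre$voxel_counts - va), 0.03 * va)
})

test_that("two-lobe solids match inclusion-exclusion exactly", {
  lb <- rbind(c(0, 0, 0, 8), c(0, 0, 6, 7))
  st <- phantomStructure("MB", "unpaired", "lobed", c(19.5, 19.5, 16.5),
                         lobes = lb)
  sp <- phantomSpec(c(40L, 40L, 40L), structures = list(st), seed = 1)
  tr <- generatePhantom(sp)$truth
  # closed-form union volume of two overlapping spheres
  r1 <- 8; r2 <- 7; d <- 6
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  va <- 4 / 3 * pi * (r1^3 + r2^3) - lens
  expect_equal(tr$analytic_volumes_vox[["MB.unpaired"]], va)
  expect_lte(abs(tr$voxel_counts - va), 0.03 * va)
  # >= 3 lobes fall back to fine-grid integration, close to voxel count
  lb3 <- rbind(c(0, 0, 0, 8), c(0, 4, 4, 7), c(4, -2, 2, 6))
  st3 <- phantomStructure("MB", "unpaired", "lobed", c(19.5, 19.5, 19.5),
                          lobes = lb3)
  sp3 <- phantomSpec(c(44L, 44L, 44L), structures = list(st3), seed = 1)
  tr3 <- generatePhantom(sp3)$truth
  expect_lte(abs(tr3$voxel_counts - tr3$analytic_volumes_vox) /
               tr3$analytic_volumes_vox, 0.03)
})

test_that("mirrored pairs have exactly equal truth counts", {
  sL <- phantomStructure("Me", "L", "sphere", c(15.5, 15.5, 10.2), 7.3)
  sp <- phantomSpec(c(32L, 32L, 48L),
                    structures = list(sL, mirrorStructure(sL, 48L)),
                    seed = 2)
  tr <- generatePhantom(sp)$truth
  expect_identical(tr$voxel_counts[["Me.L"]], tr$voxel_counts[["Me.R"]])
})

test_that("structures crossing the midline are rejected", {
  sL <- phantomStructure("Me", "L", "sphere", c(15.5, 15.5, 22), 7)
  expect_error(phantomSpec(c(32L, 32L, 48L), structures = list(sL)),
               "midline")
})

test_that("cohorts encode the programmed allometric slope", {
  co <- generateCohort(nSpecimens = 10, baseVolumeMm3 = 0.01,
                       sizeSlope = 0, seed = 4)
  expect_equal(length(unique(round(co$true_totals_mm3, 12))), 1L)
  co2 <- generateCohort(nSpecimens = 19, baseVolumeMm3 = 0.01,
                        sizeSlope = 0.015, seed = 5)
  r <- allometry(co2$records, co2$covariates)
  expect_equal(r$slope, 0.015, tolerance = 1e-3)
  expect_gte(r$r_squared, 1 - 1e-8)
  # 3% relative noise keeps the recovered slope within 2 se
  co3 <- generateCohort(nSpecimens = 19, baseVolumeMm3 = 0.01,
                        sizeSlope = 0.015, relNoiseSd = 0.03, seed = 6)
  r3 <- allometry(co3$records, co3$covariates)
  se <- (r3$ci95_slope_hi - r3$ci95_slope_lo) / (2 * qt(0.975, 17))
  expect_lte(abs(r3$slope - 0.015), 2 * se)
  expect_error(generateCohort(5, baseVolumeMm3 = -1, sizeSlope = 0.01),
               "non-positive")
})

test_that("truth tracks trace the phantom cross-sections", {
  st <- phantomStructure("Me", "unpaired", "sphere", c(19.5, 19.5, 19.5), 12)
  sp <- phantomSpec(c(40L, 40L, 40L), structures = list(st), seed = 7)
  trk <- truthTrack(sp, "Me", "unpaired", interval = 5)
  zs <- keyframeSlices(trk)
  # first and last visible slices are keyframed
  expect_lte(min(zs) - 1, 19.5 - 12 + 1)
  expect_gte(max(zs) - 1, 19.5 + 12 - 1)
  # the central keyframe circumscribes the analytic circle by ~0.5 px
  mid <- which.min(abs(zs - 20.5))
  nd <- contourNodes(keyframes(trk)[[mid]])
  rads <- sqrt((nd[, 1] - 19.5)^2 + (nd[, 2] - 19.5)^2)
  zmid <- zs[mid] - 1
  rTrue <- sqrt(12^2 - (zmid - 19.5)^2)
  expect_true(all(abs(rads - (rTrue + 0.5)) < 1e-6))
})
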