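test_that("kidney masks have the constructed bean geometry", {
  spec <- smallSpec()
  mask <- generateKidneyMask(spec)
  # symmetric about the horizontal axis through the centre (notch offset
  # is horizontal, no jitter)
  expect_identical(mask, mask[rev(seq_len(nrow(mask))), ])
  expect_gt(sum(mask), 0)
  # notch removes pixels from the outer ellipse
  plain <- phantomSpec(dim = c(96L, 96L), outerSemiAxes = c(14, 20),
                       notchSemiAxes = c(8, 7), notchOffset = c(-60, 0),
                       semiAxisJitter = 0, seed = 1L)
  # notch fully outside -> plain ellipse; area equals the pixel-count oracle
  em <- generateKidneyMask(plain)
  g <- expand.grid(y = 1:96, x = 1:96)
  oracle <- sum(((g$x - 48.5) / 14)^2 + ((g$y - 48.5) / 20)^2 <= 1)
  expect_equal(sum(em), oracle)
  expect_gt(sum(em), sum(mask))
  # determinism
  spec2 <- smallSpec(jitter = 0.1, seed = 33L)
  expect_identical(generateKidneyMask(spec2), generateKidneyMask(spec2))
  expect_false(identical(generateKidneyMask(spec2, seed = 33L),
                         generateKidneyMask(spec2, seed = 34L)))
  expect_error(phantomSpec(dim = c(40L, 40L), outerSemiAxes = c(30, 30)),
               "exceeds")
})

test_that("phantom images follow the two-level + noise intensity model", {
  spec <- smallSpec(noiseSd = 0)
  mask <- generateKidneyMask(spec)
  img <- generateDCEImage(mask, spec)
  expect_equal(sort(unique(as.vector(img))), c(60, 150))
  # phase multiplier scales the kidney level only
  s1 <- phantomSpec(phaseMultiplier = 1, noiseSd = 0)
  s2 <- phantomSpec(phaseMultiplier = 2, noiseSd = 0)
  m <- generateKidneyMask(s1)
  expect_equal(mean(generateDCEImage(m, s2)[m]) /
                 mean(generateDCEImage(m, s1)[m]), 2)
  # noise sd close to nominal within each region (>= 1e4 pixels)
  s3 <- phantomSpec(noiseSd = 10)
  m3 <- generateKidneyMask(s3)
  i3 <- generateDCEImage(m3, s3)
  expect_gt(sum(!m3), 1e4)
  expect_equal(stats::sd(i3[!m3]), 10, tolerance = 1)
  expect_equal(stats::sd(i3[m3]), 10, tolerance = 1)
  expect_true(all(i3 >= 0 & i3 <= 255))
  expect_identical(generateDCEImage(m3, s3), generateDCEImage(m3, s3))
})

test_that("training cohorts are aligned, binary and seed-reproducible", {
  spec <- smallSpec(jitter = 0.1, seed = 4L)
  cohort <- generateTrainingCohort(12, spec)
  expect_length(cohort, 12)
  expect_true(all(vapply(cohort, function(m) all(m %in% c(TRUE, FALSE)),
                         TRUE)))
  # cohort feeds the prior builder directly
  prior <- buildShapePrior(lapply(cohort, function(m) m * 1))
  expect_s4_class(prior, "ShapePriorModel")
  # jitter > 0 produces pixels observed with both labels
  NK <- Reduce(`+`, cohort)
  expect_true(any(NK > 0 & NK < 12))
  # zero jitter: all masks identical, prior values collapse to two levels
  spec0 <- smallSpec(jitter = 0, seed = 4L)
  c0 <- generateTrainingCohort(30, spec0)
  expect_true(all(vapply(c0, identical, TRUE, y = c0[[1]])))
  p0 <- buildShapePrior(lapply(c0, function(m) m * 1))
  expect_setequal(unique(as.vector(p0@PK)), c(30 / 31, 1 / 31))
  expect_length(generateTrainingCohort(2, spec), 2)
  expect_error(generateTrainingCohort(1, spec), "at least 2")
})

test_that("affine perturbation is seeded, exact and area-preserving", {
  spec <- smallSpec(noiseSd = 5)
  mask <- generateKidneyMask(spec)
  img <- generateDCEImage(mask, spec)
  # all-zero ranges: identity, bit-for-bit
  z <- perturbAffine(img, mask, ranges = list(theta = 0, shear = 0,
                                              translate = 0, scale = 0),
                     seed = 3L)
  expect_identical(z$image, img)
  expect_identical(z$mask, mask)
  expect_equal(affineVector(z$params), affineVector(affineParams()))
  # rotation-only on a disk preserves area within 1%
  g <- expand.grid(y = 1:96, x = 1:96)
  disk <- matrix((g$x - 48.5)^2 + (g$y - 48.5)^2 <= 20^2, 96, 96)
  rot <- perturbAffine(img, disk, ranges = list(theta = 2 * pi / 180,
                                                shear = 0, translate = 0,
                                                scale = 0), seed = 8L)
  expect_equal(sum(rot$mask) / sum(disk), 1, tolerance = 0.01)
  # returned params reproduce the transform exactly
  p1 <- perturbAffine(img, mask, seed = 17L)
  sm <- renalseg:::.affineSampler(p1$params, dim(img),
                                  renalseg:::.defaultCenter(dim(img)))
  again <- renalseg:::.sampleBilinear(img, sm)
  again[!sm$inside] <- stats::median(img[!mask])
  expect_identical(again, p1$image)
  # seeded sampling is reproducible
  p2 <- perturbAffine(img, mask, seed = 17L)
  expect_identical(affineVector(p1$params), affineVector(p2$params))
})
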