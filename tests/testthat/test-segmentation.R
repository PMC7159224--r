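test_that("isodata threshold separates two-point and bimodal histograms", {
  # two-point histogram: any mixture of 0 and 255 splits exactly
  set.seed(1)
  v <- sample(c(0, 255), 1024, replace = TRUE, prob = c(0.8, 0.2))
  t2 <- isodataThreshold(matrix(v, 32, 32))
  expect_gt(t2, 0); expect_lt(t2, 255)
  expect_true(all((v >= t2) == (v == 255)))

  # fixed point of the intermeans recursion
  m1 <- mean(v[v < t2]); m2 <- mean(v[v >= t2])
  expect_lt(abs(t2 - (m1 + m2) / 2), 0.5)

  # two Gaussian modes at 30 and 200, sd 5: classification >= 99.9% correct
  set.seed(2)
  lab <- rep(c(0, 1), each = 5000)
  vv <- c(rnorm(5000, 30, 5), rnorm(5000, 200, 5))
  tb <- isodataThreshold(matrix(vv, 100, 100))
  expect_gte(mean((vv >= tb) == lab), 0.999)

  expect_error(isodataThreshold(matrix(7, 32, 32)), class = "nm_no_threshold")
})

test_that("thresholding is invariant to affine intensity rescaling", {
  set.seed(3)
  v <- matrix(c(rnorm(300, 20, 4), rnorm(724, 120, 10)), 32, 32)
  t1 <- isodataThreshold(v)
  t2 <- isodataThreshold(3.5 * v + 40)
  expect_identical(v >= t1, (3.5 * v + 40) >= t2)
})

test_that("segmentFibres recovers the drawn mask and cleans speckle", {
  sim <- generateMuscleImage(gapFraction = 0, noiseSd = 0, seed = 5)
  mask <- segmentFibres(sim$image)
  tm <- maskMatrix(sim$truth$fibreMask)
  m <- maskMatrix(mask)
  expect_gte(sum(m & tm) / sum(m | tm), 0.9)   # Jaccard vs ground truth

  blank <- matrix(0, 64, 64)
  expect_error(segmentFibres(FluorescenceImage(blank, 0.25)),
               class = "nm_no_threshold")

  # a sub-minimum-area speckle leaves the cleaned mask unchanged
  img <- intensityMatrix(sim$image)
  img2 <- img; img2[2, 2] <- max(img)
  m2 <- segmentFibres(FluorescenceImage(img2, 0.25))
  expect_identical(maskMatrix(m2), m)
})

test_that("segmentFibres is monotone in minObjectArea", {
  sim <- generateMuscleImage(gapFraction = 0.1, noiseSd = 0.05, seed = 8)
  small <- maskMatrix(segmentFibres(sim$image, minObjectArea = 1))
  large <- maskMatrix(segmentFibres(sim$image, minObjectArea = 20))
  expect_true(all(!large | small))   # larger floor never adds foreground
})

test_that("estimateCellRegion behaves like the manual cell polygon", {
  # closing is idempotent on a filled convex solid
  rect <- barMask(40, 60, 10:30, 10:50, pixelSize = 1)
  roi <- estimateCellRegion(rect, closingRadius = 3)
  expect_identical(maskMatrix(roi), maskMatrix(rect))

  # ROI is a superset of the largest fibre component and recovers the cell
  sim <- generateMuscleImage(gapFraction = 0.2, seed = 4)
  mask <- segmentFibres(sim$image)
  roi2 <- estimateCellRegion(mask)
  lbl <- nemamorph:::.label8(maskMatrix(mask))
  largest <- lbl == which.max(tabulate(lbl[lbl > 0]))
  expect_true(all(!largest | maskMatrix(roi2)))
  aTrue <- sum(maskMatrix(sim$truth$cellMask))
  expect_lte(abs(sum(maskMatrix(roi2)) - aTrue) / aTrue, 0.1)

  expect_error(estimateCellRegion(BinaryMask(matrix(FALSE, 8, 8), 1)),
               class = "nm_empty_region")
})

test_that("polygon ROIs rasterize to the enclosed pixels", {
  roi <- polygonToRoi(data.frame(x = c(2, 10, 10, 2), y = c(2, 2, 8, 8)),
                      dim = c(16, 16), pixelSize = 1)
  m <- maskMatrix(roi)
  expect_true(m[5, 5])
  expect_false(m[1, 1])
  expect_error(polygonToRoi(data.frame(x = 1:2, y = 1:2), c(8, 8), 1),
               class = "nm_invalid_input")
})
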