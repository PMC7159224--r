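test_that("thinning reduces a bar to a line and preserves lone pixels", {
  g <- buildSkeletonGraph(skeletonize(barMask()))
  nodes <- graphNodes(g)
  expect_equal(sum(nodes$type == "endpoint"), 2)
  expect_equal(sum(nodes$type == "junction"), 0)
  br <- graphBranches(g)
  expect_equal(nrow(br), 1)
  expect_true(br$n_pixels >= 36 && br$n_pixels <= 40)

  one <- matrix(FALSE, 8, 8); one[4, 5] <- TRUE
  expect_identical(maskMatrix(skeletonize(BinaryMask(one, 1))), one)

  empty <- skeletonize(BinaryMask(matrix(FALSE, 8, 8), 1))
  expect_false(any(maskMatrix(empty)))
})

test_that("skeleton invariants hold on random masks", {
  set.seed(7)
  for (i in 1:20) {
    m <- randomMask(density = runif(1, 0.1, 0.6))
    s <- maskMatrix(skeletonize(BinaryMask(m, 1)))
    expect_false(has2x2Block(s))
    expect_identical(ncomp8(s), ncomp8(m))
  }
})

test_that("branch lengths follow orthogonal/diagonal step weights", {
  g <- buildSkeletonGraph(skeletonize(pathMask(11)))
  expect_equal(graphBranches(g)$length_um, 10 * 0.25, tolerance = 1e-12)

  gd <- buildSkeletonGraph(skeletonize(diagMask(5)))
  expect_equal(graphBranches(gd)$length_um, 4 * sqrt(2) * 0.25, tolerance = 1e-12)
})

test_that("a T-shaped skeleton yields one junction, three endpoints, three branches", {
  g <- buildSkeletonGraph(skeletonize(tMask(10)))
  nodes <- graphNodes(g)
  expect_equal(sum(nodes$type == "junction"), 1)
  expect_equal(sum(nodes$type == "endpoint"), 3)
  expect_equal(nrow(graphBranches(g)), 3)
  # every arm measures close to 10 pixel steps
  expect_true(all(abs(graphBranches(g)$length_um - 10 * 0.25) <= 2 * 0.25 * sqrt(2)))
})

test_that("total branch length is bounded by foreground extent", {
  set.seed(21)
  for (i in 1:5) {
    m <- randomMask(48, 48, density = 0.35)
    sk <- skeletonize(BinaryMask(m, 0.25))
    g <- buildSkeletonGraph(sk)
    expect_lte(sum(graphBranches(g)$length_um),
               sum(maskMatrix(sk)) * 0.25 * sqrt(2))
  }
})

test_that("fibre-length filter applies the (0, 250] um rule exactly", {
  f <- filterFibreLengths(c(0, 12.5, 250, 250.1, 300))
  expect_identical(f$kept, c(12.5, 250))
  expect_equal(f$nExcludedLow, 1)
  expect_equal(f$nExcludedHigh, 2)

  e <- filterFibreLengths(numeric(0))
  expect_identical(e$kept, numeric(0))
  expect_equal(e$nExcludedLow + e$nExcludedHigh, 0)

  ok <- c(1, 100, 250)
  expect_identical(filterFibreLengths(ok)$kept, ok)
  expect_error(filterFibreLengths(c(-1, 5)), class = "nm_invalid_input")
})

test_that("gap-area ratio counts retained gap components over the cell", {
  cell <- CellROI(matrix(TRUE, 100, 100), 1)
  full <- BinaryMask(matrix(TRUE, 100, 100), 1)
  expect_equal(gapAreaRatio(cell, full), 0)

  void <- matrix(TRUE, 100, 100); void[41:60, 46:55] <- FALSE
  expect_equal(gapAreaRatio(cell, BinaryMask(void, 1), minGapArea = 5), 0.02)

  none <- BinaryMask(matrix(FALSE, 100, 100), 1)
  expect_equal(gapAreaRatio(cell, none), 1)

  # monotonicity: extra gap pixels inside the cell never lower the ratio
  void2 <- void; void2[20:28, 20:28] <- FALSE
  expect_gte(gapAreaRatio(cell, BinaryMask(void2, 1)),
             gapAreaRatio(cell, BinaryMask(void, 1)))

  expect_error(gapAreaRatio(cell, BinaryMask(matrix(TRUE, 50, 50), 1)),
               class = "nm_invalid_input")
})

test_that("the composed morphometry pipeline recovers generator truth", {
  sim <- generateMuscleImage(gapFraction = 0.21, seed = 2)
  m <- summarizeMorphometry(sim$image)
  expect_lte(abs(gapRatio(m) - sim$truth$trueGapFraction), 0.03)
  expect_true(all(fibreLengths(m) > 0 & fibreLengths(m) <= 250))

  sim2 <- generateMuscleImage(gapFraction = 0.02, seed = 3)
  m2 <- summarizeMorphometry(sim2$image)
  expect_lte(abs(gapRatio(m2) - sim2$truth$trueGapFraction), 0.02)
})
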