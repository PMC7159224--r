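test_that("muscle image generator hits its gap target and is seed-pure", {
  sim <- generateMuscleImage(gapFraction = 0.21, seed = 7)
  expect_true(abs(sim$truth$trueGapFraction - 0.21) <= 0.01)
  expect_true(all(sim$truth$fibreLengths > 0))

  # no erasure: realized gap 0 and fibre mask identical to the cell mask
  s0 <- generateMuscleImage(gapFraction = 0, noiseSd = 0, clumpCount = 0, seed = 3)
  expect_identical(s0$truth$trueGapFraction, 0)
  expect_identical(maskMatrix(s0$truth$fibreMask), maskMatrix(s0$truth$cellMask))

  # seeding contract
  a <- generateMuscleImage(gapFraction = 0.1, seed = 1)
  b <- generateMuscleImage(gapFraction = 0.1, seed = 1)
  c <- generateMuscleImage(gapFraction = 0.1, seed = 2)
  expect_identical(intensityMatrix(a$image), intensityMatrix(b$image))
  expect_false(identical(maskMatrix(a$truth$fibreMask), maskMatrix(c$truth$fibreMask)))

  expect_error(generateMuscleImage(gapFraction = 1), class = "nm_invalid_spec")
  expect_error(generateMuscleImage(pixelSize = -1), class = "nm_invalid_spec")
})

test_that("realized gap fraction tracks the target over random specs", {
  set.seed(303)
  for (i in 1:20) {
    gf <- runif(1, 0, 0.5)
    sim <- generateMuscleImage(gapFraction = gf,
                               fibreLengthMean = runif(1, 25, 55),
                               fibreAngle = runif(1, 0, 180), seed = i)
    expect_lte(abs(sim$truth$trueGapFraction - gf), 0.01)
  }
})

test_that("posture generator encodes the programmed kinematics", {
  s <- generatePostureSeries(duration = 60, bendFrequency = 1, seed = 1)
  expect_equal(s$truth$thrashCount, 60)
  s2 <- generatePostureSeries(duration = 90, bendFrequency = 0.5, seed = 1)
  expect_equal(s2$truth$thrashCount, 45)

  flat <- generatePostureSeries(bendAmplitude = 0, speed = 0,
                                noiseSdAngle = 0, seed = 1)
  expect_true(all(bendAngle(flat$posture) == 0))
  expect_true(all(positions(flat$track) == 0))

  a <- generatePostureSeries(noiseSdAngle = 3, seed = 5)
  b <- generatePostureSeries(noiseSdAngle = 3, seed = 5)
  expect_identical(bendAngle(a$posture), bendAngle(b$posture))
})

test_that("activity wells: no worms or no motility means no crossings", {
  w0 <- generateActivityWells(nWorms = 0, duration = 120, seed = 1)
  expect_equal(w0$truth$crossings, 0)
  expect_false(any(w0$states))
  wm <- generateActivityWells(nWorms = 40, motility = 0, duration = 120, seed = 1)
  expect_equal(wm$truth$crossings, 0)
  a <- generateActivityWells(nWorms = 40, duration = 600, seed = 2)
  b <- generateActivityWells(nWorms = 40, duration = 600, seed = 2)
  expect_identical(a$truth$crossings, b$truth$crossings)
  expect_gt(a$truth$crossings, 0)
})

test_that("PSC trace generator: kernel peak, Poisson counts, edge cases", {
  flat <- generatePscTrace(eventRate = 0, noiseSd = 0, seed = 1)
  expect_true(all(currentSeries(flat$trace) == 0))

  # a single noise-free event: the trace minimum sits at the recorded truth
  # time with depth equal to the recorded amplitude
  one <- generatePscTrace(duration = 20, eventRate = 1 / 20, noiseSd = 0, seed = 6)
  expect_equal(length(one$truth$times), 1)
  x <- currentSeries(one$trace)
  iMin <- which.min(x)
  expect_lte(abs((iMin - 1) / sampleRate(one$trace) - one$truth$times[1]),
             1 / sampleRate(one$trace))
  # peak is sampled on the grid, so the discretized minimum sits within a
  # sample of the continuous kernel peak
  expect_equal(min(x), -one$truth$amplitudes[1], tolerance = 1e-3)

  # Poisson tail bound: 2 Hz x 60 s, every seed within 120 +/- 4*sqrt(120)
  counts <- vapply(1:10, function(s)
    length(generatePscTrace(seed = s)$truth$times), numeric(1))
  expect_true(all(abs(counts - 120) <= 4 * sqrt(120)))

  expect_error(generatePscTrace(riseTau = 5, decayTau = 2),
               class = "nm_invalid_spec")
})

test_that("group dataset generator is seeded and degenerate-safe", {
  g <- data.frame(label = c("A", "B"), mean = c(1, 2), sd = c(0, 1), n = c(5, 5))
  d <- generateGroupDataset(g, seed = 4)
  expect_true(all(d$value[d$group == "A"] == 1))
  expect_identical(d, generateGroupDataset(g, seed = 4))
  expect_error(generateGroupDataset(data.frame(label = "A", mean = 0, sd = -1, n = 5)),
               class = "nm_invalid_spec")
  expect_error(generateGroupDataset(data.frame(label = c("A", "A"), mean = 0,
                                               sd = 1, n = 5)),
               class = "nm_invalid_spec")
})
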