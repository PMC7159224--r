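test_that("thrash counter scores one count per full bend cycle", {
  s <- uniformSeries(60, 30, 45 * sin(2 * pi * 1 * (0:1799) / 30))
  th <- countThrashes(s, hysteresisDeg = 10)
  expect_equal(th$count, 60)
  expect_equal(th$perMin, 60)

  flat <- uniformSeries(60, 30, rep(0, 1800))
  expect_equal(countThrashes(flat, 10)$count, 0)

  short <- uniformSeries(5, 30, rep(0, 150))
  expect_error(countThrashes(short), class = "nm_invalid_input")

  jag <- PostureSeries(c(0, 1, 2, 3.5, 4, 5, 6, 7, 8, 9, 10, 11), rep(0, 12))
  expect_error(countThrashes(jag, 10), class = "nm_invalid_series")
})

test_that("thrash counting survives noise and dorsoventral relabelling", {
  for (s in 1:8) {
    sim <- generatePostureSeries(duration = 60, bendFrequency = 1,
                                 bendAmplitude = 45, noiseSdAngle = 4.5,
                                 seed = s)
    n <- countThrashes(sim$posture)$count
    expect_lte(abs(n - 60), 1)
    flipped <- PostureSeries(frameTimes(sim$posture), -bendAngle(sim$posture))
    expect_lte(abs(countThrashes(flipped)$count - n), 1)
  }
})

test_that("body-bend counter scores alternations, same side only once", {
  s <- uniformSeries(180, 30, 40 * sin(2 * pi * 0.5 * (0:5399) / 30))
  expect_equal(countBodyBends(s, 10)$perMin, 60)

  # +, + (same-side repeat), - : two bends, not three
  ang <- c(0, 20, 0, 25, 0, -20, 0, rep(0, 8))
  ss <- uniformSeries(15, 1, ang)
  expect_equal(countBodyBends(ss, 10)$count, 2)

  # synthetic truth 25 bends/min (f = 25/120 Hz)
  sim <- generatePostureSeries(duration = 120, bendFrequency = 25 / 120,
                               noiseSdAngle = 3, seed = 2)
  expect_lte(abs(countBodyBends(sim$posture)$perMin - 25), 1)
})

test_that("rates are stable when a periodic series doubles in length", {
  mk <- function(dur) uniformSeries(dur, 30, 45 * sin(2 * pi * 0.7 * (0:(dur * 30 - 1)) / 30))
  r1 <- countThrashes(mk(60), 10)$perMin
  r2 <- countThrashes(mk(120), 10)$perMin
  expect_lte(abs(r2 - r1) / r1, 0.02)
})

test_that("speed is path length over time, invariant to isometry", {
  tr <- CentroidTrack(0:10, (0:10) * 100, rep(0, 11))
  sp <- computeSpeed(tr)
  expect_equal(sp$pathSpeed, 100)
  expect_equal(sp$netSpeed, 100)

  still <- CentroidTrack(0:10, rep(5, 11), rep(-3, 11))
  expect_equal(computeSpeed(still)$pathSpeed, 0)

  th <- 0.7
  rot <- CentroidTrack(0:10, cos(th) * (0:10) * 100 + 50,
                       sin(th) * (0:10) * 100 - 20)
  expect_equal(computeSpeed(rot)$pathSpeed, 100, tolerance = 1e-9)

  # duplicate timestamps are rejected at construction (type invariant)
  expect_error(CentroidTrack(c(0, 1, 1, 2), c(0, 1, 2, 3), rep(0, 4)))
  expect_error(computeSpeed(CentroidTrack(0, 1, 1)), class = "nm_invalid_input")
})

test_that("activity counts integrate beam toggles per bin", {
  times <- 0:239
  states <- matrix(FALSE, 240, 4)
  expect_true(all(activityCount(states, times, 60)$count == 0))

  # one beam toggling every second: 60 toggles per 60 s bin (toggle at each
  # sample after the first)
  tog <- matrix(FALSE, 240, 1)
  tog[, 1] <- rep(c(FALSE, TRUE), 120)
  ac <- activityCount(tog, times, 60)
  expect_true(all(abs(ac$count[1:3] - 60) <= 1))

  # synthetic wells: zero worms silent; counts increase with motility
  w0 <- generateActivityWells(nWorms = 0, duration = 600, seed = 1)
  expect_equal(sum(activityCount(w0$states, w0$times, 60)$count), 0)
  lo <- generateActivityWells(nWorms = 40, motility = 1, duration = 1200, seed = 3)
  hi <- generateActivityWells(nWorms = 40, motility = 6, duration = 1200, seed = 3)
  expect_gt(sum(activityCount(hi$states, hi$times, 60)$count),
            sum(activityCount(lo$states, lo$times, 60)$count))
  expect_equal(sum(abs(diff(lo$states)) > 0) , lo$truth$crossings)
})

test_that("relative length change is a plain percent of the pre-drug length", {
  expect_equal(relativeLengthChange(1000, 800), -20)
  expect_equal(relativeLengthChange(750, 750), 0)
  expect_equal(relativeLengthChange(1000, 1100), 10)
  expect_error(relativeLengthChange(0, 500), class = "nm_invalid_input")
})

test_that("time to paralysis needs sustained quiescence", {
  dt <- 0.5
  t <- seq(0, 320, by = dt)
  moving <- t < 300
  x <- cumsum(c(0, ifelse(moving[-1], 50 * dt, 0)))
  ang <- ifelse(moving, 30 * sin(2 * pi * 0.5 * t), 0)
  track <- CentroidTrack(t, x, rep(0, length(t)))
  posture <- PostureSeries(t, ang)
  tp <- timeToParalysis(track, posture, sustainS = 10)
  expect_lte(abs(tp - 300), 2 * dt)

  # never quiescent
  busy <- PostureSeries(t, 30 * sin(2 * pi * 0.5 * t))
  xb <- cumsum(c(0, rep(50 * dt, length(t) - 1)))
  expect_true(is.na(timeToParalysis(CentroidTrack(t, xb, 0 * t), busy)))

  # a 5 s pause is ignored under a 10 s sustain rule
  pause <- t >= 100 & t < 105
  mv <- !pause
  x2 <- cumsum(c(0, ifelse(mv[-1], 50 * dt, 0)))
  ang2 <- ifelse(mv, 30 * sin(2 * pi * 0.5 * t), 0)
  tp2 <- timeToParalysis(CentroidTrack(t, x2, 0 * t), PostureSeries(t, ang2),
                         sustainS = 10)
  expect_true(is.na(tp2) || tp2 > 105)
})
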