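# Hysteresis state machine over a signed bend-angle series: the state is +1
# after the angle exceeds +h, -1 after it drops below -h, and unchanged in
# between. Returns the collapsed state sequence (one entry per state entry),
# which is what both counters consume. The dead band rejects angle noise the
# way a human counter ignores wobble short of a maximum bend.
.hysteresisEntries <- function(angle, h) {
  state <- 0L
  entries <- integer(0)
  for (a in angle) {
    s <- if (a > h) 1L else if (a < -h) -1L else state
    if (s != state && s != 0L) entries <- c(entries, s)
    if (s != 0L) state <- s
  }
  entries
}

.defaultHysteresis <- function(angle) {
  max(10, 0.3 * stats::quantile(abs(angle), 0.9, names = FALSE))
}

.seriesDuration <- function(times) {
  dt <- .checkUniformTimes(times)
  diff(range(times)) + dt
}

#' Count swimming thrashes
#'
#' A thrash is one complete cycle of maximum bend on one side of the body
#' and back. The signed bend angle is passed through a hysteresis state
#' machine with thresholds at +/-\code{hysteresisDeg}; one thrash is scored
#' per completed two-alternation cycle, and the per-minute rate is
#' \code{count * 60 / duration}.
#'
#' @param series a \linkS4class{PostureSeries} of at least 10 s, uniformly
#'   sampled (frame interval constant within 1\%).
#' @param hysteresisDeg dead-band half-width in degrees; defaults to
#'   \code{max(10, 0.3 * quantile(abs(angle), 0.9))}, a fixed floor plus an
#'   amplitude-adaptive term.
#' @return list with \code{count}, \code{perMin} and the \code{hysteresisDeg}
#'   used.
#' @export
countThrashes <- function(series, hysteresisDeg = NULL) {
  stopifnot(is(series, "PostureSeries"))
  dur <- .seriesDuration(series@times)
  if (dur < 10)
    nmStop("nm_invalid_input", "posture series must cover at least 10 s")
  h <- hysteresisDeg %||% .defaultHysteresis(series@angle)
  entries <- .hysteresisEntries(series@angle, h)
  nAlt <- if (length(entries) > 1L) sum(diff(entries) != 0L) else 0L
  count <- floor(nAlt / 2 + 0.5)
  list(count = count, perMin = count * 60 / dur, hysteresisDeg = h)
}

#' Count crawling body bends
#'
#' One body bend is scored per maximum bend of the post-pharyngeal region to
#' the opposite side, i.e. per entry into a new hysteresis state (two bends
#' per full sinusoidal cycle). Consecutive excursions to the same side are
#' counted once: a reverse bend in the same direction never re-enters the
#' state and so is not double-counted.
#'
#' @inheritParams countThrashes
#' @return list with \code{count}, \code{perMin}, \code{hysteresisDeg}.
#' @export
countBodyBends <- function(series, hysteresisDeg = NULL) {
  stopifnot(is(series, "PostureSeries"))
  dur <- .seriesDuration(series@times)
  if (dur < 10)
    nmStop("nm_invalid_input", "posture series must cover at least 10 s")
  h <- hysteresisDeg %||% .defaultHysteresis(series@angle)
  entries <- .hysteresisEntries(series@angle, h)
  count <- length(entries)
  list(count = count, perMin = count * 60 / dur, hysteresisDeg = h)
}

#' Centroid speed
#'
#' Path speed is the mean per-frame displacement over frame interval (what a
#' centroid tracker reports); net speed, reported alongside, is the net
#' start-to-end displacement over the total duration.
#'
#' @param track a \linkS4class{CentroidTrack} with at least 2 points.
#' @return list with \code{pathSpeed} and \code{netSpeed}, um/s.
#' @export
computeSpeed <- function(track) {
  stopifnot(is(track, "CentroidTrack"))
  n <- length(track@times)
  if (n < 2L) nmStop("nm_invalid_input", "track needs at least 2 points")
  dt <- diff(track@times)
  if (any(dt <= 0)) nmStop("nm_invalid_series", "duplicate or unordered timestamps")
  d <- sqrt(diff(track@x)^2 + diff(track@y)^2)
  list(pathSpeed = mean(d / dt),
       netSpeed = sqrt((track@x[n] - track@x[1])^2 +
                         (track@y[n] - track@y[1])^2) /
         (track@times[n] - track@times[1]))
}

#' Population activity counts from beam states
#'
#' Counts beam-state toggles (each toggle is one beam crossing) summed over
#' all beams within consecutive time bins -- the arbitrary-unit activity
#' count of an infrared beam-grid motility reader.
#'
#' @param states logical or 0/1 matrix, time by beams.
#' @param times sample times in seconds (common to all beams).
#' @param binS bin width in seconds (default 60).
#' @return data.frame with \code{bin_start_s} and \code{count}.
#' @export
activityCount <- function(states, times, binS = 60) {
  states <- as.matrix(states) != 0
  if (nrow(states) != length(times))
    nmStop("nm_invalid_input", "states and times lengths differ")
  toggles <- states[-1, , drop = FALSE] != states[-nrow(states), , drop = FALSE]
  tTog <- times[-1]
  binStarts <- seq(times[1], max(times), by = binS)
  bin <- findInterval(tTog, binStarts)
  counts <- vapply(seq_along(binStarts), function(b) {
    sum(toggles[bin == b, , drop = FALSE])
  }, numeric(1))
  data.frame(bin_start_s = binStarts, count = counts)
}

#' Relative body-length change under a contracting drug
#'
#' @param before body length before drug addition, um (\code{> 0}).
#' @param after body length at paralysis, um.
#' @return percent change, \code{100 * (after - before) / before}
#'   (negative for contraction).
#' @export
relativeLengthChange <- function(before, after) {
  if (any(before <= 0))
    nmStop("nm_invalid_input", "body length before treatment must be positive")
  100 * (after - before) / before
}

#' Time to full paralysis
#'
#' The first time from which centroid speed stays below \code{epsUmS} and
#' the absolute bend-angle rate below \code{epsDegS} continuously for
#' \code{sustainS} seconds. Returns the start of that quiescent window, or
#' \code{NA} when the animal never satisfies the criterion (not paralyzed).
#'
#' @param track a \linkS4class{CentroidTrack}.
#' @param posture a \linkS4class{PostureSeries} on the same time base.
#' @param epsUmS speed threshold, um/s (default 5).
#' @param epsDegS angular-rate threshold, deg/s (default 2).
#' @param sustainS required quiescent duration, s (default 10).
#' @return time in seconds, or \code{NA_real_}.
#' @export
timeToParalysis <- function(track, posture, epsUmS = 5, epsDegS = 2,
                            sustainS = 10) {
  stopifnot(is(track, "CentroidTrack"), is(posture, "PostureSeries"))
  dtA <- .checkUniformTimes(posture@times)
  .checkUniformTimes(track@times)
  if (diff(range(posture@times)) < sustainS)
    nmStop("nm_invalid_input", "series shorter than the sustain window")
  # per-interval rates on the track grid, interpolated to the posture grid
  spd <- sqrt(diff(track@x)^2 + diff(track@y)^2) / diff(track@times)
  spdMid <- (track@times[-1] + track@times[-length(track@times)]) / 2
  angRate <- abs(diff(posture@angle)) / diff(posture@times)
  angMid <- (posture@times[-1] + posture@times[-length(posture@times)]) / 2
  spdAt <- stats::approx(spdMid, spd, xout = angMid, rule = 2)$y
  quiet <- spdAt < epsUmS & angRate < epsDegS
  need <- ceiling(sustainS / dtA)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  angMid[starts[ok[1]]] - dtA / 2
}
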