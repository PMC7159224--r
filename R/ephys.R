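#' Running-median baseline of a current trace
#'
#' A running median is robust to the sparse, brief inward deflections of
#' spontaneous events while tracking slow drift in the holding current.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param windowMs window width in milliseconds (default 200, \code{>= 10}).
#' @return numeric baseline series, same length as the trace.
#' @export
estimateBaseline <- function(trace, windowMs = 200) {
  stopifnot(is(trace, "CurrentTrace"))
  if (windowMs < 10)
    nmStop("nm_invalid_input", "baseline window must be at least 10 ms")
  n <- length(trace@current)
  k <- round(windowMs / 1000 * trace@sampleRate)
  if (k > n)
    nmStop("nm_invalid_input", "baseline window is longer than the trace")
  if (k %% 2 == 0) k <- k + 1L
  as.numeric(stats::runmed(trace@current, k, endrule = "median"))
}

#' Detect spontaneous postsynaptic current events
#'
#' Threshold detection of inward (negative) deflections, sign convention of
#' a muscle clamped at -60 mV. The noise scale is \code{1.4826 * MAD} of the
#' baseline-subtracted trace; samples below \code{-kMad * sigma} mark event
#' regions, each local minimum is a candidate event with amplitude
#' \code{|minimum - baseline|}, minima closer than \code{minSepMs} are
#' merged into the deeper one, and regions narrower than \code{minWidthMs}
#' are discarded (noise excursions last one or two samples; real events with
#' millisecond rise and decay stay below threshold far longer).
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param kMad detection threshold in robust noise SDs (default 4).
#' @param minSepMs minimum separation between events, ms (default 5).
#' @param windowMs baseline window, ms (default 200).
#' @param minWidthMs minimum time below threshold, ms (default 1).
#' @return a \linkS4class{PscEventSet}. A zero-variance trace yields an
#'   empty event set, not an error.
#' @export
detectPscEvents <- function(trace, kMad = 4, minSepMs = 5, windowMs = 200,
                            minWidthMs = 1) {
  stopifnot(is(trace, "CurrentTrace"))
  x <- trace@current
  sr <- trace@sampleRate
  dur <- length(x) / sr
  b <- estimateBaseline(trace, windowMs)
  r <- x - b
  sigma <- stats::mad(r)
  if (sigma == 0) sigma <- stats::sd(r)
  if (!is.finite(sigma) || sigma == 0)
    return(PscEventSet(numeric(0), numeric(0), dur))

  below <- r < -kMad * sigma
  if (!any(below)) return(PscEventSet(numeric(0), numeric(0), dur))

  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= max(1L, round(minWidthMs / 1000 * sr))
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(PscEventSet(numeric(0), numeric(0), dur))

  # re-arm hysteresis: a noise blip that lifts an event's decay briefly above
  # the detection threshold does not start a new event unless the trace has
  # recovered above half the threshold in between
  rearm <- -kMad / 2 * sigma
  if (length(starts) > 1L) {
    ms <- starts[1]; me <- ends[1]
    outS <- integer(0); outE <- integer(0)
    for (i in 2:length(starts)) {
      gapMax <- if (starts[i] > me + 1L) max(r[(me + 1L):(starts[i] - 1L)]) else -Inf
      if (gapMax < rearm) {
        me <- ends[i]
      } else {
        outS <- c(outS, ms); outE <- c(outE, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    starts <- c(outS, ms); ends <- c(outE, me)
  }

  # one candidate per sub-threshold region: its deepest point (noise along
  # an event's decay produces several local minima inside one region, which
  # are all the same event)
  cand <- vapply(seq_along(starts), function(i) {
    starts[i] + which.min(r[starts[i]:ends[i]]) - 1L
  }, integer(1))
  cand <- sort(cand)

  # merge minima closer than minSepMs, keeping the deeper one
  minSep <- round(minSepMs / 1000 * sr)
  kept <- integer(0)
  for (idx in cand) {
    if (length(kept) && idx - kept[length(kept)] < minSep) {
      if (r[idx] < r[kept[length(kept)]]) kept[length(kept)] <- idx
    } else kept <- c(kept, idx)
  }
  # amplitude from a short mean around the peak rather than the raw
  # minimum, which rides the noise trough and overstates the event by
  # roughly one noise SD
  w <- max(1L, round(0.3 / 1000 * sr))
  amp <- vapply(kept, function(i) {
    abs(mean(r[max(1L, i - w):min(length(r), i + w)]))
  }, numeric(1))
  PscEventSet(times = (kept - 1L) / sr, amplitudes = amp, duration = dur)
}

#' Summarize a PSC event set
#'
#' @param events a \linkS4class{PscEventSet}.
#' @param durationS recording duration in seconds (\code{> 0}); defaults to
#'   the duration stored in the event set.
#' @return list with \code{frequencyHz} (count/duration) and
#'   \code{meanAmplitudePa} (NA when no events).
#' @export
summarizePsc <- function(events, durationS = NULL) {
  stopifnot(is(events, "PscEventSet"))
  dur <- durationS %||% events@duration
  if (dur <= 0) nmStop("nm_invalid_input", "duration must be positive")
  list(frequencyHz = length(events@times) / dur,
       meanAmplitudePa = meanAmplitude(events))
}
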