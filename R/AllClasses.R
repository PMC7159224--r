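#' FluorescenceImage: a calibrated 2-D fluorescence intensity grid
#'
#' Container for a single-channel fluorescence micrograph (e.g. GFP::MYO-3
#' labelled body-wall muscle) together with its pixel calibration. All
#' downstream morphometry is expressed in micrometres via \code{pixelSize}.
#'
#' @slot img numeric matrix of non-negative intensities (row, col).
#' @slot pixelSize physical pixel edge length in micrometres per pixel.
#' @export
setClass("FluorescenceImage",
  representation(img = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.isScalarNum(object@pixelSize) || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive scalar (um/pixel)")
    if (nrow(object@img) < 32 || ncol(object@img) < 32)
      msg <- c(msg, "image must be at least 32x32 pixels")
    if (any(!is.finite(object@img)) || any(object@img < 0))
      msg <- c(msg, "intensities must be finite and non-negative")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a segmentation mask with pixel calibration
#'
#' @slot mask logical matrix; TRUE marks foreground (fibre) pixels.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be a logical matrix")
    if (!.isScalarNum(object@pixelSize) || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' CellROI: a single muscle-cell region of interest
#'
#' One connected region marking the extent of a single body-wall muscle cell,
#' either estimated from the fibre mask or rasterized from a user polygon.
#'
#' @slot region logical matrix, one connected component of TRUE pixels.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("CellROI",
  representation(region = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@region)) msg <- c(msg, "region must be logical")
    if (sum(object@region) < 1L) msg <- c(msg, "region must contain at least one pixel")
    if (!.isScalarNum(object@pixelSize) || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Skeleton: one-pixel-wide medial representation of a binary mask
#'
#' @slot pixels logical matrix of skeleton pixels.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("Skeleton",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    if (!.isScalarNum(object@pixelSize) || object@pixelSize <= 0)
      return("pixelSize must be a positive scalar")
    TRUE
  })

#' SkeletonGraph: endpoints, junctions and branches of a skeleton
#'
#' Nodes are skeleton pixels with one 8-neighbour (endpoints) or three or
#' more (junctions); isolated pixels are their own nodes. Branches are pixel
#' paths between nodes; their geometric length sums orthogonal steps at
#' \code{pixelSize} and diagonal steps at \code{pixelSize * sqrt(2)}.
#'
#' @slot nodes data.frame with columns id, row, col, type
#'   ("endpoint", "junction", "isolated", "loop").
#' @slot branches data.frame with columns branch_id, from, to, n_pixels,
#'   length_um.
#' @slot paths list of integer matrices (row, col) giving each branch's pixels.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", branches = "data.frame",
                 paths = "list", pixelSize = "numeric"))

#' MuscleMorphometry: per-image muscle morphology summary
#'
#' Carries the filtered fibre-length sample (lengths in (0, 250] um; zero
#' lengths and lengths above 250 um are excluded and counted) and the
#' gap-to-total-cell-area ratio.
#'
#' @slot fibreLengths numeric, kept branch lengths in micrometres.
#' @slot meanLength mean of the kept lengths (NA when none kept).
#' @slot gapRatio gap area / cell area, in [0, 1].
#' @slot nExcludedLow number of zero-length records excluded.
#' @slot nExcludedHigh number of records above 250 um excluded.
#' @export
setClass("MuscleMorphometry",
  representation(fibreLengths = "numeric", meanLength = "numeric",
                 gapRatio = "numeric", nExcludedLow = "integer",
                 nExcludedHigh = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gapRatio) != 1L || is.na(object@gapRatio) ||
        object@gapRatio < 0 || object@gapRatio > 1)
      msg <- c(msg, "gapRatio must lie in [0, 1]")
    if (length(object@fibreLengths) &&
        (any(object@fibreLengths <= 0) || any(object@fibreLengths > 250)))
      msg <- c(msg, "fibreLengths must lie in (0, 250] um")
    if (length(msg)) msg else TRUE
  })

#' PostureSeries: per-frame dorsoventral bend angle
#'
#' @slot times frame times in seconds, strictly increasing.
#' @slot angle signed bend angle in degrees of the post-pharyngeal region.
#' @export
setClass("PostureSeries",
  representation(times = "numeric", angle = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@angle))
      msg <- c(msg, "times and angle must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' CentroidTrack: worm centroid positions over time
#'
#' @slot times seconds, strictly increasing.
#' @slot x,y centroid coordinates in micrometres.
#' @export
setClass("CentroidTrack",
  representation(times = "numeric", x = "numeric", y = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@x) ||
        length(object@times) != length(object@y))
      msg <- c(msg, "times, x and y must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' CurrentTrace: a voltage-clamp current recording
#'
#' Whole-cell current from a muscle clamped at the holding potential
#' (-60 mV in the neuromuscular-junction protocol); inward currents are
#' negative by convention.
#'
#' @slot current pA series.
#' @slot sampleRate Hz, at least 1000.
#' @slot holdingPotential mV (metadata).
#' @export
setClass("CurrentTrace",
  representation(current = "numeric", sampleRate = "numeric",
                 holdingPotential = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.isScalarNum(object@sampleRate) || object@sampleRate < 1000)
      msg <- c(msg, "sampleRate must be at least 1000 Hz")
    if (any(!is.finite(object@current)))
      msg <- c(msg, "current values must be finite")
    if (length(msg)) msg else TRUE
  })

#' PscEventSet: detected spontaneous postsynaptic current events
#'
#' @slot times event (peak) times in seconds, strictly increasing.
#' @slot amplitudes positive magnitudes in pA of the inward deflections.
#' @slot duration trace duration in seconds used for the frequency.
#' @export
setClass("PscEventSet",
  representation(times = "numeric", amplitudes = "numeric",
                 duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@amplitudes))
      msg <- c(msg, "times and amplitudes must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "event times must be strictly increasing")
    if (length(object@amplitudes) && any(object@amplitudes <= 0))
      msg <- c(msg, "amplitudes must be positive magnitudes")
    if (!.isScalarNum(object@duration) || object@duration <= 0)
      msg <- c(msg, "duration must be positive")
    if (length(msg)) msg else TRUE
  })

## ---- constructors ----------------------------------------------------------

#' Create a FluorescenceImage
#' @param img numeric matrix of non-negative intensities.
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{FluorescenceImage}.
#' @export
FluorescenceImage <- function(img, pixelSize) {
  new("FluorescenceImage", img = img, pixelSize = as.numeric(pixelSize))
}

#' Create a BinaryMask
#' @param mask logical matrix.
#' @param pixelSize micrometres per pixel.
#' @export
BinaryMask <- function(mask, pixelSize) {
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask, pixelSize = as.numeric(pixelSize))
}

#' Create a CellROI
#' @param region logical matrix with one connected region of TRUE pixels.
#' @param pixelSize micrometres per pixel.
#' @export
CellROI <- function(region, pixelSize) {
  storage.mode(region) <- "logical"
  new("CellROI", region = region, pixelSize = as.numeric(pixelSize))
}

#' Create a Skeleton
#' @param pixels logical matrix of skeleton pixels.
#' @param pixelSize micrometres per pixel.
#' @export
Skeleton <- function(pixels, pixelSize) {
  storage.mode(pixels) <- "logical"
  new("Skeleton", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Create a PostureSeries
#' @param times seconds.
#' @param angle degrees.
#' @export
PostureSeries <- function(times, angle) {
  new("PostureSeries", times = as.numeric(times), angle = as.numeric(angle))
}

#' Create a CentroidTrack
#' @param times seconds.
#' @param x,y micrometres.
#' @export
CentroidTrack <- function(times, x, y) {
  new("CentroidTrack", times = as.numeric(times), x = as.numeric(x),
      y = as.numeric(y))
}

#' Create a CurrentTrace
#' @param current pA series (inward negative).
#' @param sampleRate Hz.
#' @param holdingPotential mV, defaults to -60.
#' @export
CurrentTrace <- function(current, sampleRate, holdingPotential = -60) {
  new("CurrentTrace", current = as.numeric(current),
      sampleRate = as.numeric(sampleRate),
      holdingPotential = as.numeric(holdingPotential))
}

#' Create a PscEventSet
#' @param times event times in seconds.
#' @param amplitudes positive pA magnitudes.
#' @param duration trace duration in seconds.
#' @export
PscEventSet <- function(times, amplitudes, duration) {
  new("PscEventSet", times = as.numeric(times),
      amplitudes = as.numeric(amplitudes), duration = as.numeric(duration))
}

## ---- generics and accessors ------------------------------------------------

#' Pixel calibration accessor
#' @param x an image-like object.
#' @return micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname pixelSize
setMethod("pixelSize", "FluorescenceImage", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "CellROI", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "Skeleton", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "SkeletonGraph", function(x) x@pixelSize)

#' Intensity matrix accessor
#' @param x a \linkS4class{FluorescenceImage}.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname intensityMatrix
setMethod("intensityMatrix", "FluorescenceImage", function(x) x@img)

#' Logical pixel grid accessor
#' @param x a \linkS4class{BinaryMask}, \linkS4class{CellROI} or
#'   \linkS4class{Skeleton}.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname maskMatrix
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)
#' @rdname maskMatrix
setMethod("maskMatrix", "CellROI", function(x) x@region)
#' @rdname maskMatrix
setMethod("maskMatrix", "Skeleton", function(x) x@pixels)

#' Skeleton-graph node table
#' @param x a \linkS4class{SkeletonGraph}.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname graphNodes
setMethod("graphNodes", "SkeletonGraph", function(x) x@nodes)

#' Skeleton-graph branch table
#' @param x a \linkS4class{SkeletonGraph}.
#' @export
setGeneric("graphBranches", function(x) standardGeneric("graphBranches"))
#' @rdname graphBranches
setMethod("graphBranches", "SkeletonGraph", function(x) x@branches)

#' Kept fibre lengths (um)
#' @param x a \linkS4class{MuscleMorphometry}.
#' @export
setGeneric("fibreLengths", function(x) standardGeneric("fibreLengths"))
#' @rdname fibreLengths
setMethod("fibreLengths", "MuscleMorphometry", function(x) x@fibreLengths)

#' Gap-to-total-cell-area ratio
#' @param x a \linkS4class{MuscleMorphometry}.
#' @export
setGeneric("gapRatio", function(x) standardGeneric("gapRatio"))
#' @rdname gapRatio
setMethod("gapRatio", "MuscleMorphometry", function(x) x@gapRatio)

#' Mean kept fibre length (um)
#' @param x a \linkS4class{MuscleMorphometry}.
#' @export
setGeneric("meanFibreLength", function(x) standardGeneric("meanFibreLength"))
#' @rdname meanFibreLength
setMethod("meanFibreLength", "MuscleMorphometry", function(x) x@meanLength)

#' Frame / sample times accessor
#' @param x a time-series object.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname frameTimes
setMethod("frameTimes", "PostureSeries", function(x) x@times)
#' @rdname frameTimes
setMethod("frameTimes", "CentroidTrack", function(x) x@times)

#' Bend-angle series (degrees)
#' @param x a \linkS4class{PostureSeries}.
#' @export
setGeneric("bendAngle", function(x) standardGeneric("bendAngle"))
#' @rdname bendAngle
setMethod("bendAngle", "PostureSeries", function(x) x@angle)

#' Centroid positions as a two-column matrix (um)
#' @param x a \linkS4class{CentroidTrack}.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname positions
setMethod("positions", "CentroidTrack", function(x) cbind(x = x@x, y = x@y))

#' Current series accessor (pA)
#' @param x a \linkS4class{CurrentTrace}.
#' @export
setGeneric("currentSeries", function(x) standardGeneric("currentSeries"))
#' @rdname currentSeries
setMethod("currentSeries", "CurrentTrace", function(x) x@current)

#' Sampling rate accessor (Hz)
#' @param x a \linkS4class{CurrentTrace}.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname sampleRate
setMethod("sampleRate", "CurrentTrace", function(x) x@sampleRate)

#' Event times (s)
#' @param x a \linkS4class{PscEventSet}.
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname eventTimes
setMethod("eventTimes", "PscEventSet", function(x) x@times)

#' Event amplitudes (pA, positive magnitudes)
#' @param x a \linkS4class{PscEventSet}.
#' @export
setGeneric("eventAmplitudes", function(x) standardGeneric("eventAmplitudes"))
#' @rdname eventAmplitudes
setMethod("eventAmplitudes", "PscEventSet", function(x) x@amplitudes)

#' Event frequency (Hz): count / duration
#' @param x a \linkS4class{PscEventSet}.
#' @export
setGeneric("pscFrequency", function(x) standardGeneric("pscFrequency"))
#' @rdname pscFrequency
setMethod("pscFrequency", "PscEventSet", function(x) length(x@times) / x@duration)

#' Mean event amplitude (pA); NA when no events were detected
#' @param x a \linkS4class{PscEventSet}.
#' @export
setGeneric("meanAmplitude", function(x) standardGeneric("meanAmplitude"))
#' @rdname meanAmplitude
setMethod("meanAmplitude", "PscEventSet", function(x) {
  if (length(x@amplitudes)) mean(x@amplitudes) else NA_real_
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "FluorescenceImage", function(object) {
  cat(sprintf("FluorescenceImage: %d x %d px, %.4g um/px, range [%.3g, %.3g]\n",
              nrow(object@img), ncol(object@img), object@pixelSize,
              min(object@img), max(object@img)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %.4g um/px, %d foreground px (%.1f%%)\n",
              nrow(object@mask), ncol(object@mask), object@pixelSize,
              sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "CellROI", function(object) {
  a <- sum(object@region)
  cat(sprintf("CellROI: %d px (%.1f um^2)\n", a, a * object@pixelSize^2))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d px on a %d x %d grid, %.4g um/px\n",
              sum(object@pixels), nrow(object@pixels), ncol(object@pixels),
              object@pixelSize))
})

setMethod("show", "SkeletonGraph", function(object) {
  tt <- table(factor(object@nodes$type,
                     levels = c("endpoint", "junction", "isolated", "loop")))
  cat(sprintf(
    "SkeletonGraph: %d nodes (%d endpoints, %d junctions), %d branches, total %.1f um\n",
    nrow(object@nodes), tt[["endpoint"]], tt[["junction"]],
    nrow(object@branches), sum(object@branches$length_um)))
})

setMethod("show", "MuscleMorphometry", function(object) {
  cat(sprintf(
    "MuscleMorphometry: %d fibres kept (mean %.1f um), gap ratio %.3f, excluded %d low / %d high\n",
    length(object@fibreLengths), object@meanLength, object@gapRatio,
    object@nExcludedLow, object@nExcludedHigh))
})

setMethod("show", "PostureSeries", function(object) {
  cat(sprintf("PostureSeries: %d frames over %.1f s\n",
              length(object@times), diff(range(object@times))))
})

setMethod("show", "CentroidTrack", function(object) {
  cat(sprintf("CentroidTrack: %d points over %.1f s\n",
              length(object@times), diff(range(object@times))))
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %.1f s at %g Hz, held at %g mV\n",
              length(object@current) / object@sampleRate, object@sampleRate,
              object@holdingPotential))
})

setMethod("show", "PscEventSet", function(object) {
  cat(sprintf("PscEventSet: %d events in %.1f s (%.2f Hz), mean amplitude %.1f pA\n",
              length(object@times), object@duration, pscFrequency(object),
              meanAmplitude(object)))
})
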