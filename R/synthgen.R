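#' Generate a synthetic muscle-fibre fluorescence image with ground truth
#'
#' Emulates a GFP-labelled body-wall muscle cell: parallel obliquely
#' oriented fibres drawn inside a spindle-shaped (tapered) cell, with
#' fibre-free gaps erased until a requested area fraction is reached, then
#' optional bright clump artefacts, point-spread blur and additive Gaussian
#' noise. The ground truth records the post-erasure fibre fragment lengths,
#' the realized gap fraction, the post-erasure fibre mask and the
#' pre-erasure cell mask, giving every downstream morphometry stage a
#' parameter-recovery oracle.
#'
#' With the default \code{fibreWidth == fibreSpacing} the fibre stripes tile
#' the cell contiguously (striation appears as an intensity modulation), so
#' the non-fibre area inside the cell is exactly the erased gap area --
#' the regime in which the gap-to-area ratio is a clean recovery target.
#' Setting \code{fibreWidth < fibreSpacing} draws separated fibres suitable
#' for per-fibre length recovery.
#'
#' @param imageShape c(rows, cols) in pixels.
#' @param pixelSize um per pixel (default 0.25, typical of a 400x
#'   magnification setup; configurable).
#' @param fibreAngle fibre orientation in degrees from the image x-axis.
#' @param fibreSpacing um between fibre centrelines (default 2).
#' @param fibreWidth um stripe width (default = \code{fibreSpacing}).
#' @param fibreLengthMean,fibreLengthSd um; mean sets the cell's long axis,
#'   sd jitters individual fibre lengths.
#' @param gapFraction target erased fraction of cell area, in [0, 1).
#' @param clumpCount number of bright Gaussian blob artefacts (default 0).
#' @param psfSigma um blur sigma (default 0.2).
#' @param noiseSd additive Gaussian noise sd in intensity units where fibre
#'   intensity is ~1 (default 0.02).
#' @param seed integer RNG seed; identical arguments and seed give an
#'   identical image and truth.
#' @return list with \code{image} (a \linkS4class{FluorescenceImage}) and
#'   \code{truth}: \code{fibreLengths} (um fragment lengths per fibre after
#'   gap erasure), \code{cellPolygon} (x, y pixel vertices, 0-based),
#'   \code{trueGapFraction}, \code{fibreMask} (post-erasure
#'   \linkS4class{BinaryMask}), \code{cellMask} (pre-erasure mask) and
#'   \code{cellAreaUm2}.
#' @export
generateMuscleImage <- function(imageShape = c(256, 256), pixelSize = 0.25,
                                fibreAngle = 30, fibreSpacing = 2,
                                fibreWidth = fibreSpacing,
                                fibreLengthMean = 40, fibreLengthSd = 4,
                                gapFraction = 0, clumpCount = 0,
                                psfSigma = 0.2, noiseSd = 0.02, seed = 1) {
  if (gapFraction < 0 || gapFraction >= 1)
    nmStop("nm_invalid_spec", "gapFraction must lie in [0, 1)")
  if (fibreLengthMean <= 0 || pixelSize <= 0 || fibreSpacing <= 0 ||
      fibreWidth <= 0 || any(imageShape < 32))
    nmStop("nm_invalid_spec", "non-positive geometry in muscle image spec")

  .withSeed(seed, {
    nr <- imageShape[1]; nc <- imageShape[2]
    th <- fibreAngle * pi / 180
    cx <- (nc - 1) / 2 * pixelSize
    cy <- (nr - 1) / 2 * pixelSize
    # fibre-aligned coordinates: u along the fibre axis, v across it (um)
    X <- matrix(rep((0:(nc - 1)) * pixelSize, each = nr), nr, nc)
    Y <- matrix(rep((0:(nr - 1)) * pixelSize, times = nc), nr, nc)
    U <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    V <- -(X - cx) * sin(th) + (Y - cy) * cos(th)

    # spindle geometry: chord length tapers quadratically toward the edges
    taper <- 0.35
    nFib <- max(3L, round(0.6 * fibreLengthMean / fibreSpacing))
    W <- nFib * fibreSpacing
    lMax <- fibreLengthMean / (1 - taper / 3)
    vCentres <- (seq_len(nFib) - (nFib + 1) / 2) * fibreSpacing
    chord <- lMax * (1 - taper * (2 * vCentres / W)^2)
    halfLen <- pmax(1, pmin(chord, stats::rnorm(nFib, chord, fibreLengthSd))) / 2

    # assign pixels to the nearest fibre band
    band <- round(V / fibreSpacing + (nFib + 1) / 2)
    inBand <- band >= 1 & band <= nFib
    dv <- abs(V - ifelse(inBand, (band - (nFib + 1) / 2) * fibreSpacing, Inf))
    preMask <- inBand & dv <= fibreWidth / 2 &
      abs(U) <= ifelse(inBand, halfLen[pmax(band, 1)], 0)
    cellPx <- sum(preMask)
    if (cellPx < 50)
      nmStop("nm_invalid_spec", "cell does not fit the image; enlarge imageShape")

    # erase rectangular lesions at random positions until the realized gap
    # fraction is within tolerance of the target (never overshooting by more
    # than 0.01); degeneration gaps in vivo are patches spanning one to a
    # few adjacent fibres, not sub-fibre notches
    erased <- matrix(FALSE, nr, nc)
    eraseIntervals <- rep(list(matrix(numeric(0), 0, 2)), nFib)
    if (gapFraction > 0) {
      realized <- 0
      # lesions stay interior to the cell: the imaged cells keep a traceable
      # outline (a requirement of the manual polygon protocol this emulates)
      jPool <- if (nFib >= 4L) 2:(nFib - 1L) else seq_len(nFib)
      for (it in 1:4000) {
        if (realized >= gapFraction - 0.004) break
        j <- jPool[sample.int(length(jPool), 1L)]
        v0 <- vCentres[j]
        hu <- stats::runif(1, 1.5, 4)
        hv <- stats::runif(1, 1.5, 3)
        hv <- max(min(hv, W / 2 - abs(v0) - fibreWidth / 2), fibreWidth / 2)
        uMax <- max(halfLen[j] - hu - 1, 0)
        u0 <- stats::runif(1, -uMax, uMax)
        for (shrink in 1:40) {
          seg <- preMask & abs(U - u0) <= hu & abs(V - v0) <= hv & !erased
          newRealized <- (sum(erased) + sum(seg)) / cellPx
          if (newRealized <= gapFraction + 0.009) break
          hu <- hu * 0.7
          hv <- max(hv * 0.85, fibreWidth / 2)
        }
        if (newRealized > gapFraction + 0.009) next
        erased <- erased | seg
        for (jj in which(abs(vCentres - v0) <= hv))
          eraseIntervals[[jj]] <- rbind(eraseIntervals[[jj]], c(u0 - hu, u0 + hu))
        realized <- newRealized
      }
    }
    trueGap <- sum(erased) / cellPx

    # per-fibre fragment lengths: complement of merged erase intervals
    fragLengths <- numeric(0)
    for (j in seq_len(nFib)) {
      lo <- -halfLen[j]; hi <- halfLen[j]
      iv <- eraseIntervals[[j]]
      if (nrow(iv)) {
        iv[, 1] <- pmax(iv[, 1], lo); iv[, 2] <- pmin(iv[, 2], hi)
        iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        merged <- matrix(numeric(0), 0, 2)
        for (k in seq_len(nrow(iv))) {
          if (nrow(merged) && iv[k, 1] <= merged[nrow(merged), 2]) {
            merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
          } else merged <- rbind(merged, iv[k, ])
        }
        # complement of the merged erase intervals within [lo, hi]
        starts <- c(lo, merged[, 2]); ends <- c(merged[, 1], hi)
        frags <- ends - starts
      } else frags <- hi - lo
      fragLengths <- c(fragLengths, frags[frags > 1e-9])
    }

    fibreMask <- preMask & !erased

    # intensity: unit fibre brightness with a mild cosine striation profile
    img <- matrix(0, nr, nc)
    img[fibreMask] <- 0.85 + 0.15 * cos(2 * pi * dv[fibreMask] / fibreSpacing)
    if (clumpCount > 0) {
      inside <- which(preMask)
      pick <- sample(inside, min(clumpCount, length(inside)))
      for (p in pick) {
        pr <- ((p - 1) %% nr) + 1; pc <- ((p - 1) %/% nr) + 1
        amp <- stats::runif(1, 3, 5)
        sig <- 1 / pixelSize
        rr <- pmax(1, pr - ceiling(3 * sig)):pmin(nr, pr + ceiling(3 * sig))
        cc <- pmax(1, pc - ceiling(3 * sig)):pmin(nc, pc + ceiling(3 * sig))
        d2 <- outer((rr - pr)^2, (cc - pc)^2, "+")
        img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sig^2))
      }
    }
    if (psfSigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = psfSigma / pixelSize))
    if (noiseSd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    img <- pmax(img, 0)

    # polygon tracing the fibre ends on both flanks (0-based x, y pixel coords)
    ex <- function(u, v) (cx + u * cos(th) - v * sin(th)) / pixelSize
    ey <- function(u, v) (cy + u * sin(th) + v * cos(th)) / pixelSize
    poly <- data.frame(
      x = c(ex(halfLen, vCentres), rev(ex(-halfLen, vCentres))),
      y = c(ey(halfLen, vCentres), rev(ey(-halfLen, vCentres))))

    list(image = FluorescenceImage(img, pixelSize),
         truth = list(fibreLengths = fragLengths,
                      cellPolygon = poly,
                      trueGapFraction = trueGap,
                      fibreMask = BinaryMask(fibreMask, pixelSize),
                      cellMask = BinaryMask(preMask, pixelSize),
                      cellAreaUm2 = cellPx * pixelSize^2))
  })
}

#' Generate a synthetic posture series and centroid track
#'
#' Bend angle is a sinusoid \code{amplitude * sin(2 pi f t)} plus white
#' Gaussian noise; the centroid advances at constant speed along a gently
#' curving path, flipping direction at each requested reversal time. The
#' truth records \code{floor(bendFrequency * duration)} completed bend
#' cycles (one thrash each) and the programmed speed.
#'
#' @param duration s. @param frameRate Hz.
#' @param bendAmplitude degrees. @param bendFrequency Hz (thrash cycles/s).
#' @param speed um/s. @param noiseSdAngle degrees of white angle noise.
#' @param reversalTimes seconds at which the heading reverses.
#' @param seed integer seed.
#' @return list with \code{posture} (\linkS4class{PostureSeries}),
#'   \code{track} (\linkS4class{CentroidTrack}) and \code{truth}
#'   (\code{thrashCount}, \code{thrashesPerMin}, \code{bendsPerMin},
#'   \code{speed}).
#' @export
generatePostureSeries <- function(duration = 60, frameRate = 30,
                                  bendAmplitude = 45, bendFrequency = 1,
                                  speed = 150, noiseSdAngle = 0,
                                  reversalTimes = numeric(), seed = 1) {
  if (duration <= 0 || frameRate <= 0)
    nmStop("nm_invalid_spec", "duration and frameRate must be positive")
  .withSeed(seed, {
    n <- round(duration * frameRate)
    t <- (0:(n - 1)) / frameRate
    ang <- bendAmplitude * sin(2 * pi * bendFrequency * t)
    if (noiseSdAngle > 0) ang <- ang + stats::rnorm(n, 0, noiseSdAngle)
    dirSign <- (-1)^findInterval(t, sort(reversalTimes))
    heading <- 0.3 * sin(2 * pi * 0.05 * t)
    dt <- 1 / frameRate
    vx <- speed * dirSign * cos(heading)
    vy <- speed * dirSign * sin(heading)
    x <- cumsum(c(0, vx[-n] * dt))
    y <- cumsum(c(0, vy[-n] * dt))
    list(posture = PostureSeries(t, ang),
         track = CentroidTrack(t, x, y),
         truth = list(thrashCount = floor(bendFrequency * duration),
                      thrashesPerMin = bendFrequency * 60,
                      bendsPerMin = 2 * bendFrequency * 60,
                      speed = speed))
  })
}

#' Simulate a population-activity beam-grid assay
#'
#' Worms perform seeded random crossings over a grid of infrared beams;
#' each crossing toggles the state of one beam. The truth is the total
#' number of toggles, the quantity an activity counter integrates.
#'
#' @param nWorms number of worms in the well (\code{>= 0}).
#' @param beams number of beams (\code{>= 1}).
#' @param duration s. @param motility expected crossings per worm per minute.
#' @param dt sampling interval of the beam state series, s (default 1).
#' @param seed integer seed.
#' @return list with \code{times}, \code{states} (time x beams logical
#'   matrix) and \code{truth} (\code{crossings}).
#' @export
generateActivityWells <- function(nWorms = 40, beams = 16, duration = 3600,
                                  motility = 2, dt = 1, seed = 1) {
  if (nWorms < 0 || beams < 1)
    nmStop("nm_invalid_spec", "nWorms must be >= 0 and beams >= 1")
  .withSeed(seed, {
    n <- round(duration / dt)
    times <- (0:(n - 1)) * dt
    states <- matrix(FALSE, n, beams)
    crossings <- 0L
    if (nWorms > 0 && motility > 0) {
      p <- min(1, motility / 60 * dt)
      cur <- rep(FALSE, beams)
      for (i in seq_len(n)) {
        # distinct beams within one sampling step, so every crossing is
        # visible as a state change in the sampled series
        k <- min(stats::rbinom(1, nWorms, p), beams)
        if (k > 0) {
          hit <- sample.int(beams, k)
          cur[hit] <- !cur[hit]
          crossings <- crossings + k
        }
        states[i, ] <- cur
      }
    }
    list(times = times, states = states, truth = list(crossings = crossings))
  })
}

#' Generate a synthetic voltage-clamp trace with spontaneous PSC events
#'
#' Events occur at Poisson times; each adds an inward (negative)
#' biexponential transient \code{exp(-t/decayTau) - exp(-t/riseTau)}
#' normalized so its peak equals \code{-amplitude}. Gaussian noise is added.
#' Truth times are the kernel peak times (where the trace minimum of an
#' isolated event falls), matching the detector's event-time semantics.
#'
#' @param duration s. @param sampleRate Hz.
#' @param eventRate Hz, Poisson rate of events.
#' @param ampMean,ampSd pA magnitude distribution (draws truncated at 0.5 pA).
#' @param riseTau,decayTau ms, with \code{decayTau > riseTau > 0}.
#' @param noiseSd pA. @param seed integer seed.
#' @return list with \code{trace} (\linkS4class{CurrentTrace}) and
#'   \code{truth} (\code{times} at event peaks, \code{amplitudes}).
#' @export
generatePscTrace <- function(duration = 60, sampleRate = 10000,
                             eventRate = 2, ampMean = 25, ampSd = 5,
                             riseTau = 0.8, decayTau = 6, noiseSd = 2,
                             seed = 1) {
  if (!(decayTau > riseTau && riseTau > 0))
    nmStop("nm_invalid_spec", "decayTau > riseTau > 0 is required")
  if (eventRate < 0) nmStop("nm_invalid_spec", "eventRate must be >= 0")
  .withSeed(seed, {
    n <- round(duration * sampleRate)
    x <- numeric(n)
    tr <- riseTau / 1000; td <- decayTau / 1000
    tPeak <- log(td / tr) * tr * td / (td - tr)
    kPeak <- exp(-tPeak / td) - exp(-tPeak / tr)
    kLen <- ceiling(8 * td * sampleRate)
    kt <- (0:kLen) / sampleRate
    kernel <- (exp(-kt / td) - exp(-kt / tr)) / kPeak

    nEv <- stats::rpois(1, eventRate * duration)
    onset <- sort(stats::runif(nEv, 0, max(duration - 10 * td, duration * 0.9)))
    amps <- pmax(0.5, stats::rnorm(nEv, ampMean, ampSd))
    for (i in seq_len(nEv)) {
      i0 <- floor(onset[i] * sampleRate) + 1L
      idx <- i0:min(n, i0 + kLen)
      x[idx] <- x[idx] - amps[i] * kernel[seq_along(idx)]
    }
    if (noiseSd > 0) x <- x + stats::rnorm(n, 0, noiseSd)
    peakTimes <- (floor(onset * sampleRate)) / sampleRate + tPeak
    list(trace = CurrentTrace(x, sampleRate),
         truth = list(times = peakTimes, amplitudes = amps))
  })
}

#' Generate a grouped measurement table of independent normal draws
#'
#' @param groups data.frame with columns \code{label}, \code{mean},
#'   \code{sd} (\code{>= 0}) and \code{n} (\code{>= 2}).
#' @param seed integer seed.
#' @return data.frame with columns \code{group} and \code{value}.
#' @export
generateGroupDataset <- function(groups, seed = 1) {
  groups <- as.data.frame(groups)
  if (any(groups$sd < 0) || any(groups$n < 2))
    nmStop("nm_invalid_spec", "group sd must be >= 0 and n >= 2")
  if (anyDuplicated(groups$label))
    nmStop("nm_invalid_spec", "duplicate group labels")
  .withSeed(seed, {
    do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      data.frame(group = rep(groups$label[i], groups$n[i]),
                 value = stats::rnorm(groups$n[i], groups$mean[i], groups$sd[i]),
                 stringsAsFactors = FALSE)
    }))
  })
}
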