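# Small geometric fixtures used across the skeleton and segmentation tests.

barMask <- function(nr = 10, nc = 50, rows = 4:6, cols = 6:45, pixelSize = 0.25) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  BinaryMask(m, pixelSize)
}

# horizontal 1-px path of n pixels
pathMask <- function(n = 11, pixelSize = 0.25) {
  m <- matrix(FALSE, 5, n + 4)
  m[3, 3:(n + 2)] <- TRUE
  BinaryMask(m, pixelSize)
}

# perfect diagonal of n pixels
diagMask <- function(n = 5, pixelSize = 0.25) {
  m <- matrix(FALSE, n + 4, n + 4)
  for (i in seq_len(n)) m[2 + i, 2 + i] <- TRUE
  BinaryMask(m, pixelSize)
}

# "T": three arms of `arm` pixels meeting at one junction pixel
tMask <- function(arm = 10, pixelSize = 0.25) {
  sz <- 2 * arm + 5
  m <- matrix(FALSE, sz, sz)
  cr <- arm + 3
  m[(cr - arm):cr, cr] <- TRUE          # north arm into centre
  m[cr:(cr + arm), cr] <- TRUE          # south arm
  m[cr, cr:(cr + arm)] <- TRUE          # east arm
  BinaryMask(m, pixelSize)
}

randomMask <- function(nr = 64, nc = 64, density = 0.3) {
  matrix(stats::runif(nr * nc) < density, nr, nc)
}

has2x2Block <- function(s) {
  any(s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] & s[-nrow(s), -1] & s[-1, -1])
}

ncomp8 <- function(m) nemamorph:::.ncomp8(m)

# sparse separated straight fibres with known ground-truth lengths
sparseFibreSim <- function(seed = 11) {
  generateMuscleImage(
    imageShape = c(288, 288), fibreSpacing = 5, fibreWidth = 1.2,
    fibreLengthMean = 55, fibreLengthSd = 25, gapFraction = 0,
    psfSigma = 0.15, noiseSd = 0, seed = seed)
}

uniformSeries <- function(duration, rate, angle) {
  PostureSeries((0:(round(duration * rate) - 1)) / rate, angle)
}
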