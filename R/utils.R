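#' @import methods
NULL

# Condition helper: all package errors carry a subclass so callers and tests
# can distinguish failure modes without matching message text.
nmStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators funnel randomness through this, making them pure functions
# of (spec, seed).
.withSeed <- function(seed, code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = ge)
    on.exit(assign(".Random.seed", old, envir = ge), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = ge)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc), padding with `fill`. Used by the vectorized
# thinning candidate pass and neighbour counting.
.shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Count of 8-connected foreground neighbours for every pixel.
.neighbourCount <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + .shiftMat(m, dr, dc)
  }
  s
}

# Even-odd (ray casting) point-in-polygon test, vectorized over query points.
# px/py: query coordinates; vx/vy: polygon vertices (closed implicitly).
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# 8-connected component labelling: a 4-connected pass (EBImage::bwlabel)
# followed by union of labels that touch diagonally. Connectivity is 8 for
# foreground everywhere in this package; bwlabel alone is 4-connected.
.label8 <- function(m) {
  lbl <- EBImage::bwlabel(m * 1)
  n <- max(lbl)
  if (n <= 1L) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  pairs <- rbind(
    cbind(as.vector(lbl[-nr, -nc]), as.vector(lbl[-1, -1])),   # down-right
    cbind(as.vector(lbl[-nr, -1]), as.vector(lbl[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lbl
  out[lbl > 0] <- dense[lbl[lbl > 0]]
  out
}

.ncomp8 <- function(m) max(.label8(m))

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.checkUniformTimes <- function(times, tol = 0.01) {
  dt <- diff(times)
  if (any(dt <= 0)) nmStop("nm_invalid_series", "time stamps must be strictly increasing")
  md <- stats::median(dt)
  if (any(abs(dt - md) > tol * md))
    nmStop("nm_invalid_series", "series is not uniformly sampled (frame interval varies by more than 1%)")
  md
}
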