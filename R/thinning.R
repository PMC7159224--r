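#' Skeletonize a binary mask
#'
#' Topology-preserving morphological thinning to a one-pixel-wide medial
#' skeleton. The main loop is the classical two-sub-iteration (Zhang-Suen)
#' parallel scheme; each parallel sweep is accepted only if it preserves the
#' 8-connected component count (a bare parallel sweep annihilates an
#' isolated 2x2 block outright), falling back to sequential simple-point
#' deletion otherwise. A final minimalization pass removes the redundant
#' staircase corner pixels the parallel scheme is known to leave, and a
#' last-resort pass resolves 2x2 blocks at dense crossings. The result is
#' deterministic and satisfies both skeleton invariants: no 2x2
#' all-foreground block, and exactly as many 8-connected components as the
#' source mask.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return a \linkS4class{Skeleton}; an empty mask yields an empty skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  Skeleton(.thin(mask@mask), mask@pixelSize)
}

# Neighbour order (clockwise from north): P2..P9 = N, NE, E, SE, S, SW, W, NW.
# In matrix terms row decreases northwards; offsets are (dr, dc).
.nbOffsets <- cbind(
  dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# Adjacency among the 8 ring positions (N, NE, E, SE, S, SW, W, NW):
# consecutive positions touch, and the four cardinal pairs also touch
# diagonally across an empty corner (N-E, E-S, S-W, W-N).
.ringAdj <- local({
  adj <- vector("list", 8)
  for (i in 1:8) adj[[i]] <- c(if (i == 1) 8 else i - 1, if (i == 8) 1 else i + 1)
  for (pr in list(c(1, 3), c(3, 5), c(5, 7), c(7, 1))) {
    adj[[pr[1]]] <- c(adj[[pr[1]]], pr[2])
    adj[[pr[2]]] <- c(adj[[pr[2]]], pr[1])
  }
  adj
})

# TRUE when deleting the pixel preserves topology: its foreground
# neighbours form a single 8-connected set (no split) and at least one
# cardinal neighbour is background, so the vacated cell joins an existing
# 4-connected background region instead of opening a hole.
.simple8 <- function(p) {
  if (all(p[c(1L, 3L, 5L, 7L)])) return(FALSE)
  idx <- which(p)
  if (length(idx) <= 1L) return(length(idx) == 1L)
  seen <- logical(8)
  stack <- idx[1]
  seen[idx[1]] <- TRUE
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    for (j in .ringAdj[[i]]) {
      if (p[j] && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
    }
  }
  all(seen[idx])
}

# Topology-safe deletability of pixel (r, c) in padded logical matrix m.
# sub = 1L or 2L selects the sub-iteration's directional conditions.
.deletable <- function(m, r, c, sub) {
  p <- logical(8)
  for (k in 1:8) p[k] <- m[r + .nbOffsets[k, 1L], c + .nbOffsets[k, 2L]]
  b <- sum(p)
  if (b < 2L || b > 6L) return(FALSE)
  if (!.simple8(p)) return(FALSE)
  if (sub == 1L) !(p[1] && p[3] && p[5]) && !(p[3] && p[5] && p[7])
  else           !(p[1] && p[3] && p[7]) && !(p[1] && p[5] && p[7])
}

.thin <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(FALSE, nr, nc))
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ncomp <- .ncomp8(m)

  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      cand <- .candidates(m, sub)
      if (!length(cand)) next
      # parallel deletion, the classical scheme: gives smooth diagonals
      m2 <- m
      m2[cand] <- FALSE
      if (.ncomp8(m2) == ncomp) {
        m <- m2
        changed <- TRUE
      } else {
        # the parallel sweep would merge away or split a component (e.g. an
        # isolated 2x2 block is annihilated outright); fall back to
        # sequential deletion with the conditions re-checked per pixel,
        # which removes only simple points and so preserves topology
        rr <- ((cand - 1L) %% nrow(m)) + 1L
        cc <- ((cand - 1L) %/% nrow(m)) + 1L
        for (i in seq_along(cand)) {
          if (.deletable(m, rr[i], cc[i], sub)) {
            m[rr[i], cc[i]] <- FALSE
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  m <- .minimalize(m)
  m <- .stubbornCleanup(m, ncomp)
  m[2:(nr + 1L), 2:(nc + 1L)]
}

# Reduce the thinned image to a minimal 8-connected skeleton: sequentially
# delete every non-endpoint pixel whose foreground neighbours remain
# connected without it. This removes the redundant corner pixels the
# parallel sweeps leave along staircases (their Rutovitz crossing number is
# 2, so they are never candidates) and any remaining 2x2 corners, while
# endpoints (one neighbour) and topology are untouched.
.minimalize <- function(m) {
  repeat {
    idx <- which(m)
    removed <- FALSE
    rr <- ((idx - 1L) %% nrow(m)) + 1L
    cc <- ((idx - 1L) %/% nrow(m)) + 1L
    for (i in seq_along(idx)) {
      r <- rr[i]; c <- cc[i]
      if (!m[r, c]) next
      p <- logical(8)
      for (k in 1:8) p[k] <- m[r + .nbOffsets[k, 1L], c + .nbOffsets[k, 2L]]
      if (sum(p) >= 2L && .simple8(p)) {
        m[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# Last resort for 2x2 blocks whose pixels all fail the local simple test
# (dense crossings where the arcs reconnect globally): tentatively delete a
# block pixel and keep the deletion when the global 8-connected component
# count is unchanged.
.stubbornCleanup <- function(m, ncomp) {
  repeat {
    blk <- m & .shiftMat(m, -1L, 0L) & .shiftMat(m, 0L, -1L) & .shiftMat(m, -1L, -1L)
    if (!any(blk)) break
    idx <- which(blk | .shiftMat(blk, 1L, 0L) | .shiftMat(blk, 0L, 1L) |
                   .shiftMat(blk, 1L, 1L))
    removed <- FALSE
    rr <- ((idx - 1L) %% nrow(m)) + 1L
    cc <- ((idx - 1L) %/% nrow(m)) + 1L
    for (i in seq_along(idx)) {
      r <- rr[i]; c <- cc[i]
      if (!m[r, c] || !.inSquare(m, r, c)) next
      m[r, c] <- FALSE
      if (.ncomp8(m) == ncomp) {
        removed <- TRUE
        m <- .squareCleanup(m)
        next
      }
      # deletion orphans an arm attached only to this corner: re-route the
      # arm through an adjacent background pixel that restores connectivity
      # without forming a new 2x2 block
      rerouted <- FALSE
      for (k in 1:8) {
        qr <- r + .nbOffsets[k, 1L]; qc <- c + .nbOffsets[k, 2L]
        if (qr < 2L || qc < 2L || qr > nrow(m) - 1L || qc > ncol(m) - 1L) next
        if (m[qr, qc]) next
        m[qr, qc] <- TRUE
        if (.ncomp8(m) == ncomp && !.inSquare(m, qr, qc)) {
          rerouted <- TRUE
          break
        }
        m[qr, qc] <- FALSE
      }
      if (rerouted) {
        removed <- TRUE
        m <- .squareCleanup(m)
      } else {
        m[r, c] <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# Vectorized parallel pass: linear indices of pixels satisfying the
# sub-iteration conditions (raster = column-major order, deterministic).
.candidates <- function(m, sub) {
  p <- lapply(1:8, function(k)
    .shiftMat(m, -.nbOffsets[k, 1L], -.nbOffsets[k, 2L]))
  b <- Reduce(`+`, p)
  a <- Reduce(`+`, lapply(1:8, function(k) {
    nxt <- if (k == 8L) 1L else k + 1L
    (!p[[k]]) & p[[nxt]]
  }))
  cond <- m & b >= 2L & b <= 6L & a == 1L
  cond <- cond & if (sub == 1L) {
    !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
  } else {
    !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
  }
  which(cond)
}

# Remove topology-safe pixels belonging to residual 2x2 blocks (staircase
# corners that survive the directional sweeps). A pixel is removed only
# when its foreground neighbours stay connected without it and it is not an
# endpoint, so connectivity and component count are untouched.
.squareCleanup <- function(m) {
  repeat {
    blk <- m & .shiftMat(m, -1L, 0L) & .shiftMat(m, 0L, -1L) & .shiftMat(m, -1L, -1L)
    if (!any(blk)) break
    idx <- which(blk | .shiftMat(blk, 1L, 0L) | .shiftMat(blk, 0L, 1L) |
                   .shiftMat(blk, 1L, 1L))
    removed <- FALSE
    rr <- ((idx - 1L) %% nrow(m)) + 1L
    cc <- ((idx - 1L) %/% nrow(m)) + 1L
    for (i in seq_along(idx)) {
      r <- rr[i]; c <- cc[i]
      if (!m[r, c]) next
      if (!.inSquare(m, r, c)) next
      p <- logical(8)
      for (k in 1:8) p[k] <- m[r + .nbOffsets[k, 1L], c + .nbOffsets[k, 2L]]
      if (sum(p) >= 2L && .simple8(p)) {
        m[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

.inSquare <- function(m, r, c) {
  for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
    if (m[r + dr, c + dc] && m[r + dr + 1L, c + dc] &&
        m[r + dr, c + dc + 1L] && m[r + dr + 1L, c + dc + 1L]) return(TRUE)
  }
  FALSE
}
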