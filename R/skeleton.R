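#' Build the node/branch graph of a skeleton
#'
#' Skeleton pixels are classified by their 8-neighbour count: endpoints
#' (one neighbour), junctions (three or more) and isolated pixels; pixels
#' with exactly two neighbours are path interior. Branches are the pixel
#' paths connecting two nodes; a closed loop with no node gets one
#' designated "loop" node carrying the whole cycle as a single branch.
#' Branch geometric length accumulates \code{pixelSize} per orthogonal step
#' and \code{pixelSize * sqrt(2)} per diagonal step, matching standard
#' skeleton-analysis branch semantics.
#'
#' @param skel a \linkS4class{Skeleton}.
#' @return a \linkS4class{SkeletonGraph}.
#' @export
buildSkeletonGraph <- function(skel) {
  stopifnot(is(skel, "Skeleton"))
  ps <- skel@pixelSize
  nr0 <- nrow(skel@pixels); nc0 <- ncol(skel@pixels)
  m <- matrix(FALSE, nr0 + 2L, nc0 + 2L)
  m[2:(nr0 + 1L), 2:(nc0 + 1L)] <- skel@pixels
  nr <- nrow(m)

  emptyNodes <- data.frame(id = integer(), row = integer(), col = integer(),
                           type = character(), stringsAsFactors = FALSE)
  emptyBranches <- data.frame(branch_id = integer(), from = integer(),
                              to = integer(), n_pixels = integer(),
                              length_um = numeric(), stringsAsFactors = FALSE)
  if (!any(m))
    return(new("SkeletonGraph", nodes = emptyNodes, branches = emptyBranches,
               paths = list(), pixelSize = ps))

  # linear-index offsets of the 8 neighbours in the padded matrix
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  fg <- which(m)
  nbc <- integer(length(m))
  for (o in offs) nbc[fg] <- nbc[fg] + m[fg + o]

  isNode <- logical(length(m))
  isNode[fg] <- nbc[fg] != 2L
  nodeType <- character(0)
  nodeIdx <- fg[nbc[fg] != 2L]
  nodeType <- ifelse(nbc[nodeIdx] == 0L, "isolated",
                     ifelse(nbc[nodeIdx] == 1L, "endpoint", "junction"))

  # components that are pure cycles (no node pixel) get a designated node
  if (length(nodeIdx) == 0L || any(!isNode[fg])) {
    lbl <- .label8(m)
    nodeComp <- unique(lbl[nodeIdx])
    allComp <- unique(lbl[fg])
    for (comp in setdiff(allComp, nodeComp)) {
      pick <- min(which(lbl == comp))
      nodeIdx <- c(nodeIdx, pick)
      nodeType <- c(nodeType, "loop")
      isNode[pick] <- TRUE
    }
  }
  ord <- order(nodeIdx)
  nodeIdx <- nodeIdx[ord]; nodeType <- nodeType[ord]
  nodeId <- integer(length(m))
  nodeId[nodeIdx] <- seq_along(nodeIdx)

  stepKey <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  paths <- list(); from <- integer(); to <- integer(); lens <- numeric()
  npix <- integer()

  stepLen <- function(a, b) {
    d <- abs(a - b)
    if (d == 1L || d == nr) ps else ps * sqrt(2)
  }

  for (v in nodeIdx) {
    for (o in offs) {
      w <- v + o
      if (!m[w]) next
      k <- stepKey(v, w)
      if (!is.null(seen[[k]])) next
      seen[[k]] <- TRUE
      path <- c(v, w)
      len <- stepLen(v, w)
      prev <- v; cur <- w
      while (!isNode[cur]) {
        nxt <- NA_integer_
        for (o2 in offs) {
          cnd <- cur + o2
          if (m[cnd] && cnd != prev) { nxt <- cnd; break }
        }
        if (is.na(nxt)) break
        seen[[stepKey(cur, nxt)]] <- TRUE
        len <- len + stepLen(cur, nxt)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
      from <- c(from, nodeId[v]); to <- c(to, nodeId[cur])
      lens <- c(lens, len); npix <- c(npix, length(path))
    }
  }

  rows <- ((nodeIdx - 1L) %% nr) + 1L - 1L   # back to unpadded 1-based coords
  cols <- ((nodeIdx - 1L) %/% nr) + 1L - 1L
  nodes <- data.frame(id = seq_along(nodeIdx), row = rows, col = cols,
                      type = nodeType, stringsAsFactors = FALSE)
  branches <- if (length(paths)) {
    data.frame(branch_id = seq_along(paths), from = from, to = to,
               n_pixels = npix, length_um = lens, stringsAsFactors = FALSE)
  } else emptyBranches
  pathMats <- lapply(paths, function(p) {
    cbind(row = ((p - 1L) %% nr) + 1L - 1L, col = ((p - 1L) %/% nr) + 1L - 1L)
  })
  new("SkeletonGraph", nodes = nodes, branches = branches,
      paths = pathMats, pixelSize = ps)
}

#' Filter fibre lengths to the physiologically plausible range
#'
#' Keeps lengths in (0, 250] um. Zero-length records are excluded as not
#' physiologically possible, and records of more than 250 um exceed the
#' maximum reasonable length for a single myosin filament; 250 um exactly is
#' kept.
#'
#' @param lengths numeric vector of branch lengths in um (all \code{>= 0}).
#' @return list with \code{kept} (the retained lengths, order preserved),
#'   \code{nExcludedLow} and \code{nExcludedHigh}.
#' @export
filterFibreLengths <- function(lengths) {
  if (any(lengths < 0))
    nmStop("nm_invalid_input", "fibre lengths must be non-negative")
  keep <- lengths > 0 & lengths <= 250
  list(kept = lengths[keep],
       nExcludedLow = sum(lengths == 0),
       nExcludedHigh = sum(lengths > 250))
}

#' Gap-to-total-cell-area ratio
#'
#' Gap pixels are cell-region pixels not covered by fibre foreground,
#' retained as 8-connected gap components of at least \code{minGapArea};
#' the ratio is retained gap pixels over cell-region pixels. The component
#' floor suppresses sub-resolution inter-striation slivers that a manually
#' traced gap polygon would not include.
#'
#' @param cell a \linkS4class{CellROI}.
#' @param fibreMask a \linkS4class{BinaryMask} of the same shape.
#' @param minGapArea smallest gap component retained, in um^2 (default 5).
#' @return the ratio, a number in [0, 1].
#' @export
gapAreaRatio <- function(cell, fibreMask, minGapArea = 5) {
  stopifnot(is(cell, "CellROI"), is(fibreMask, "BinaryMask"))
  if (!identical(dim(cell@region), dim(fibreMask@mask)))
    nmStop("nm_invalid_input", "cell region and fibre mask shapes differ")
  region <- cell@region
  if (!any(region)) nmStop("nm_empty_region", "cell region is empty")
  gap <- region & !fibreMask@mask
  gap <- .removeSmall(gap, minPx = minGapArea / cell@pixelSize^2)
  sum(gap) / sum(region)
}

#' Run the full muscle-morphometry pipeline on one image
#'
#' Segments fibres, obtains the cell region (an explicit ROI overrides the
#' automatic estimate), skeletonizes, measures branch lengths, applies the
#' (0, 250] um filter and computes the gap-to-cell-area ratio.
#'
#' @param image a \linkS4class{FluorescenceImage}.
#' @param cell optional \linkS4class{CellROI}; when NULL it is estimated by
#'   \code{\link{estimateCellRegion}}.
#' @param smoothSigma,minObjectArea passed to \code{\link{segmentFibres}}.
#' @param closingRadius passed to \code{\link{estimateCellRegion}}.
#' @param minGapArea passed to \code{\link{gapAreaRatio}}.
#' @return a \linkS4class{MuscleMorphometry}.
#' @export
summarizeMorphometry <- function(image, cell = NULL, smoothSigma = 0.5,
                                 minObjectArea = 1, closingRadius = 4,
                                 minGapArea = 5) {
  mask <- segmentFibres(image, smoothSigma = smoothSigma,
                        minObjectArea = minObjectArea)
  roi <- if (is.null(cell)) estimateCellRegion(mask, closingRadius) else cell
  graph <- buildSkeletonGraph(skeletonize(mask))
  filt <- filterFibreLengths(graph@branches$length_um)
  gr <- gapAreaRatio(roi, mask, minGapArea = minGapArea)
  new("MuscleMorphometry",
      fibreLengths = filt$kept,
      meanLength = if (length(filt$kept)) mean(filt$kept) else NA_real_,
      gapRatio = gr,
      nExcludedLow = as.integer(filt$nExcludedLow),
      nExcludedHigh = as.integer(filt$nExcludedHigh))
}
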