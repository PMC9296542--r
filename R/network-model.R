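#' Proper crossing of two straight segments
#'
#' Exact geometric primitive shared by the observer and the occupancy
#' optimizer: two open segments properly cross when they intersect in a
#' single interior point.  Endpoint contacts (branching points are shared
#' vertices, not crossings) and parallel disjoint segments return `NULL`;
#' collinear overlapping segments are a degenerate input and raise an error.
#'
#' @param aStart,aEnd,bStart,bEnd Numeric length-2 points (mm).
#' @return `NULL` when the segments do not properly cross, otherwise a list
#'   with `point` (the crossing, mm) and `angle` (the acute crossing angle,
#'   degrees in (0, 90]).
#' @examples
#' segmentIntersection(c(0, 0), c(2, 0), c(1, -1), c(1, 1))  # (1,0), 90 deg
#' segmentIntersection(c(0, 0), c(1, 0), c(0, 1), c(1, 1))   # NULL
#' @export
segmentIntersection <- function(aStart, aEnd, bStart, bEnd) {
  pts <- c(aStart, aEnd, bStart, bEnd)
  stopifnot(length(pts) == 8L, all(is.finite(pts)))
  r <- aEnd - aStart; s <- bEnd - bStart
  la <- sqrt(sum(r^2)); lb <- sqrt(sum(s^2))
  if (la == 0 || lb == 0) stop("segments must have positive length")
  denom <- r[1] * s[2] - r[2] * s[1]
  qp <- bStart - aStart
  if (abs(denom) <= 1e-12 * la * lb) {
    # parallel; collinear overlap is degenerate
    cr <- qp[1] * r[2] - qp[2] * r[1]
    if (abs(cr) <= 1e-12 * la * sqrt(sum(qp^2)) || all(qp == 0)) {
      t0 <- sum(qp * r) / (la^2)
      t1 <- t0 + sum(s * r) / (la^2)
      if (max(min(t0, t1), 0) < min(max(t0, t1), 1))
        stop("degenerate overlap: collinear overlapping segments")
    }
    return(NULL)
  }
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  if (t <= 0 || t >= 1) return(NULL)
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (u <= 0 || u >= 1) return(NULL)
  ang <- atan2(abs(denom), abs(sum(r * s))) / pi * 180
  list(point = aStart + t * r, angle = ang)
}

#' Summary counts of a thallus
#'
#' Counts by vertex kind, segment and drawn-branch counts, total and mean
#' lengths, and the lateral branch fraction.  For a pure binary tree
#' (lateral branching off) the closed forms hold: `nV1 = nGerm * 2^(g-2)`
#' apexes and `3 * (2^(g-1) - 1)` segments for three germination branches.
#' Two 3-degree tallies are reported: `nV3` counts apical branching events
#' and `nDegree3WithGerm` additionally counts lateral branch points and the
#' germination vertex itself (for three germination branches at g = 9,
#' lateral branching off, these are 381 and 382; counting conventions for
#' the germination vertex differ between reports, so both tallies are
#' given).
#'
#' @param thallus A [Thallus-class] object.
#' @return A list with components `nV1`, `nV3`, `nV1l`, `nV3l`, `nSegments`,
#'   `nBranches` (drawn branches, splits not double counted),
#'   `nLateralBranches`, `totalLength`, `meanSegmentLength`,
#'   `meanBranchLength`, `pLateral` (lateral-origin drawn branches per
#'   apical-origin drawn branch), `nDegree3WithGerm` and `generation`.
#' @export
summarizeThallus <- function(thallus) {
  stopifnot(is(thallus, "Thallus"))
  v <- thallus@vertices; s <- thallus@segments
  kinds <- table(factor(v$kind, levels = .vertex_kinds))
  L <- sum(s$length)
  nBranch <- length(unique(s$branchId))
  latIds <- unique(s$branchId[s$type == "lateral"])
  nLat <- length(latIds)
  list(nV1 = as.integer(kinds[["V1"]]),
       nV3 = as.integer(kinds[["V3"]]),
       nV1l = as.integer(kinds[["V1l"]]),
       nV3l = as.integer(kinds[["V3l"]]),
       nSegments = nrow(s),
       nBranches = nBranch,
       nLateralBranches = nLat,
       totalLength = L,
       meanSegmentLength = if (nrow(s)) L / nrow(s) else 0,
       meanBranchLength = if (nBranch) L / nBranch else 0,
       pLateral = if (nBranch > nLat) nLat / (nBranch - nLat) else NA_real_,
       nDegree3WithGerm = as.integer(kinds[["V3"]] + kinds[["V3l"]] + 1L),
       generation = thallus@generation)
}

#' Geometric branch crossings of a thallus
#'
#' Detects every pair of non-adjacent segments that properly cross in the
#' 2D embedding.  These crossings are purely geometric: the tree has no
#' cycles, but the planar projection superposes branches, and an imaging
#' chain reports such superpositions as apparent 3-degree vertices (V3i).
#'
#' @param thallus A [Thallus-class] object (or any object with a `segments`
#'   slot carrying `x0, y0, x1, y1, tail, head`).
#' @return data.frame with one row per crossing: `segA`, `segB` (row indices
#'   into the segment table), `x`, `y` (crossing point, mm), `angle` (acute
#'   crossing angle, degrees).
#' @export
detectGeometricVertices <- function(thallus) {
  s <- thallus@segments
  .cross_segments(s$x0, s$y0, s$x1, s$y1,
                  as.integer(s$tail), as.integer(s$head))
}

#' @describeIn summarizeThallus `summary` method for `Thallus`.
#' @param object,... For the `summary` method.
#' @export
setMethod("summary", "Thallus", function(object, ...) summarizeThallus(object))

#' Plot a thallus
#'
#' Draws the network with segments coloured by branch type and apex/branch
#' vertices marked.
#'
#' @param x A [Thallus-class] object.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics segments points legend
#' @export
setMethod("plot", signature(x = "Thallus", y = "missing"),
  function(x, y, ...) {
    s <- x@segments; v <- x@vertices
    cols <- c(germinal = "black", exploratory = "steelblue",
              operating = "darkorange", lateral = "forestgreen")
    plot(NA, xlim = range(c(s$x0, s$x1)), ylim = range(c(s$y0, s$y1)),
         asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
    segments(s$x0, s$y0, s$x1, s$y1, col = cols[s$type])
    ap <- v$kind %in% c("V1", "V1l")
    points(v$x[ap], v$y[ap], pch = 16, cex = 0.4,
           col = ifelse(v$kind[ap] == "V1", "blue", "grey40"))
    invisible(x)
  })
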