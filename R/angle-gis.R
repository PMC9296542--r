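#' Rasterize a thallus as a binary ribbon mask
#'
#' Draws every segment as a constant-width ribbon on a binary pixel grid,
#' bridging the vector simulator to the raster measurement pipeline.
#' Pixels are foreground when their center lies within half a ribbon width
#' of any segment.  Columns map to x and rows to y (row 1 at the bottom of
#' the coordinate frame).
#'
#' @param thallus A [Thallus-class] object with at least one segment.
#' @param pixelSize Pixel edge in mm (default: one fifth of the hyphal
#'   width, giving 5-px ribbons; thin ribbons keep the thinned junction
#'   triple points close to the true branching points).
#' @param widthPx Ribbon width in pixels (>= 1).
#' @param pad Padding margin in pixels around the bounding box.
#' @param maxPixels Error out above this canvas size.
#' @return An object of class `rasterMask`: list with `mask` (logical
#'   matrix), `pixelSize`, `origin` (mm coordinates of the lower-left
#'   pixel corner), `widthPx`, `provenance`.
#' @export
rasterizeThallus <- function(thallus,
                             pixelSize = thallus@parameters@hyphalWidth / 5,
                             widthPx = 5, pad = widthPx + 5,
                             maxPixels = 4e7) {
  stopifnot(pixelSize > 0, widthPx >= 1)
  s <- thallus@segments
  if (!nrow(s)) stop("empty thallus: nothing to rasterize")
  halfw <- widthPx * pixelSize / 2
  xmin <- min(s$x0, s$x1) - pad * pixelSize
  ymin <- min(s$y0, s$y1) - pad * pixelSize
  nc <- ceiling((max(s$x0, s$x1) + pad * pixelSize - xmin) / pixelSize)
  nr <- ceiling((max(s$y0, s$y1) + pad * pixelSize - ymin) / pixelSize)
  if (as.double(nr) * nc > maxPixels)
    stop("canvas of ", nr, " x ", nc, " pixels exceeds maxPixels")
  mask <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(s))) {
    c0 <- floor((min(s$x0[k], s$x1[k]) - halfw - xmin) / pixelSize) + 1L
    c1 <- ceiling((max(s$x0[k], s$x1[k]) + halfw - xmin) / pixelSize)
    r0 <- floor((min(s$y0[k], s$y1[k]) - halfw - ymin) / pixelSize) + 1L
    r1 <- ceiling((max(s$y0[k], s$y1[k]) + halfw - ymin) / pixelSize)
    c0 <- max(1L, c0); r0 <- max(1L, r0)
    c1 <- min(nc, c1); r1 <- min(nr, r1)
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    px <- xmin + (cols - 0.5) * pixelSize
    py <- ymin + (rows - 0.5) * pixelSize
    gx <- rep(px, each = length(py))
    gy <- rep(py, times = length(px))
    d <- .point_segment_dist(gx, gy, s$x0[k], s$y0[k], s$x1[k], s$y1[k])
    hit <- d <= halfw
    if (any(hit)) {
      rr <- rep(rows, times = length(cols))[hit]
      cc <- rep(cols, each = length(rows))[hit]
      mask[cbind(rr, cc)] <- TRUE
    }
  }
  structure(list(mask = mask, pixelSize = pixelSize,
                 origin = c(xmin, ymin), widthPx = widthPx,
                 provenance = sprintf("thallus g=%g", thallus@generation)),
            class = "rasterMask")
}

#' @export
print.rasterMask <- function(x, ...) {
  cat(sprintf("rasterMask %d x %d px (%.4g mm/px), %d foreground px [%s]\n",
              nrow(x$mask), ncol(x$mask), x$pixelSize, sum(x$mask),
              x$provenance))
  invisible(x)
}

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen morphological thinning to a 1-px centerline
.thin_zs <- function(img) {
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row+1 = north here;
  # only the cyclic order matters)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) .shift_mat(img, -o[1], -o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(img), ncol(img))
      for (k in 1:8) {
        nxt <- if (k == 8) 1 else k + 1
        A <- A + (!P[[k]] & P[[nxt]])
      }
      if (step == 1) {
        c1 <- !(P[[1]] & P[[3]] & P[[5]])
        c2 <- !(P[[3]] & P[[5]] & P[[7]])
      } else {
        c1 <- !(P[[1]] & P[[3]] & P[[7]])
        c2 <- !(P[[1]] & P[[5]] & P[[7]])
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

.neighbor_count <- function(img) {
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  Reduce(`+`, lapply(offs, function(o) .shift_mat(img, o[1], o[2])))
}

# Rutovitz crossing number: 0->1 transitions around the 8-neighbourhood;
# 1 at line ends, 2 along a line, >= 3 at branch points
.crossing_number <- function(img) {
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  P <- lapply(offs, function(o) .shift_mat(img, -o[1], -o[2]))
  A <- matrix(0L, nrow(img), ncol(img))
  for (k in 1:8) {
    nxt <- if (k == 8) 1 else k + 1
    A <- A + (!P[[k]] & P[[nxt]])
  }
  A
}

# Lookup table of "simple" 8-neighbourhoods: the foreground neighbours of
# a pixel form a single 8-connected component, so removing the pixel
# cannot disconnect them.  Ring order N, NE, E, SE, S, SW, W, NW; two ring
# cells are adjacent when the underlying pixels are 8-adjacent.
.simple_lut <- local({
  offs <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
                c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  adj <- matrix(FALSE, 8, 8)
  for (i in 1:8) for (j in 1:8)
    adj[i, j] <- i != j && all(abs(offs[i, ] - offs[j, ]) <= 1)
  lut <- logical(256)
  for (pat in 0:255) {
    on <- which(bitwAnd(pat, 2^(0:7)) > 0)
    if (!length(on)) { lut[pat + 1] <- FALSE; next }
    seen <- on[1]
    repeat {
      grow <- unique(c(seen, on[vapply(on, function(j)
        any(adj[j, seen]), logical(1))]))
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    lut[pat + 1] <- length(seen) == length(on)
  }
  lut
})

# remove the 2-px staircase redundancy thinning leaves on diagonals: a
# pixel whose foreground neighbours stay mutually connected without it is
# redundant unless it supports a line end; deletions are restricted to one
# (row, col) parity phase at a time so no two adjacent pixels disappear
# together (connectivity-safe)
.staircase_pass <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  rowPar <- matrix(seq_len(nr) %% 2L, nr, nc)
  colPar <- matrix(rep(seq_len(nc) %% 2L, each = nr), nr, nc)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  repeat {
    changed <- FALSE
    for (pr in 0:1) for (pc in 0:1) {
      P <- lapply(offs, function(o) .shift_mat(img, -o[1], -o[2]))
      B <- Reduce(`+`, P)
      pat <- matrix(0L, nr, nc)
      for (k in 1:8) pat <- pat + P[[k]] * 2L^(k - 1L)
      simple <- matrix(.simple_lut[pat + 1L], nr, nc)
      ends <- img & B == 1
      nearEnd <- .neighbor_count(ends) > 0
      del <- img & B >= 2 & B <= 6 & simple & !nearEnd &
        rowPar == pr & colPar == pc
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# remove endpoint-to-junction paths shorter than maxLen
.prune_spurs <- function(img, maxLen) {
  repeat {
    nb <- .neighbor_count(img)
    ends <- which(img & nb == 1, arr.ind = TRUE)
    if (!nrow(ends)) break
    removed <- FALSE
    for (k in seq_len(nrow(ends))) {
      path <- matrix(ends[k, ], 1)
      cur <- ends[k, ]
      prev <- c(NA, NA)
      spur <- FALSE
      for (step in seq_len(maxLen)) {
        win <- expand.grid(r = cur[1] + (-1:1), c = cur[2] + (-1:1))
        win <- win[win$r >= 1 & win$r <= nrow(img) &
                     win$c >= 1 & win$c <= ncol(img), ]
        win <- win[!(win$r == cur[1] & win$c == cur[2]), ]
        win <- win[img[cbind(win$r, win$c)], ]
        win <- win[!(win$r == prev[1] & win$c == prev[2]) | is.na(prev[1]), ]
        if (nrow(win) == 0) break            # isolated short segment: keep
        if (nrow(win) > 1) { spur <- TRUE; break }  # reached a junction
        if (nb[win$r[1], win$c[1]] >= 3) { spur <- TRUE; break }
        prev <- cur
        cur <- c(win$r[1], win$c[1])
        path <- rbind(path, cur)
      }
      if (spur) {
        img[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  img
}

#' Skeletonize a binary ribbon mask
#'
#' Extracts a one-pixel-wide, topology-preserving centerline by
#' morphological thinning, then applies two pruning rules: centerline
#' pixels within `trimErosionPx` of the mask boundary are removed
#' (suppressing junction artifacts that shoot toward the ribbon corners;
#' this slightly shortens the apex tips), and remaining short spurs --
#' endpoint paths not connected at both ends to the trunk -- are removed
#' iteratively.  Masks thinner than 2 px everywhere are already
#' centerlines and are returned as-is with a warning.
#'
#' @param mask A `rasterMask` or logical matrix.
#' @param trimErosionPx Boundary trim width in pixels.
#' @param prunePx Maximum spur length removed (default
#'   `2 * trimErosionPx + 1`).
#' @return A `rasterMask` whose `mask` is the skeleton.
#' @export
skeletonizeMask <- function(mask, trimErosionPx = 3, prunePx = NULL) {
  obj <- if (inherits(mask, "rasterMask")) mask
         else structure(list(mask = mask, pixelSize = 1, origin = c(0, 0),
                             widthPx = NA, provenance = "matrix"),
                        class = "rasterMask")
  m <- obj$mask
  if (!any(m)) stop("empty mask")
  if (is.null(prunePx)) prunePx <- 2L * trimErosionPx + 1L
  dm <- EBImage::distmap(.pad_bg(m))
  dm <- dm[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  if (max(dm) < 2) {
    warning("mask is thinner than 2 px everywhere; returned as-is")
    obj$provenance <- paste("skeleton of", obj$provenance)
    return(obj)
  }
  sk <- .thin_zs(m)
  sk <- .staircase_pass(sk)
  sk <- .prune_spurs(sk, prunePx)
  sk <- .trim_tips(sk, dm, trimErosionPx)
  obj$mask <- sk
  obj$provenance <- paste("skeleton of", obj$provenance)
  obj
}

# walk inward from every endpoint removing centerline pixels that lie in
# the boundary-erosion zone (tip caps); never crosses a junction, so the
# trunk stays connected
.trim_tips <- function(img, dm, trimPx) {
  if (trimPx <= 0) return(img)
  maxSteps <- 2L * trimPx + 2L
  repeat {
    nb <- .neighbor_count(img)
    ends <- which(img & nb == 1 & dm <= trimPx, arr.ind = TRUE)
    if (!nrow(ends)) break
    for (k in seq_len(nrow(ends))) {
      cur <- ends[k, ]
      for (step in seq_len(maxSteps)) {
        if (!img[cur[1], cur[2]] || dm[cur[1], cur[2]] > trimPx) break
        win <- expand.grid(r = cur[1] + (-1:1), c = cur[2] + (-1:1))
        win <- win[win$r >= 1 & win$r <= nrow(img) &
                     win$c >= 1 & win$c <= ncol(img), ]
        win <- win[!(win$r == cur[1] & win$c == cur[2]), ]
        win <- win[img[cbind(win$r, win$c)], ]
        if (nrow(win) != 1) break            # junction or isolated pixel
        img[cur[1], cur[2]] <- FALSE
        cur <- c(win$r[1], win$c[1])
      }
    }
    break
  }
  img
}

.pad_bg <- function(m) {
  out <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  out
}

.label_components4 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  nr <- nrow(m)
  for (i in which(m)) {
    if (lab[i]) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + o[1]; c2 <- cc + o[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(m)) next
        j <- (c2 - 1L) * nr + r2
        if (m[j] && !lab[j]) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

.label_components <- function(m) {
  # 8-connected component labelling by flood fill
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  idx <- which(m)
  for (i in idx) {
    if (lab[i]) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    nr <- nrow(m)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(m)) next
        j <- (c2 - 1L) * nr + r2
        if (m[j] && !lab[j]) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Detect skeleton vertices
#'
#' Labels skeleton pixels by their 8-neighbour count: endpoints (one
#' neighbour) are observed apexes V1ob; branch pixels (three or more
#' neighbours) are clustered within a 2-px radius and dissolved to a
#' single observed 3-degree vertex V3ob each.  Clusters from which more
#' than three arms leave (e.g. an X-crossing reconstructed as one blob)
#' are flagged with their arm degree.
#'
#' @param skeleton A `rasterMask` holding a 1-px skeleton.
#' @return data.frame with columns `id`, `kind` (V1ob/V3ob), `row`, `col`
#'   (pixel coordinates, possibly fractional for dissolved clusters), `x`,
#'   `y` (mm), `degree`, `flag`.
#' @export
detectSkeletonVertices <- function(skeleton) {
  stopifnot(inherits(skeleton, "rasterMask"))
  sk <- skeleton$mask
  nb <- .neighbor_count(sk)
  endIdx <- which(sk & nb == 1, arr.ind = TRUE)
  # after staircase cleanup the centerline is minimal, so three or more
  # neighbours reliably marks a branch pixel (including 2x2 crossing cores)
  branch <- sk & nb >= 3
  # dissolve branch pixels within 2 px: label the once-dilated branch mask
  dil <- branch
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    dil <- dil | .shift_mat(branch, o[1], o[2])
  lab <- .label_components(dil)
  lab[!branch] <- 0L
  rows <- list()
  nid <- 0L
  if (nrow(endIdx))
    for (k in seq_len(nrow(endIdx))) {
      nid <- nid + 1L
      rows[[nid]] <- data.frame(id = nid, kind = "V1ob",
                                row = endIdx[k, 1], col = endIdx[k, 2],
                                degree = 1L, flag = "ok",
                                stringsAsFactors = FALSE)
    }
  for (l in setdiff(unique(as.vector(lab)), 0L)) {
    px <- which(lab == l, arr.ind = TRUE)
    ctr <- colMeans(px)
    # arms: skeleton components in a thin annulus around the cluster
    rad <- 5
    r0 <- max(1, floor(ctr[1] - rad)); r1 <- min(nrow(sk), ceiling(ctr[1] + rad))
    c0 <- max(1, floor(ctr[2] - rad)); c1 <- min(ncol(sk), ceiling(ctr[2] + rad))
    win <- sk[r0:r1, c0:c1, drop = FALSE]
    wr <- rep(r0:r1, times = c1 - c0 + 1)
    wc <- rep(c0:c1, each = r1 - r0 + 1)
    d <- sqrt((wr - ctr[1])^2 + (wc - ctr[2])^2)
    win[d <= 2.2 | d > rad] <- FALSE
    deg <- max(as.vector(.label_components(win)), 0L)
    nid <- nid + 1L
    rows[[nid]] <- data.frame(id = nid, kind = "V3ob",
                              row = ctr[1], col = ctr[2],
                              degree = deg,
                              flag = if (deg > 3) "multi-arm" else "ok",
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(), kind = character(), row = numeric(),
                      col = numeric(), degree = integer(),
                      flag = character(), stringsAsFactors = FALSE)
  out$x <- skeleton$origin[1] + (out$col - 0.5) * skeleton$pixelSize
  out$y <- skeleton$origin[2] + (out$row - 0.5) * skeleton$pixelSize
  out
}

#' Buffer angle spectrum of a skeleton
#'
#' Centers a disc (buffer) of radius `bufferRadiusPx` on every detected
#' vertex and converts the partition of the disc by the skeleton into arc
#' angles.  Two estimators are available.  `"arms"` (default) fits a
#' total-least-squares line to each skeleton arm inside the disc,
#' re-estimates the branching point as the least-squares intersection of
#' the arm lines (morphological thinning displaces the triple point of a
#' junction towards the narrowest inter-arm wedge by about half a ribbon
#' width, which biases raw sector areas), and measures the arcs between
#' consecutive arm directions around the corrected center.  `"area"`
#' converts each sector's pixel-area fraction directly to its angular
#' counterpart (an arc is `360 * area / discArea` degrees).
#'
#' A clean apex buffer contains a single arm and contributes one
#' 360-degree sample; a clean 3-degree vertex contributes three arcs
#' summing to 360 degrees.  Vertices closer than `minSeparationPx` to
#' another vertex produce artifact arcs; their samples are retained but
#' flagged (together with multi-arm crossing blobs, these flags let
#' downstream fits exclude geometric-intersection contamination).
#' Vertices closer than the buffer radius to the image border are skipped.
#'
#' @param skeleton A `rasterMask` holding a skeleton.
#' @param vertices Output of [detectSkeletonVertices()].
#' @param bufferRadiusPx Disc radius (px).
#' @param minSeparationPx Flagging distance between vertices (px).
#' @param innerRadiusPx Pixels closer than this to the center are excluded
#'   from the `"area"` estimator (junction geometry is distorted there).
#' @param method Arc estimator (see Details).
#' @return Object of class `angleSpectrum`: list with `angles` (data.frame
#'   `angle`, `vertexId`, `kind`, `flag`), `bufferRadiusPx`,
#'   `minSeparationPx`, `skipped` (vertex ids too close to the border).
#' @export
bufferSpectrum <- function(skeleton, vertices, bufferRadiusPx = 5,
                           minSeparationPx = 10, innerRadiusPx = 0,
                           method = c("arms", "area")) {
  stopifnot(bufferRadiusPx > 0, minSeparationPx > 0,
            innerRadiusPx < bufferRadiusPx)
  method <- match.arg(method)
  sk <- skeleton$mask
  r <- bufferRadiusPx
  near <- rep(FALSE, nrow(vertices))
  if (nrow(vertices) > 1) {
    dmat <- as.matrix(dist(vertices[, c("row", "col")]))
    diag(dmat) <- Inf
    near <- apply(dmat, 1, min) < minSeparationPx
  }
  rowsOut <- list()
  skipped <- integer()
  for (k in seq_len(nrow(vertices))) {
    r0 <- vertices$row[k]; c0 <- vertices$col[k]
    if (r0 - r < 1 || r0 + r > nrow(sk) || c0 - r < 1 || c0 + r > ncol(sk)) {
      skipped <- c(skipped, vertices$id[k])
      next
    }
    rr <- floor(r0 - r):ceiling(r0 + r)
    cc <- floor(c0 - r):ceiling(c0 + r)
    rr <- rr[rr >= 1 & rr <= nrow(sk)]
    cc <- cc[cc >= 1 & cc <= ncol(sk)]
    win <- sk[rr, cc, drop = FALSE]
    nrw <- length(rr); ncw <- length(cc)
    pr <- rep(rr, times = ncw); pc <- rep(cc, each = nrw)
    d2 <- matrix((pr - r0)^2 + (pc - c0)^2, nrw, ncw)
    flag <- if (near[k]) "near" else "ok"
    arcs <- if (method == "arms")
      .arcs_from_arms(win, d2, pr, pc, r0, c0, r)
    else .arcs_from_areas(win, d2, r, innerRadiusPx)
    if (is.null(arcs)) next
    rowsOut[[length(rowsOut) + 1L]] <-
      data.frame(angle = arcs, vertexId = vertices$id[k],
                 kind = vertices$kind[k], flag = flag,
                 stringsAsFactors = FALSE)
  }
  angles <- if (length(rowsOut)) do.call(rbind, rowsOut)
            else data.frame(angle = numeric(), vertexId = integer(),
                            kind = character(), flag = character())
  structure(list(angles = angles, bufferRadiusPx = bufferRadiusPx,
                 minSeparationPx = minSeparationPx, skipped = skipped,
                 method = method),
            class = "angleSpectrum")
}

.arcs_from_areas <- function(win, d2, r, innerRadiusPx) {
  sectors <- (d2 <= r^2) & !win
  if (!any(sectors)) return(NULL)
  # the complement of an 8-connected curve splits under 4-connectivity;
  # pixels inside innerRadiusPx are excluded from the areas (junction
  # geometry is distorted there) but still connect their sector
  lab <- .label_components4(sectors)
  lab[d2 < innerRadiusPx^2] <- 0L
  sizes <- tabulate(lab[lab > 0])
  sizes <- sizes[sizes > 0]
  if (!sum(sizes)) return(NULL)
  if (length(sizes) == 1) return(360)
  360 * sizes / sum(sizes)
}

.arcs_from_arms <- function(win, d2, pr, pc, r0, c0, r) {
  # separate the arms by removing the (possibly displaced) junction core:
  # branch pixels and their immediate neighbours
  core <- win & .neighbor_count(win) >= 3 & d2 <= 4.5^2
  coreD <- core
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    coreD <- coreD | .shift_mat(core, o[1], o[2])
  arms <- win & d2 <= r^2 & d2 > 1.5^2 & !coreD
  if (!any(arms)) return(NULL)
  lab <- .label_components(arms)
  prm <- matrix(pr, nrow(win), ncol(win))
  pcm <- matrix(pc, nrow(win), ncol(win))
  lines <- list()
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    if (sum(sel) < 2) next
    # arms must be attached to the central region, not stray passers-by
    if (min(d2[sel]) > 4.5^2) next
    py <- prm[sel]; px <- pcm[sel]
    ctr <- c(mean(px), mean(py))
    pcv <- if (sum(sel) == 2) {
      dd <- c(px[2] - px[1], py[2] - py[1]); dd / sqrt(sum(dd^2))
    } else eigen(cov(cbind(px, py)), symmetric = TRUE)$vectors[, 1]
    lines[[length(lines) + 1L]] <- list(p = ctr, d = pcv)
  }
  if (!length(lines)) return(NULL)
  if (length(lines) == 1) return(360)
  # least-squares intersection of the arm lines
  A <- matrix(0, 2, 2); b <- c(0, 0)
  for (ln in lines) {
    M <- diag(2) - tcrossprod(ln$d)
    A <- A + M
    b <- b + M %*% ln$p
  }
  cxy <- tryCatch(drop(solve(A, b)), error = function(e) c(c0, r0))
  if (sqrt((cxy[1] - c0)^2 + (cxy[2] - r0)^2) > r / 2) cxy <- c(c0, r0)
  ang <- vapply(lines, function(ln) {
    s <- sign(sum(ln$d * (ln$p - cxy)))
    if (s == 0) s <- 1
    atan2(s * ln$d[2], s * ln$d[1]) / pi * 180
  }, numeric(1))
  ang <- sort(ang %% 360)
  diff(c(ang, ang[1] + 360))
}

#' @export
print.angleSpectrum <- function(x, ...) {
  cat(sprintf("angle spectrum: %d samples from %d vertices (radius %g px)\n",
              nrow(x$angles), length(unique(x$angles$vertexId)),
              x$bufferRadiusPx))
  invisible(x)
}

#' Constrained three-Gaussian fit of an angle spectrum
#'
#' Fits the binned angular spectrum (inside a window excluding the 0- and
#' 360-degree artifact peaks) with a sum of three Gaussians of which the
#' third is constrained by the circle closure: the three arc means must sum
#' to 360 degrees, so \eqn{\mu_3 = 360 - \mu_1 - \mu_2}, its width is set
#' to \eqn{\sqrt{w_1^2 + w_2^2}} and only its amplitude is free.  The free
#' Gaussians are initialized on histogram peaks; all pairings of the three
#' strongest peaks are tried and the candidate with both free means in the
#' mother-arc range (90, 180) and the best chi-square is kept.
#'
#' @param spectrum An `angleSpectrum`.
#' @param window Fit window in degrees (default `c(20, 340)`).
#' @param binWidth Histogram bin width in degrees.
#' @param minSamples Minimum angle samples required inside the window.
#' @param excludeFlagged Drop samples from flagged vertices (near
#'   neighbours and multi-arm crossing blobs) before fitting; these are
#'   dominated by geometric-intersection artifacts.
#' @return Object of class `spectrumFit`: list with `mu1`, `mu2`, `mu3`,
#'   `w1`, `w2`, `w3`, `amplitudes`, `seMu1`, `seMu2`, `chi2`, `dof`,
#'   `chi2Reduced`, `window`, `binWidth`, `n`, `candidates` (diagnostics
#'   for every initialization).
#' @export
fitSpectrum <- function(spectrum, window = c(20, 340), binWidth = 10,
                        minSamples = 200, excludeFlagged = TRUE) {
  a <- spectrum$angles
  if (excludeFlagged) a <- a[a$flag == "ok", , drop = FALSE]
  a <- a$angle
  a <- a[a >= window[1] & a <= window[2]]
  if (length(a) < minSamples)
    stop("need at least ", minSamples, " angle samples inside the window")
  breaks <- seq(window[1], window[2] + binWidth, by = binWidth)
  breaks <- breaks[breaks <= window[2] + 1e-9]
  h <- graphics::hist(a[a <= max(breaks)], breaks = breaks, plot = FALSE)
  x <- h$mids; counts <- h$counts
  # peak candidates on a lightly smoothed histogram
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  pk <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2)
  pk <- pk[order(sm[pk], decreasing = TRUE)]
  pk <- utils::head(pk, 2)
  # overlapping populations can merge into one histogram hump: pad the
  # initialization candidates with spread quantiles of the samples, then
  # merge near-duplicates
  peakPos <- c(x[pk], unname(quantile(a, c(0.15, 0.5, 0.85))))
  peakPos <- peakPos[!is.na(peakPos)]
  keep <- rep(TRUE, length(peakPos))
  for (i in seq_along(peakPos)[-1])
    if (any(abs(peakPos[seq_len(i - 1)][keep[seq_len(i - 1)]] -
                  peakPos[i]) < 8)) keep[i] <- FALSE
  peakPos <- peakPos[keep]
  peakHeight <- stats::approx(x, counts, xout = peakPos, rule = 2)$y
  pairs <- utils::combn(seq_along(peakPos), 2, simplify = FALSE)
  N <- length(a)
  cand <- list()
  for (pr in pairs) {
    st <- list(mu1 = peakPos[pr[1]], mu2 = peakPos[pr[2]],
               s1 = 10, s2 = 10,
               A1 = max(peakHeight[pr[1]], 1) * sqrt(2 * pi) * 10,
               A2 = max(peakHeight[pr[2]], 1) * sqrt(2 * pi) * 10,
               A3 = max(median(peakHeight), 1) * sqrt(2 * pi) * 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ binWidth * (A1 * dnorm(x, mu1, s1) + A2 * dnorm(x, mu2, s2) +
                               A3 * dnorm(x, 360 - mu1 - mu2,
                                          sqrt(s1^2 + s2^2))),
        start = st, weights = 1 / pmax(counts, 1),
        lower = c(window[1], window[1], 1, 1, 0, 0, 0),
        upper = c(window[2], window[2], 90, 90, Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    chi2 <- sum(((counts - predict(fit))^2) / pmax(counts, 1))
    mu12 <- sort(c(cf[["mu1"]], cf[["mu2"]]))
    plausible <- all(mu12 > 90 & mu12 < 180) && diff(mu12) > 1e-6
    cand[[length(cand) + 1L]] <- list(fit = fit, coef = cf, chi2 = chi2,
                                      plausible = plausible,
                                      init = unlist(st[c("mu1", "mu2")]))
  }
  if (!length(cand))
    stop("three-Gaussian fit did not converge from any peak initialization; ",
         "peaks tried at ", paste(round(peakPos, 1), collapse = ", "))
  ok <- vapply(cand, `[[`, logical(1), "plausible")
  pool <- if (any(ok)) cand[ok] else cand
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "chi2"))]]
  cf <- best$coef
  Vc <- tryCatch(vcov(best$fit), error = function(e) matrix(NA, 7, 7))
  dof <- length(counts) - 7L
  out <- list(mu1 = cf[["mu1"]], mu2 = cf[["mu2"]],
              mu3 = 360 - cf[["mu1"]] - cf[["mu2"]],
              w1 = cf[["s1"]], w2 = cf[["s2"]],
              w3 = sqrt(cf[["s1"]]^2 + cf[["s2"]]^2),
              amplitudes = cf[c("A1", "A2", "A3")],
              seMu1 = sqrt(Vc[1, 1]), seMu2 = sqrt(Vc[2, 2]),
              chi2 = best$chi2, dof = dof, chi2Reduced = best$chi2 / dof,
              window = window, binWidth = binWidth, n = N,
              candidates = lapply(cand, function(z)
                list(mu = unname(z$coef[c("mu1", "mu2")]), chi2 = z$chi2,
                     plausible = z$plausible, init = z$init)))
  class(out) <- "spectrumFit"
  out
}

#' @export
print.spectrumFit <- function(x, ...) {
  cat(sprintf("three-Gaussian spectrum fit (constraint mu3 = 360 - mu1 - mu2)\n"))
  cat(sprintf("  mu = %.1f +- %.1f, %.1f +- %.1f, [%.1f] deg\n",
              x$mu1, x$seMu1, x$mu2, x$seMu2, x$mu3))
  cat(sprintf("  widths %.1f, %.1f, [%.1f] deg; chi2/dof = %.2f/%d\n",
              x$w1, x$w2, x$w3, x$chi2, x$dof))
  invisible(x)
}

#' Resolve the branching angles from fitted arc means
#'
#' With three arcs around an apical branching and the constraint that they
#' sum to 360 degrees there is a single geometric scenario: the two freely
#' fitted means are the mother-daughter arcs, so the exploratory angle is
#' the supplement of the larger mean and the operating angle the
#' supplement of the smaller, while the constrained arc is the
#' daughter-daughter arc \eqn{\theta_e + \theta_o}.  Plausibility
#' (0 < thetaE < thetaO < 90) is enforced; on failure all three candidate
#' assignments are reported in the error.
#'
#' @param fit A `spectrumFit` (or any list with `mu1`, `mu2`, `seMu1`,
#'   `seMu2`).
#' @return Object of class `scenarioResult`: list with `thetaE`, `thetaO`
#'   (degrees), `seThetaE`, `seThetaO`, `arcs` (the three arc means),
#'   `consistent` (closure check).
#' @examples
#' resolveScenario(list(mu1 = 106, mu2 = 137, seMu1 = 1, seMu2 = 3))
#' @export
resolveScenario <- function(fit) {
  mus <- c(fit$mu1, fit$mu2)
  ses <- c(fit$seMu1 %||% NA_real_, fit$seMu2 %||% NA_real_)
  if (any(!is.finite(mus))) stop("fit means are not finite")
  hi <- which.max(mus); lo <- which.min(mus)
  thetaE <- 180 - mus[hi]
  thetaO <- 180 - mus[lo]
  if (!(thetaE > 0 && thetaE < thetaO && thetaO < 90)) {
    mu3 <- 360 - sum(mus)
    allMus <- c(mus, mu3)
    cands <- utils::combn(3, 2, simplify = FALSE)
    msg <- vapply(cands, function(ix) {
      te <- 180 - max(allMus[ix]); to <- 180 - min(allMus[ix])
      sprintf("arcs (%.1f, %.1f) -> thetaE = %.1f, thetaO = %.1f",
              allMus[ix][1], allMus[ix][2], te, to)
    }, character(1))
    stop("no plausible scenario (need 0 < thetaE < thetaO < 90); candidates:\n  ",
         paste(msg, collapse = "\n  "))
  }
  mu3 <- 360 - sum(mus)
  out <- list(thetaE = thetaE, thetaO = thetaO,
              seThetaE = ses[hi], seThetaO = ses[lo],
              arcs = c(mus, mu3),
              consistent = abs((thetaE + thetaO) - mu3) < 1e-9)
  class(out) <- "scenarioResult"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenarioResult <- function(x, ...) {
  cat(sprintf("resolved scenario: thetaE = %.1f +- %.1f, thetaO = %.1f +- %.1f deg\n",
              x$thetaE, x$seThetaE, x$thetaO, x$seThetaO))
  invisible(x)
}

#' Full raster angle pipeline on a thallus
#'
#' Convenience wrapper chaining [rasterizeThallus()], [skeletonizeMask()],
#' [detectSkeletonVertices()], [bufferSpectrum()], [fitSpectrum()] and
#' [resolveScenario()].
#'
#' @inheritParams rasterizeThallus
#' @inheritParams bufferSpectrum
#' @inheritParams fitSpectrum
#' @param trimErosionPx Passed to [skeletonizeMask()].
#' @return List with all intermediate products plus `scenario`.
#' @export
measureAnglesGIS <- function(thallus,
                             pixelSize = thallus@parameters@hyphalWidth / 5,
                             widthPx = 5, trimErosionPx = 2,
                             bufferRadiusPx = 10, minSeparationPx = 10,
                             window = c(20, 340), binWidth = 10,
                             minSamples = 200) {
  mask <- rasterizeThallus(thallus, pixelSize, widthPx)
  skel <- skeletonizeMask(mask, trimErosionPx)
  verts <- detectSkeletonVertices(skel)
  spec <- bufferSpectrum(skel, verts, bufferRadiusPx, minSeparationPx)
  fit <- fitSpectrum(spec, window, binWidth, minSamples)
  list(mask = mask, skeleton = skel, vertices = verts, spectrum = spec,
       fit = fit, scenario = resolveScenario(fit))
}
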