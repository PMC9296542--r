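.toy_params <- function(params, thetaO, thetaE, sameSide = TRUE) {
  params@thetaO <- thetaO; params@thetaE <- thetaE
  params@sigmaO <- 0; params@sigmaE <- 0
  params@apicalSameSide <- sameSide
  params
}

#' Branch-overlap measure at one angle pair
#'
#' Grows `nSeeds` toy networks (deterministic equal branch lengths, zero
#' angle variance, random side choices, lateral branching off) to
#' generation `g` at the given apical angle means, counts proper branch
#' crossings, and accumulates the overlap area lost per crossing.  Two
#' constant-width straight ribbons crossing at angle \eqn{\phi} overlap in
#' a rhombus of area \eqn{w^2/\sin\phi} (capped by the ribbon area
#' available at grazing incidence); exactly stacked parallel branch pairs,
#' which the zero-variance toy geometry produces whenever two branching
#' orders commute, contribute the \eqn{\phi \to 0} limit of the same
#' area, \eqn{(w - d)\,\ell_{overlap}}.  The occupied surface is the
#' ribbon area minus this overlap: at fixed total length, maximizing
#' occupancy means minimizing the overlap measure.
#'
#' The toy places both daughters on the same rotation sense
#' (`sameSide = TRUE`): under that convention equal angle means collapse
#' the two daughter sub-trees onto each other, which is what makes the
#' occupancy argument discriminate the two angles; the opposite-side
#' convention is blind to the angle labels (swapping them only mirrors
#' the ensemble).
#'
#' @param params A [GrowthParameters-class] (supplies length scale, width,
#'   germination geometry).
#' @param thetaO,thetaE Operating and exploratory angle means (deg).
#' @param g Generation (default 9).
#' @param nSeeds Networks averaged per evaluation.
#' @param seed RNG seed used to derive the per-network seeds.
#' @param fixedLength Deterministic branch length (mm); defaults to the
#'   Gamma mean \eqn{k\theta}.
#' @param sigma Angle s.d. used in the toy geometry (default 0).
#' @param sameSide Daughter side convention of the toy (see Details).
#' @return List with `meanCrossings` and `meanOverlap` (mm^2), plus
#'   `sBio = L w` (mm^2) and `sOcc = sBio - meanOverlap`.
#' @export
overlapMeasure <- function(params, thetaO, thetaE, g = 9, nSeeds = 10,
                           seed = NA, fixedLength = NULL, sigma = 0,
                           sameSide = TRUE) {
  if (is.null(fixedLength))
    fixedLength <- params@gammaShape * params@gammaScale
  p <- .toy_params(params, thetaO, thetaE, sameSide)
  p@sigmaO <- sigma; p@sigmaE <- sigma
  if (!is.na(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nSeeds)
  w <- params@hyphalWidth
  res <- vapply(seeds, function(sd) {
    th <- simulateThallus(p, g, lateral = FALSE, seed = sd,
                          fixedLength = fixedLength)
    s <- th@segments
    c(.cross_overlap(s$x0, s$y0, s$x1, s$y1,
                     as.integer(s$tail), as.integer(s$head), w)[1:2],
      L = sum(s$length))
  }, numeric(3))
  mc <- mean(res[1, ]); mo <- mean(res[2, ])
  sBio <- mean(res[3, ]) * w
  list(meanCrossings = mc, meanOverlap = mo, sBio = sBio,
       sOcc = sBio - mo)
}

#' Sweep apical angle pairs and locate the occupancy optimum
#'
#' Evaluates [overlapMeasure()] on a grid of (operating, exploratory) angle
#' means with the same seed set in every cell (paired seeds), smooths the
#' seed-averaged overlap with a 3x3 cell window to damp Monte-Carlo noise,
#' and returns the grid minimum of the overlap measure, i.e. the angle pair
#' that maximizes the occupied surface at fixed total length.  Ties are
#' broken toward the larger angle separation `thetaO - thetaE`.  Because
#' the operating branch is by definition the one with the wider angle,
#' grid cells with `thetaO <= thetaE` are relabelings of cells above the
#' diagonal; by default the minimum is located on the `thetaO > thetaE`
#' wedge only (`wedgeOnly = FALSE` searches the whole grid).
#'
#' @inheritParams overlapMeasure
#' @param thetaO,thetaE Grid coordinates (deg), strictly increasing.
#' @param smooth Apply the 3x3 smoothing before locating the minimum.
#' @return An object of class `occupancyMap`: list with the grids, the
#'   `crossings` and `overlap` matrices (thetaO in rows), the smoothed
#'   overlap, `sBio`, `sOcc`, the `optimum` (named vector thetaO, thetaE)
#'   and the sweep settings.
#' @examples
#' \donttest{
#' p <- growthParameters()
#' om <- sweepOptimize(p, seq(10, 90, 20), seq(0, 60, 20), g = 7,
#'                     nSeeds = 3, seed = 1)
#' om$optimum
#' }
#' @export
sweepOptimize <- function(params, thetaO = seq(10, 90, by = 5),
                          thetaE = seq(0, 60, by = 5), g = 9, nSeeds = 10,
                          seed = 1, fixedLength = NULL, sigma = 0,
                          sameSide = TRUE, smooth = TRUE,
                          wedgeOnly = TRUE) {
  if (!length(thetaO) || !length(thetaE)) stop("empty angle grid")
  stopifnot(!is.unsorted(thetaO, strictly = TRUE),
            !is.unsorted(thetaE, strictly = TRUE))
  if (is.null(fixedLength))
    fixedLength <- params@gammaShape * params@gammaScale
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nSeeds)
  w <- params@hyphalWidth
  nO <- length(thetaO); nE <- length(thetaE)
  crossings <- overlap <- matrix(0, nO, nE,
                                 dimnames = list(thetaO, thetaE))
  Lbar <- 0
  for (i in seq_len(nO)) for (j in seq_len(nE)) {
    p <- .toy_params(params, thetaO[i], thetaE[j], sameSide)
    p@sigmaO <- sigma; p@sigmaE <- sigma
    acc <- c(0, 0, 0)
    for (sd in seeds) {
      th <- simulateThallus(p, g, lateral = FALSE, seed = sd,
                            fixedLength = fixedLength)
      s <- th@segments
      acc <- acc + c(.cross_overlap(s$x0, s$y0, s$x1, s$y1,
                                    as.integer(s$tail), as.integer(s$head),
                                    w)[1:2],
                     sum(s$length))
    }
    crossings[i, j] <- acc[1] / nSeeds
    overlap[i, j] <- acc[2] / nSeeds
    Lbar <- acc[3] / nSeeds
  }
  smoothed <- if (smooth) .smooth3x3(overlap) else overlap
  search <- smoothed
  if (wedgeOnly) {
    outside <- outer(thetaO, thetaE, `<=`)
    if (!all(outside)) search[outside] <- Inf
  }
  idx <- which(search == min(search), arr.ind = TRUE)
  if (nrow(idx) > 1) {
    sep <- thetaO[idx[, 1]] - thetaE[idx[, 2]]
    idx <- idx[which.max(sep), , drop = FALSE]
  }
  optimum <- c(thetaO = thetaO[idx[1, 1]], thetaE = thetaE[idx[1, 2]])
  sBio <- Lbar * w
  out <- list(thetaO = thetaO, thetaE = thetaE, crossings = crossings,
              overlap = overlap, smoothed = smoothed, sBio = sBio,
              sOcc = sBio - overlap, optimum = optimum, g = g,
              nSeeds = nSeeds, seed = seed, fixedLength = fixedLength,
              hyphalWidth = w)
  class(out) <- "occupancyMap"
  out
}

.smooth3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    rj <- max(1, j - 1):min(nc, j + 1)
    out[i, j] <- mean(m[ri, rj])
  }
  out
}

#' @export
print.occupancyMap <- function(x, ...) {
  cat(sprintf("occupancy sweep: %d x %d cells, g = %g, %d seeds/cell\n",
              length(x$thetaO), length(x$thetaE), x$g, x$nSeeds))
  cat(sprintf("  optimum (min overlap): thetaO = %g, thetaE = %g deg\n",
              x$optimum[["thetaO"]], x$optimum[["thetaE"]]))
  cat(sprintf("  overlap at optimum %.4g mm^2 of S_bio = %.4g mm^2\n",
              min(x$smoothed), x$sBio))
  invisible(x)
}

#' Heat map of the overlap measure
#'
#' Renders `log10` of the seed-averaged overlap measure over the angle
#' grid, with the located optimum marked.
#'
#' @param x An `occupancyMap`.
#' @param ... Passed to [graphics::image()].
#' @importFrom graphics image points
#' @importFrom grDevices hcl.colors
#' @export
plot.occupancyMap <- function(x, ...) {
  z <- log10(pmax(x$smoothed, .Machine$double.xmin))
  image(x$thetaE, x$thetaO, t(z), col = hcl.colors(64, "viridis"),
        xlab = expression(theta[e] * " (deg)"),
        ylab = expression(theta[o] * " (deg)"), ...)
  points(x$optimum[["thetaE"]], x$optimum[["thetaO"]], pch = 4, cex = 2,
         col = "red", lwd = 2)
  invisible(x)
}

#' Write an occupancy map as a long-format table
#'
#' @param x An `occupancyMap`.
#' @param file Output CSV path.
#' @return The long-format data.frame, invisibly.
#' @export
writeOccupancyMap <- function(x, file) {
  d <- expand.grid(thetaO = x$thetaO, thetaE = x$thetaE)
  d$crossings <- as.vector(x$crossings)
  d$overlap <- as.vector(x$overlap)
  d$sOcc <- as.vector(x$sOcc)
  write.csv(d, file, row.names = FALSE)
  invisible(d)
}
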