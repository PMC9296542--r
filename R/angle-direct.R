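.wrap180 <- function(a) ((a + 180) %% 360) - 180

# first point at Euclidean distance R from (cx, cy) along a chain of
# segment rows (walked in the given direction), or NULL if the path ends
# inside the circle or passes through an apical branching
.walk_to_radius <- function(seg, from, cx, cy, R) {
  # seg: ordered data.frame rows of the walked path; from: "tail" or "head"
  for (k in seq_len(nrow(seg))) {
    if (from == "tail") {
      ax <- seg$x0[k]; ay <- seg$y0[k]; bx <- seg$x1[k]; by <- seg$y1[k]
    } else {
      ax <- seg$x1[k]; ay <- seg$y1[k]; bx <- seg$x0[k]; by <- seg$y0[k]
    }
    # solve |a + t (b - a) - c| = R for t in (0, 1]
    dx <- bx - ax; dy <- by - ay
    fx <- ax - cx; fy <- ay - cy
    A <- dx * dx + dy * dy
    B <- 2 * (fx * dx + fy * dy)
    C <- fx * fx + fy * fy - R * R
    disc <- B * B - 4 * A * C
    if (disc >= 0) {
      t <- (-B + sqrt(disc)) / (2 * A)
      if (t > 0 && t <= 1)
        return(c(ax + t * dx, ay + t * dy))
    }
  }
  NULL
}

# ordered chain of segments leaving vertex vid along branch bid
.chain_forward <- function(s, vid, bid) {
  rows <- NULL
  cur <- vid
  repeat {
    k <- which(s$tail == cur & s$branchId == bid)
    if (!length(k)) break
    rows <- c(rows, k[1])
    cur <- s$head[k[1]]
    if (length(rows) > 50) break
  }
  s[rows, , drop = FALSE]
}

# ordered chain of segments arriving at vertex vid, walked backwards
.chain_backward <- function(s, vid) {
  rows <- NULL
  cur <- vid
  repeat {
    k <- which(s$head == cur)
    if (!length(k)) break
    if (length(rows)) {
      # keep following the same drawn branch through split points
      k <- k[s$branchId[k] == s$branchId[rows[length(rows)]]]
      if (!length(k)) break
    }
    rows <- c(rows, k[1])
    cur <- s$tail[k[1]]
    if (length(rows) > 50) break
  }
  s[rows, , drop = FALSE]
}

#' Direct circle-based angle measurement at apical branchings
#'
#' Reproduces the manual measurement protocol on the ground-truth network:
#' a circle of radius `radius` is centered on each apical branching vertex
#' (V3); the intersections of the circle with the mother path and the two
#' daughter paths define, relative to the extension of the mother hypha,
#' a small signed angle (exploratory) and a wide signed angle (operating).
#' By convention the wide angle defines the positive rotation sense, so
#' `thetaO > 0` always and `thetaE` keeps its relative sign.  Vertices
#' whose circle is crossed by a non-incident branch, or whose daughter
#' paths terminate inside the circle, are skipped with a flag.
#'
#' @param thallus A [Thallus-class] object.
#' @param vertexIds V3 vertex ids to measure (default: all apical
#'   branchings).
#' @param radius Circle radius in mm (default five hyphal widths).
#' @return data.frame with one row per vertex: `vertex`, `thetaE`,
#'   `thetaO` (signed degrees), `radius`, `flag` (`"ok"`,
#'   `"ambiguous neighborhood"`, or `"short branch"`); flagged vertices
#'   carry `NA` angles.
#' @export
circleAngles <- function(thallus, vertexIds = NULL,
                         radius = 5 * thallus@parameters@hyphalWidth) {
  stopifnot(radius > 0)
  v <- thallus@vertices; s <- thallus@segments
  if (is.null(vertexIds)) vertexIds <- v$id[v$kind == "V3"]
  out <- lapply(vertexIds, function(vid) {
    row <- data.frame(vertex = vid, thetaE = NA_real_, thetaO = NA_real_,
                      radius = radius, flag = "ok",
                      stringsAsFactors = FALSE)
    cx <- v$x[v$id == vid]; cy <- v$y[v$id == vid]
    dIdx <- which(s$tail == vid)
    mIdx <- which(s$head == vid)
    if (length(dIdx) != 2L || length(mIdx) != 1L) {
      row$flag <- "ambiguous neighborhood"; return(row)
    }
    mother <- .chain_backward(s, vid)
    d1 <- .chain_forward(s, vid, s$branchId[dIdx[1]])
    d2 <- .chain_forward(s, vid, s$branchId[dIdx[2]])
    pm <- .walk_to_radius(mother, "head", cx, cy, radius)
    p1 <- .walk_to_radius(d1, "tail", cx, cy, radius)
    p2 <- .walk_to_radius(d2, "tail", cx, cy, radius)
    if (is.null(pm) || is.null(p1) || is.null(p2)) {
      row$flag <- "short branch"; return(row)
    }
    # any non-incident segment crossing the circle?
    pathRows <- unique(c(rownames(mother), rownames(d1), rownames(d2)))
    others <- s[!(rownames(s) %in% pathRows), , drop = FALSE]
    if (nrow(others)) {
      near <- .point_segment_dist(cx, cy, others$x0, others$y0,
                                  others$x1, others$y1) < radius
      if (any(near)) {
        row$flag <- "ambiguous neighborhood"; return(row)
      }
    }
    motherDir <- atan2(cy - pm[2], cx - pm[1]) / pi * 180
    a1 <- .wrap180(atan2(p1[2] - cy, p1[1] - cx) / pi * 180 - motherDir)
    a2 <- .wrap180(atan2(p2[2] - cy, p2[1] - cx) / pi * 180 - motherDir)
    wide <- if (abs(a1) >= abs(a2)) a1 else a2
    small <- if (abs(a1) >= abs(a2)) a2 else a1
    sgn <- if (wide < 0) -1 else 1
    row$thetaO <- sgn * wide
    row$thetaE <- sgn * small
    row
  })
  do.call(rbind, out)
}

#' Gaussian population estimates from signed angle samples
#'
#' Splits signed angle samples into a small-angle and a wide-angle
#' population at a magnitude threshold and fits each with a Gaussian by
#' maximum likelihood.  Measurement errors are themselves Gaussian with
#' s.d. `deltaTheta`, so the fitted population width is deconvolved as
#' \eqn{\hat\sigma = \sqrt{s^2 - \delta\theta^2}} (floored at 0), and the
#' per-population uncertainty on the mean folds the systematic in:
#' \eqn{\sqrt{\delta\theta^2 + \hat\sigma^2 / n}}.
#'
#' @param samples Signed angles (degrees).
#' @param deltaTheta Systematic angle uncertainty (degrees, default 4).
#' @param splitThreshold Magnitude separating the populations (deg).
#' @return List of two `populationEstimate` objects (`small`, `wide`),
#'   each with `mean`, `width`, `statUncertainty` (width of the mean),
#'   `uncertainty` (systematic folded in), `systematic`, `n`.
#' @export
fitGaussianPopulations <- function(samples, deltaTheta = 4,
                                   splitThreshold = 35) {
  samples <- samples[is.finite(samples)]
  small <- samples[abs(samples) < splitThreshold]
  wide <- samples[abs(samples) >= splitThreshold]
  if (length(small) < 10 || length(wide) < 10)
    stop("populations are not separable: need >= 10 samples on each side of ",
         splitThreshold, " degrees")
  mk <- function(x) {
    m <- mean(x)
    s2 <- mean((x - m)^2)            # Gaussian MLE variance
    width <- sqrt(max(s2 - deltaTheta^2, 0))
    stat <- sqrt(s2 / length(x))
    est <- list(mean = m, width = width, statUncertainty = stat,
                uncertainty = sqrt(deltaTheta^2 + s2 / length(x)),
                systematic = deltaTheta, n = length(x))
    class(est) <- "populationEstimate"
    est
  }
  list(small = mk(small), wide = mk(wide))
}

#' Build a population estimate from reported values
#'
#' Convenience constructor for pooling published per-experiment estimates
#' (a fitted mean and its quoted uncertainty).
#'
#' @param mean Fitted population mean (deg).
#' @param uncertainty Quoted uncertainty of the mean (deg).
#' @param width Fitted population width (deg, optional).
#' @param n Sample size (optional).
#' @param systematic Systematic uncertainty folded in the quote (deg).
#' @return A `populationEstimate`.
#' @export
populationEstimate <- function(mean, uncertainty, width = NA_real_,
                               n = NA_integer_, systematic = 4) {
  est <- list(mean = mean, width = width,
              statUncertainty = NA_real_, uncertainty = uncertainty,
              systematic = systematic, n = n)
  class(est) <- "populationEstimate"
  est
}

#' @export
print.populationEstimate <- function(x, ...) {
  cat(sprintf("population estimate: mean %.2f +- %.2f deg (width %.2f, n = %s)\n",
              x$mean, x$uncertainty, x$width, format(x$n)))
  invisible(x)
}

#' Pool angle estimates from independent experiments
#'
#' Averages the per-experiment Gaussian means as i.i.d. estimates: the
#' pooled mean is the simple average of the means, the pooled statistical
#' uncertainty is the mean of the per-experiment uncertainties divided by
#' \eqn{\sqrt{n}}, and the total uncertainty folds the systematic
#' \eqn{\delta\theta} back in quadrature.  Presentation values are rounded
#' to whole degrees.
#'
#' @param estimates List of `populationEstimate` objects.
#' @param deltaTheta Systematic angle uncertainty (deg).
#' @param weighted Use inverse-variance weighting instead of the simple
#'   average.
#' @return A `populationEstimate` with additional fields `magnitude`,
#'   `totalUncertainty`, `meanRounded`, `uncertaintyRounded`.
#' @examples
#' ests <- lapply(c(-8.5, -10.2, -9.2), populationEstimate, uncertainty = 4.2)
#' combineEstimates(ests)  # pooled -9.3 +- 2.4 (stat), +- 5 total rounded
#' @export
combineEstimates <- function(estimates, deltaTheta = 4, weighted = FALSE) {
  if (!length(estimates)) stop("empty estimate list")
  m <- vapply(estimates, `[[`, numeric(1), "mean")
  u <- vapply(estimates, `[[`, numeric(1), "uncertainty")
  k <- length(m)
  pooled <- if (weighted && all(is.finite(u)) && all(u > 0))
    sum(m / u^2) / sum(1 / u^2) else mean(m)
  stat <- mean(u) / sqrt(k)
  total <- sqrt(stat^2 + deltaTheta^2)
  est <- list(mean = pooled, magnitude = abs(pooled),
              width = mean(vapply(estimates, `[[`, numeric(1), "width")),
              statUncertainty = stat, uncertainty = stat,
              totalUncertainty = total, systematic = deltaTheta,
              n = k, meanRounded = round(abs(pooled)),
              uncertaintyRounded = round(total))
  class(est) <- c("pooledEstimate", "populationEstimate")
  est
}

#' @export
print.pooledEstimate <- function(x, ...) {
  cat(sprintf(
    "pooled over %d experiments: |mean| %.2f +- %.2f (stat) +- %.2f (total)\n",
    x$n, x$magnitude, x$statUncertainty, x$totalUncertainty))
  cat(sprintf("  rounded: %d +- %d deg\n", x$meanRounded,
              x$uncertaintyRounded))
  invisible(x)
}
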