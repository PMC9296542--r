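.deg2rad <- pi / 180

.draw_len <- function(n, params, fixedLength = NULL) {
  if (!is.null(fixedLength)) rep(fixedLength, n)
  else rgamma(n, shape = params@gammaShape, scale = params@gammaScale)
}

#' Draw branch lengths from the Gamma growth law
#'
#' Branch lengths follow a Gamma law with shape `k` and scale `theta` (mm);
#' particular parameter choices recover the exponential law (k = 1), the
#' Maxwell-Boltzmann law (k = 3/2) and the chi-square law (theta = 2).
#'
#' @param params A [GrowthParameters-class] object.
#' @param n Number of draws.
#' @return Positive lengths (mm).
#' @examples
#' p <- growthParameters(seed = 1)
#' mean(sampleBranchLength(p, 1000))  # close to k * theta = 0.2 mm
#' @export
sampleBranchLength <- function(params, n = 1) {
  stopifnot(params@gammaShape > 0, params@gammaScale > 0)
  rgamma(n, shape = params@gammaShape, scale = params@gammaScale)
}

#' Lateral branching probability of a segment
#'
#' The per-pass probability that a segment of length `x` spawns a lateral
#' branch is the power law \eqn{p = p_0 (x / x_0)^\alpha}, recomputed after
#' each generation.  Lengths beyond `x0` (the law nominally requires
#' \eqn{x_0 \ge x}) are clamped to `p0` with a warning.
#'
#' @param x Segment length(s), mm.
#' @param params A [GrowthParameters-class] object.
#' @param warn Warn when `x > lateralX0` (clamped); the simulation engine
#'   clamps silently.
#' @return Probabilities in `[0, 1]`.
#' @export
lateralProbability <- function(x, params, warn = TRUE) {
  stopifnot(all(x >= 0))
  over <- x > params@lateralX0
  if (warn && any(over))
    warning("segment length exceeds lateralX0; probability clamped to lateralP0")
  pmin(1, params@lateralP0 *
         (pmin(x, params@lateralX0) / params@lateralX0)^params@lateralAlpha)
}

#' One apical branching event
#'
#' Draws the pair of daughters created when an apex divides: an exploratory
#' branch deviating by a small angle from the mother's extension and an
#' operating branch deviating by a wide angle on the opposite side.  Which
#' side carries the operating branch is a Bernoulli draw
#' (`apicalSideProb`); positive signed angles are counter-clockwise.
#'
#' @param motherDir Direction of the mother branch at the apex, degrees.
#' @param params A [GrowthParameters-class] object.
#' @param fixedLength Optional deterministic daughter length (mm) replacing
#'   the Gamma draw.
#' @return data.frame with one row per daughter (`type`, `signedAngle`,
#'   `direction` in degrees, `length` in mm).
#' @examples
#' p <- growthParameters(sigmaE = 0, sigmaO = 0, seed = 1)
#' apicalBranch(0, p)  # daughters at +71/-10 or -71/+10 degrees
#' @export
apicalBranch <- function(motherDir = 0, params, fixedLength = NULL) {
  side <- if (runif(1) < params@apicalSideProb) 1 else -1
  eSide <- if (params@apicalSameSide) side else -side
  angO <- rnorm(1, params@thetaO, params@sigmaO) * side
  angE <- rnorm(1, params@thetaE, params@sigmaE) * eSide
  len <- .draw_len(2, params, fixedLength)
  data.frame(type = c("operating", "exploratory"),
             signedAngle = c(angO, angE),
             direction = motherDir + c(angO, angE),
             length = len)
}

.germinate <- function(params, fixedLength = NULL) {
  nG <- params@nGerm
  dirs <- (seq_len(nG) - 1) * params@germSeparation * .deg2rad
  len <- .draw_len(nG, params, fixedLength)
  v <- data.frame(
    id = seq_len(nG + 1L),
    kind = c("germ", rep("V1", nG)),
    x = c(0, len * cos(dirs)), y = c(0, len * sin(dirs)),
    birthGen = c(1L, rep(2L, nG)),
    dir = c(NA_real_, dirs),
    stringsAsFactors = FALSE)
  s <- data.frame(
    id = seq_len(nG), tail = rep(1L, nG), head = 2:(nG + 1L),
    x0 = 0, y0 = 0, x1 = len * cos(dirs), y1 = len * sin(dirs),
    length = len, type = "germinal", generation = 2L,
    branchId = seq_len(nG), stringsAsFactors = FALSE)
  list(v = v, s = s)
}

.apical_pass <- function(st, params, gg, fixedLength = NULL) {
  ap <- which(st$v$kind %in% c("V1", "V1l"))
  n <- length(ap)
  if (n == 0L) return(st)
  dir <- st$v$dir[ap]
  side <- ifelse(runif(n) < params@apicalSideProb, 1, -1)
  eSide <- if (params@apicalSameSide) side else -side
  angO <- rnorm(n, params@thetaO, params@sigmaO) * side
  angE <- rnorm(n, params@thetaE, params@sigmaE) * eSide
  lenO <- .draw_len(n, params, fixedLength)
  lenE <- .draw_len(n, params, fixedLength)
  dO <- dir + angO * .deg2rad
  dE <- dir + angE * .deg2rad
  px <- st$v$x[ap]; py <- st$v$y[ap]
  lateralLine <- st$v$kind[ap] == "V1l"
  nv <- nrow(st$v); ns <- nrow(st$s); nb <- max(st$s$branchId)
  idO <- nv + seq_len(n); idE <- nv + n + seq_len(n)
  newv <- data.frame(
    id = c(idO, idE),
    kind = rep(ifelse(lateralLine, "V1l", "V1"), 2L),
    x = c(px + lenO * cos(dO), px + lenE * cos(dE)),
    y = c(py + lenO * sin(dO), py + lenE * sin(dE)),
    birthGen = gg, dir = c(dO, dE), stringsAsFactors = FALSE)
  news <- data.frame(
    id = ns + seq_len(2L * n),
    tail = rep(st$v$id[ap], 2L), head = c(idO, idE),
    x0 = rep(px, 2L), y0 = rep(py, 2L),
    x1 = newv$x, y1 = newv$y,
    length = c(lenO, lenE),
    type = rep(c("operating", "exploratory"), each = n),
    generation = gg, branchId = nb + seq_len(2L * n),
    stringsAsFactors = FALSE)
  st$v$kind[ap] <- ifelse(lateralLine, "V3l", "V3")
  st$v$dir[ap] <- NA_real_
  st$v <- rbind(st$v, newv)
  st$s <- rbind(st$s, news)
  st
}

.lateral_pass <- function(st, params, gg, fixedLength = NULL) {
  el <- which(st$s$generation < gg)
  if (!length(el)) return(st)
  p <- lateralProbability(st$s$length[el], params, warn = FALSE)
  hit <- el[runif(length(el)) < p]
  m <- length(hit)
  if (!m) return(st)
  cf <- params@censorshipFraction
  u <- runif(m, cf, 1 - cf)
  hx0 <- st$s$x0[hit]; hy0 <- st$s$y0[hit]
  hx1 <- st$s$x1[hit]; hy1 <- st$s$y1[hit]
  hostDir <- atan2(hy1 - hy0, hx1 - hx0)
  pxx <- hx0 + u * (hx1 - hx0); pyy <- hy0 + u * (hy1 - hy0)
  side <- ifelse(runif(m) < params@lateralSideProb, 1, -1)
  ang <- hostDir + side *
    rnorm(m, params@thetaLateral, params@sigmaLateral) * .deg2rad
  blen <- .draw_len(m, params, fixedLength)
  nv <- nrow(st$v); ns <- nrow(st$s); nb <- max(st$s$branchId)
  idV3l <- nv + seq_len(m); idV1l <- nv + m + seq_len(m)
  newv <- data.frame(
    id = c(idV3l, idV1l),
    kind = rep(c("V3l", "V1l"), each = m),
    x = c(pxx, pxx + blen * cos(ang)),
    y = c(pyy, pyy + blen * sin(ang)),
    birthGen = gg, dir = c(rep(NA_real_, m), ang),
    stringsAsFactors = FALSE)
  # distal halves of the split hosts keep type/generation/branchId
  distal <- st$s[hit, ]
  distal$id <- ns + seq_len(m)
  distal$tail <- idV3l
  distal$x0 <- pxx; distal$y0 <- pyy
  distal$length <- (1 - u) * st$s$length[hit]
  # proximal halves: shorten in place
  st$s$head[hit] <- idV3l
  st$s$x1[hit] <- pxx; st$s$y1[hit] <- pyy
  st$s$length[hit] <- u * st$s$length[hit]
  news <- data.frame(
    id = ns + m + seq_len(m),
    tail = idV3l, head = idV1l,
    x0 = pxx, y0 = pyy,
    x1 = pxx + blen * cos(ang), y1 = pyy + blen * sin(ang),
    length = blen, type = "lateral", generation = gg,
    branchId = nb + seq_len(m), stringsAsFactors = FALSE)
  st$v <- rbind(st$v, newv)
  st$s <- rbind(st$s, distal, news)
  st
}

.as_thallus <- function(st, g, params) {
  new("Thallus", vertices = st$v, segments = st$s,
      generation = g, germinationPoint = c(0, 0), parameters = params)
}

#' Simulate the growth of a thallus
#'
#' Grows a lattice-free full binary tree from an ascospore germination:
#' `nGerm` initial branches separated by `germSeparation` degrees, then
#' `generations - 2` growth passes.  Each pass (i) apically branches every
#' apex (V1 and V1l) into an exploratory and an operating daughter and
#' (ii) when `lateral = TRUE` visits every segment created in an earlier
#' pass and spawns at most one lateral branch with probability
#' [lateralProbability()] of its current length, placed uniformly along the
#' segment outside a censorship zone at each end.  Lateral sub-trees keep
#' the lateral vertex kinds (V3l branch points, V1l apexes), so the apical
#' apex count is exactly `nGerm * 2^(g-2)` for every seed.
#'
#' @param params A [GrowthParameters-class] object.
#' @param generations Final generation index g >= 2; g = 2 is the
#'   germination state (three apexes, no branchings).
#' @param lateral Enable lateral branching.
#' @param seed RNG seed; default the seed stored in `params` (NA leaves the
#'   RNG state untouched).
#' @param fixedLength Optional deterministic branch length (mm) replacing
#'   every Gamma draw (the toy-model geometry used for the angle sweep).
#' @return A [Thallus-class] object.
#' @examples
#' th <- simulateThallus(growthParameters(seed = 1), 6)
#' summarizeThallus(th)$nV1  # 3 * 2^(6-2) = 48
#' @export
simulateThallus <- function(params, generations, lateral = FALSE,
                            seed = params@seed, fixedLength = NULL) {
  if (generations < 2)
    stop("generations must be >= 2 (g = 2 is the germination state)")
  if (!is.na(seed)) set.seed(as.integer(seed))
  st <- .germinate(params, fixedLength)
  if (generations > 2)
    for (gg in seq(3L, generations)) {
      st <- .apical_pass(st, params, gg, fixedLength)
      if (lateral) st <- .lateral_pass(st, params, gg, fixedLength)
    }
  .as_thallus(st, generations, params)
}

#' Simulate a thallus and keep every intermediate generation
#'
#' Identical growth path to [simulateThallus()] (same seed gives the same
#' final network) but returns the state after germination and after each
#' pass, for time-series observation and calibration.
#'
#' @inheritParams simulateThallus
#' @param gMax Final generation (>= 2).
#' @return List of [Thallus-class] objects for g = 2, ..., gMax.
#' @export
thallusSeries <- function(params, gMax, lateral = FALSE,
                          seed = params@seed, fixedLength = NULL) {
  if (gMax < 2) stop("gMax must be >= 2")
  if (!is.na(seed)) set.seed(as.integer(seed))
  st <- .germinate(params, fixedLength)
  out <- list(.as_thallus(st, 2, params))
  if (gMax > 2)
    for (gg in seq(3L, gMax)) {
      st <- .apical_pass(st, params, gg, fixedLength)
      if (lateral) st <- .lateral_pass(st, params, gg, fixedLength)
      out[[length(out) + 1L]] <- .as_thallus(st, gg, params)
    }
  names(out) <- as.character(seq(2L, gMax))
  out
}
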