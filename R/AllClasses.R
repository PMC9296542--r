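#' @useDynLib thallus, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rgamma rnorm runif rbinom rpois dnorm sd var quantile
#'   coef vcov lm nls optim setNames median qnorm dist predict
#' @importFrom utils read.csv write.csv head tail
NULL

.vertex_kinds <- c("germ", "V1", "V3", "V1l", "V3l")
.branch_types <- c("germinal", "exploratory", "operating", "lateral")

#' Growth-law parameters of the branching model
#'
#' Container for every probability-law parameter of the lattice-free
#' binary-tree growth model: the Gamma law for branch lengths, the Gaussian
#' laws for the exploratory, operating and lateral branching angles, the
#' power law for lateral branching, the chirality Bernoulli probabilities and
#' the germination geometry.  Units: lengths in mm, angles in degrees.
#'
#' @slot gammaShape Gamma shape \eqn{k} of the branch-length law (unitless).
#' @slot gammaScale Gamma scale \eqn{\theta} of the branch-length law (mm);
#'   the mean drawn length is \eqn{k\theta}.
#' @slot thetaE,sigmaE Mean and s.d. of the exploratory branching angle (deg).
#' @slot thetaO,sigmaO Mean and s.d. of the operating branching angle (deg).
#' @slot thetaLateral,sigmaLateral Mean and s.d. of the lateral branching
#'   angle (deg); default to the operating values.
#' @slot lateralP0 Scale \eqn{p_0} of the lateral branching probability.
#' @slot lateralX0 Length scale \eqn{x_0} (mm) of the lateral power law;
#'   defaults to the largest realizable draw, mean plus three s.d.
#'   (\eqn{k\theta + 3\sqrt{k}\theta}).
#' @slot lateralAlpha Exponent \eqn{\alpha} of the lateral power law.
#' @slot apicalSideProb Probability that the operating daughter is placed on
#'   the left (counter-clockwise) side of the mother's extension.
#' @slot apicalSameSide When `FALSE` (default) the exploratory daughter
#'   deviates on the opposite side of the mother's extension from the
#'   operating one, as measured in *P. anserina* (wide angle positive,
#'   small angle negative); when `TRUE` both daughters deviate with the
#'   same rotation sense, the convention under which equal angle means
#'   collapse the two sub-trees onto each other (used by the occupancy
#'   sweep).
#' @slot lateralSideProb Probability that a lateral branch emerges on the
#'   left side of its host segment.
#' @slot censorshipFraction Fraction of a host segment's length, at each end,
#'   excluded from the uniform placement of lateral branching points.
#' @slot nGerm Number of germination branches (default 3).
#' @slot germSeparation Angular separation of germination branches (deg).
#' @slot hyphalWidth Hyphal (ribbon) width \eqn{w} in mm.
#' @slot velocityMean,velocitySd Nominal apex velocity annotation
#'   (mm per generation); does not modify geometry.
#' @slot seed Default RNG seed (NA for none).
#' @seealso [growthParameters()] for construction with defaults.
#' @export
setClass("GrowthParameters", representation(
  gammaShape = "numeric", gammaScale = "numeric",
  thetaE = "numeric", sigmaE = "numeric",
  thetaO = "numeric", sigmaO = "numeric",
  thetaLateral = "numeric", sigmaLateral = "numeric",
  lateralP0 = "numeric", lateralX0 = "numeric", lateralAlpha = "numeric",
  apicalSideProb = "numeric", apicalSameSide = "logical",
  lateralSideProb = "numeric",
  censorshipFraction = "numeric",
  nGerm = "integer", germSeparation = "numeric",
  hyphalWidth = "numeric",
  velocityMean = "numeric", velocitySd = "numeric",
  seed = "integer"
))

setValidity("GrowthParameters", function(object) {
  p <- object
  msg <- character()
  for (s in slotNames(p)) if (length(slot(p, s)) != 1L)
    msg <- c(msg, paste0(s, " must be length 1"))
  if (length(msg)) return(msg)
  probs <- c(p@lateralP0, p@apicalSideProb, p@lateralSideProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (p@gammaShape <= 0 || p@gammaScale <= 0)
    msg <- c(msg, "Gamma parameters must be positive")
  if (p@lateralX0 <= 0) msg <- c(msg, "lateralX0 must be positive")
  if (p@lateralAlpha < 0) msg <- c(msg, "lateralAlpha must be >= 0")
  if (p@censorshipFraction < 0 || p@censorshipFraction >= 0.5)
    msg <- c(msg, "censorshipFraction must lie in [0, 0.5)")
  if (p@nGerm < 1L) msg <- c(msg, "nGerm must be >= 1")
  if (p@hyphalWidth <= 0) msg <- c(msg, "hyphalWidth must be positive")
  if (any(c(p@sigmaE, p@sigmaO, p@sigmaLateral) < 0))
    msg <- c(msg, "angle standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct growth parameters
#'
#' Defaults describe the standard study conditions for *Podospora anserina*:
#' mean inter-vertex length 0.2 mm (Gamma with shape 3), measured apical
#' angle means 10 and 71 degrees with measured widths 8.7 and 12 degrees,
#' lateral branching power law with \eqn{p_0 = 1/2} and \eqn{\alpha = 2},
#' three germination branches 120 degrees apart, hyphal width 16 um.
#'
#' @param gammaShape,gammaScale Gamma branch-length law (shape, scale in mm).
#' @param thetaE,sigmaE,thetaO,sigmaO Apical angle laws (deg).
#' @param thetaLateral,sigmaLateral Lateral angle law (deg); `NA` uses the
#'   operating values.
#' @param lateralP0,lateralX0,lateralAlpha Lateral branching power law;
#'   `lateralX0 = NA` uses \eqn{k\theta + 3\sqrt{k}\theta}.
#' @param apicalSideProb,lateralSideProb Chirality Bernoulli probabilities.
#' @param apicalSameSide Place both daughters on the same rotation sense
#'   (`FALSE`: opposite sides, the measured configuration).
#' @param censorshipFraction Censored fraction at each host-segment end.
#' @param nGerm,germSeparation Germination branch count and separation (deg).
#' @param hyphalWidth Ribbon width (mm).
#' @param velocityMean,velocitySd Nominal velocity annotation.
#' @param seed Default seed (`NA` for none).
#' @return A [GrowthParameters-class] object.
#' @examples
#' p <- growthParameters(seed = 1)
#' lateralProbability(p@lateralX0 / 2, p)
#' @export
growthParameters <- function(gammaShape = 3, gammaScale = 0.2 / 3,
                             thetaE = 10, sigmaE = 8.7,
                             thetaO = 71, sigmaO = 12,
                             thetaLateral = NA, sigmaLateral = NA,
                             lateralP0 = 0.5, lateralX0 = NA,
                             lateralAlpha = 2,
                             apicalSideProb = 0.5, apicalSameSide = FALSE,
                             lateralSideProb = 0.5,
                             censorshipFraction = 0.1,
                             nGerm = 3L, germSeparation = 120,
                             hyphalWidth = 0.016,
                             velocityMean = 1, velocitySd = 0,
                             seed = NA) {
  if (is.na(thetaLateral)) thetaLateral <- thetaO
  if (is.na(sigmaLateral)) sigmaLateral <- sigmaO
  if (is.na(lateralX0))
    lateralX0 <- gammaShape * gammaScale + 3 * sqrt(gammaShape) * gammaScale
  new("GrowthParameters",
      gammaShape = gammaShape, gammaScale = gammaScale,
      thetaE = thetaE, sigmaE = sigmaE, thetaO = thetaO, sigmaO = sigmaO,
      thetaLateral = thetaLateral, sigmaLateral = sigmaLateral,
      lateralP0 = lateralP0, lateralX0 = lateralX0,
      lateralAlpha = lateralAlpha,
      apicalSideProb = apicalSideProb, apicalSameSide = apicalSameSide,
      lateralSideProb = lateralSideProb,
      censorshipFraction = censorshipFraction,
      nGerm = as.integer(nGerm), germSeparation = germSeparation,
      hyphalWidth = hyphalWidth,
      velocityMean = velocityMean, velocitySd = velocitySd,
      seed = as.integer(seed))
}

setMethod("show", "GrowthParameters", function(object) {
  cat("GrowthParameters\n")
  cat(sprintf("  branch length ~ Gamma(k = %g, theta = %g mm)  <l> = %g mm\n",
              object@gammaShape, object@gammaScale,
              object@gammaShape * object@gammaScale))
  cat(sprintf("  apical angles: exploratory N(%g, %g), operating N(%g, %g) deg\n",
              object@thetaE, object@sigmaE, object@thetaO, object@sigmaO))
  cat(sprintf("  lateral: N(%g, %g) deg, p = %g (x/%g mm)^%g, censorship %g\n",
              object@thetaLateral, object@sigmaLateral, object@lateralP0,
              object@lateralX0, object@lateralAlpha,
              object@censorshipFraction))
  cat(sprintf("  germination: %d branches, %g deg apart; hyphal width %g mm\n",
              object@nGerm, object@germSeparation, object@hyphalWidth))
})

#' Planar rooted branching network of a simulated thallus
#'
#' The ground-truth vegetative network: typed vertices (germination point,
#' apical apexes V1, apical branch points V3, lateral apexes V1l, lateral
#' branch points V3l) and straight segments between them.  The network is a
#' tree rooted at the germination point; branch crossings exist only
#' geometrically (in the 2D embedding), never as graph edges.
#'
#' @slot vertices data.frame with columns `id`, `kind` (one of germ, V1, V3,
#'   V1l, V3l), `x`, `y` (mm), `birthGen`, `dir` (incoming direction,
#'   radians; NA for non-apex vertices).
#' @slot segments data.frame with columns `id`, `tail`, `head`, `x0`, `y0`,
#'   `x1`, `y1`, `length` (mm), `type` (germinal/exploratory/operating/
#'   lateral), `generation`, `branchId` (drawn-branch identity preserved
#'   across lateral splits).
#' @slot generation Generation index g; g = 2 is the germination state.
#' @slot germinationPoint Coordinates of the germination point (mm).
#' @slot parameters The [GrowthParameters-class] used to grow the network.
#' @seealso [simulateThallus()], [summarizeThallus()]
#' @export
setClass("Thallus", representation(
  vertices = "data.frame", segments = "data.frame",
  generation = "numeric", germinationPoint = "numeric",
  parameters = "GrowthParameters"
))

setValidity("Thallus", function(object) {
  v <- object@vertices; s <- object@segments
  msg <- character()
  if (!all(c("id", "kind", "x", "y", "birthGen") %in% names(v)))
    msg <- c(msg, "vertices missing required columns")
  if (!all(c("id", "tail", "head", "x0", "y0", "x1", "y1", "length",
             "type", "generation", "branchId") %in% names(s)))
    msg <- c(msg, "segments missing required columns")
  if (length(msg)) return(msg)
  if (!all(v$kind %in% .vertex_kinds)) msg <- c(msg, "unknown vertex kind")
  if (!all(is.finite(v$x)) || !all(is.finite(v$y)))
    msg <- c(msg, "vertex positions must be finite")
  if (nrow(s) && any(s$length <= 0)) msg <- c(msg, "segment lengths must be positive")
  if (object@generation < 2) msg <- c(msg, "generation must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Thallus", function(object) {
  s <- summarizeThallus(object)
  cat(sprintf("Thallus (g = %g)\n", object@generation))
  cat(sprintf("  vertices: %d V1, %d V3, %d V1l, %d V3l (+ germ)\n",
              s$nV1, s$nV3, s$nV1l, s$nV3l))
  cat(sprintf("  segments: %d (%d drawn branches, %d lateral)\n",
              s$nSegments, s$nBranches, s$nLateralBranches))
  cat(sprintf("  total length %.3f mm, mean segment length %.4f mm\n",
              s$totalLength, s$meanSegmentLength))
})

#' Measurement-chain parameters for observing a thallus
#'
#' Parameters of the artifact layer that converts a ground-truth network into
#' what an imaging chain reports: isotropic Gaussian position blur, geometric
#' branch crossings recorded as apparent vertices, apexes merged into nearby
#' branches, rare hyphal fusions, and ghost vertices from reconstruction.
#'
#' @slot resolutionSigma Gaussian position blur s.d. (mm).
#' @slot mergeDistance Apex-near-branch merge threshold (mm).
#' @slot ghostRate Expected ghost vertices per image (Poisson mean).
#' @slot fuseProb Probability that a crossing is recorded as a fusion (V3o).
#' @slot crossingMultiplicity Observed 3-degree vertices per pure crossing.
#' @slot seed Default seed (NA for none).
#' @seealso [observationParameters()], [observeThallus()]
#' @export
setClass("ObservationParameters", representation(
  resolutionSigma = "numeric", mergeDistance = "numeric",
  ghostRate = "numeric", fuseProb = "numeric",
  crossingMultiplicity = "integer", seed = "integer"
))

setValidity("ObservationParameters", function(object) {
  msg <- character()
  if (object@resolutionSigma < 0 || object@mergeDistance < 0 ||
      object@ghostRate < 0)
    msg <- c(msg, "observation parameters must be non-negative")
  if (object@fuseProb < 0 || object@fuseProb > 1)
    msg <- c(msg, "fuseProb must lie in [0, 1]")
  if (object@crossingMultiplicity < 1L)
    msg <- c(msg, "crossingMultiplicity must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct observation parameters
#'
#' Defaults: position blur of half a hyphal width, merge threshold of one
#' hyphal width, no hyphal fusion (anastomosis is marginal), no ghosts
#' (marginal and time independent), two observed 3-degree vertices per pure
#' crossing (a crossing reconstructs as two nearby 3-branch vertices).
#'
#' @param resolutionSigma Gaussian position blur s.d. (mm).
#' @param mergeDistance Apex-near-branch merge threshold (mm).
#' @param ghostRate Expected ghost vertices per image.
#' @param fuseProb Probability a crossing is recorded as a fusion.
#' @param crossingMultiplicity 3-degree vertices per pure crossing.
#' @param seed Default seed.
#' @return An [ObservationParameters-class] object.
#' @export
observationParameters <- function(resolutionSigma = 0.008,
                                  mergeDistance = 0.016,
                                  ghostRate = 0, fuseProb = 0,
                                  crossingMultiplicity = 2L, seed = NA) {
  new("ObservationParameters",
      resolutionSigma = resolutionSigma, mergeDistance = mergeDistance,
      ghostRate = ghostRate, fuseProb = fuseProb,
      crossingMultiplicity = as.integer(crossingMultiplicity),
      seed = as.integer(seed))
}

setMethod("show", "ObservationParameters", function(object) {
  cat("ObservationParameters\n")
  cat(sprintf("  blur sigma %g mm, merge distance %g mm\n",
              object@resolutionSigma, object@mergeDistance))
  cat(sprintf("  fuseProb %g, crossing multiplicity %d, ghost rate %g\n",
              object@fuseProb, object@crossingMultiplicity, object@ghostRate))
})

#' A thallus as seen through the measurement chain
#'
#' Output of [observeThallus()]: the jittered network, the geometric-crossing
#' records, the observed vertex table (with artifact vertices) and the
#' assembled observed counts.
#'
#' @slot vertices Observed vertex table: columns `id`, `kind` (V1ob, V3ob,
#'   V3i, V3o, V1g, V3g), `x`, `y`, `origin` (true kind or artifact source).
#' @slot segments Jittered segment table (same columns as in
#'   [Thallus-class]).
#' @slot crossings data.frame of proper crossings (segA, segB, x, y, angle,
#'   fused).
#' @slot counts Named numeric vector of observed counts (N_V1ob, N_V3ob,
#'   N_V3i, N_V3o, N_V1g, N_V3g, crossings, merged, L_ob, t and the true
#'   composition terms N_V1, N_V1l, N_V3, N_V3l).
#' @slot parameters The [ObservationParameters-class] used.
#' @export
setClass("ObservedThallus", representation(
  vertices = "data.frame", segments = "data.frame",
  crossings = "data.frame", counts = "numeric",
  parameters = "ObservationParameters"
))

setMethod("show", "ObservedThallus", function(object) {
  n <- object@counts
  cat("ObservedThallus\n")
  cat(sprintf("  N_V1ob = %d, N_V3ob = %d (crossings %d, merged %d, fused %d)\n",
              as.integer(n[["N_V1ob"]]), as.integer(n[["N_V3ob"]]),
              as.integer(n[["crossings"]]), as.integer(n[["merged"]]),
              as.integer(n[["N_V3o"]])))
  cat(sprintf("  observed length %.3f mm at t = %g\n",
              n[["L_ob"]], n[["t"]]))
})
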