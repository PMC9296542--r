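.point_segment_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  l2 <- dx * dx + dy * dy
  # zero-length segments project everything onto their single point
  t <- ((px - x0) * dx + (py - y0) * dy) / pmax(l2, .Machine$double.xmin)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# apexes within eps of a segment they are not an endpoint of
.merged_apexes <- function(v, s, eps) {
  ap <- which(v$kind %in% c("V1", "V1l"))
  if (!length(ap) || eps <= 0 || !nrow(s)) return(integer())
  merged <- logical(length(ap))
  for (k in seq_along(ap)) {
    i <- ap[k]
    px <- v$x[i]; py <- v$y[i]
    cand <- which(s$tail != v$id[i] & s$head != v$id[i] &
                    pmin(s$x0, s$x1) - eps <= px &
                    pmax(s$x0, s$x1) + eps >= px &
                    pmin(s$y0, s$y1) - eps <= py &
                    pmax(s$y0, s$y1) + eps >= py)
    if (length(cand))
      merged[k] <- any(.point_segment_dist(px, py, s$x0[cand], s$y0[cand],
                                           s$x1[cand], s$y1[cand]) <= eps)
  }
  ap[merged]
}

#' Observe a thallus through the measurement chain
#'
#' Convolves the ground-truth network with the artifact layer of an imaging
#' chain: (1) every vertex position is jittered by an isotropic Gaussian of
#' s.d. `resolutionSigma`; (2) geometric branch crossings are detected on
#' the jittered geometry; each is recorded as a hyphal fusion (one observed
#' 3-degree vertex, V3o) with probability `fuseProb`, otherwise as a pure
#' crossing contributing `crossingMultiplicity` observed 3-degree vertices
#' (V3i); (3) every apex within `mergeDistance` of a non-incident segment is
#' indistinguishable from that branch: it is removed from the observed
#' apexes and counted as one additional V3i; (4) Poisson(`ghostRate`) ghost
#' vertices are added, split evenly between 1-degree (V1g) and 3-degree
#' (V3g) ghosts.  With all artifact parameters zero the observation is the
#' identity on counts.
#'
#' The observed apex count decomposes as
#' `N_V1ob = N_V1 + N_V1l + N_V1g - merged`, and the observed 3-degree
#' count as `N_V3ob = N_V3 + N_V3l + multiplicity * pureCrossings + N_V3o +
#' merged + N_V3g`; the realized artifact terms are reported in `counts`
#' rather than as free coefficients.
#'
#' @param thallus A [Thallus-class] object.
#' @param obs An [ObservationParameters-class] object.
#' @param time Nominal time stamp stored with the counts (defaults to the
#'   generation index).
#' @param seed RNG seed (default the seed in `obs`; NA leaves the RNG state
#'   untouched).
#' @return An [ObservedThallus-class] object.
#' @export
observeThallus <- function(thallus, obs = observationParameters(),
                           time = thallus@generation, seed = obs@seed) {
  stopifnot(is(thallus, "Thallus"), is(obs, "ObservationParameters"))
  if (!is.na(seed)) set.seed(as.integer(seed))
  v <- thallus@vertices; s <- thallus@segments
  if (obs@resolutionSigma > 0) {
    v$x <- v$x + rnorm(nrow(v), 0, obs@resolutionSigma)
    v$y <- v$y + rnorm(nrow(v), 0, obs@resolutionSigma)
    s$x0 <- v$x[match(s$tail, v$id)]; s$y0 <- v$y[match(s$tail, v$id)]
    s$x1 <- v$x[match(s$head, v$id)]; s$y1 <- v$y[match(s$head, v$id)]
    s$length <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
  }
  cross <- .cross_segments(s$x0, s$y0, s$x1, s$y1,
                           as.integer(s$tail), as.integer(s$head))
  nCross <- nrow(cross)
  fused <- if (nCross) runif(nCross) < obs@fuseProb else logical()
  cross$fused <- fused
  mergedIdx <- .merged_apexes(v, s, obs@mergeDistance)
  nMerged <- length(mergedIdx)
  nGhost <- if (obs@ghostRate > 0) rpois(1, obs@ghostRate) else 0L
  nV1g <- if (nGhost) sum(runif(nGhost) < 0.5) else 0L
  nV3g <- nGhost - nV1g

  kindTrue <- v$kind
  nV1 <- sum(kindTrue == "V1"); nV1l <- sum(kindTrue == "V1l")
  nV3 <- sum(kindTrue == "V3"); nV3l <- sum(kindTrue == "V3l")
  nPure <- nCross - sum(fused)
  nV3i <- nPure + nMerged
  nV3o <- sum(fused)
  nV1ob <- nV1 + nV1l + nV1g - nMerged
  nV3ob <- nV3 + nV3l + obs@crossingMultiplicity * nPure + nV3o +
    nMerged + nV3g
  Lob <- sum(s$length)

  obsKind <- ifelse(kindTrue %in% c("V1", "V1l"), "V1ob",
                    ifelse(kindTrue %in% c("V3", "V3l"), "V3ob", "germ"))
  obsKind[mergedIdx] <- "V3i"
  ov <- data.frame(id = v$id, kind = obsKind, x = v$x, y = v$y,
                   origin = kindTrue, stringsAsFactors = FALSE)
  if (nCross) {
    ov <- rbind(ov, data.frame(
      id = max(v$id) + seq_len(nCross),
      kind = ifelse(fused, "V3o", "V3i"),
      x = cross$x, y = cross$y, origin = "crossing",
      stringsAsFactors = FALSE))
  }
  if (nGhost) {
    rx <- range(v$x); ry <- range(v$y)
    ov <- rbind(ov, data.frame(
      id = max(ov$id) + seq_len(nGhost),
      kind = c(rep("V1g", nV1g), rep("V3g", nV3g)),
      x = runif(nGhost, rx[1], rx[2]), y = runif(nGhost, ry[1], ry[2]),
      origin = "ghost", stringsAsFactors = FALSE))
  }
  counts <- c(N_V1ob = nV1ob, N_V3ob = nV3ob, N_V3i = nV3i, N_V3o = nV3o,
              N_V1g = nV1g, N_V3g = nV3g, crossings = nCross,
              merged = nMerged, N_V1 = nV1, N_V1l = nV1l, N_V3 = nV3,
              N_V3l = nV3l, L_ob = Lob, t = time)
  new("ObservedThallus", vertices = ov, segments = s, crossings = cross,
      counts = counts, parameters = obs)
}

#' Observed growth time series
#'
#' Grows one thallus to `gMax` and observes each intermediate generation
#' independently (cumulative network, fresh observation per time point),
#' producing the input expected by the growth-curve calibration: counts with
#' Poisson uncertainties and total length with
#' \eqn{\sigma_L = \sqrt{N_{V1ob} + N_{V3ob}}\,\langle\ell\rangle}.
#'
#' @inheritParams simulateThallus
#' @param obs An [ObservationParameters-class] object.
#' @param gMax Final generation (>= 3).
#' @param lateral Enable lateral branching (on by default: the observed
#'   series is the quantity the growth model is calibrated on).
#' @return data.frame with one row per generation `t = 2, ..., gMax` and
#'   columns `t`, `N_V1ob`, `N_V3ob`, `L`, `sigma_V1`, `sigma_V3`,
#'   `sigma_L`, plus the realized artifact terms `N_V3i`, `N_V3o`,
#'   `crossings`, `merged`.
#' @export
observedSeries <- function(params, obs = observationParameters(),
                           gMax = 9, lateral = TRUE, seed = params@seed) {
  stopifnot(gMax >= 3)
  if (!is.na(seed)) set.seed(as.integer(seed))
  obsSeeds <- sample.int(.Machine$integer.max - 1L, gMax - 1L)
  series <- thallusSeries(params, gMax, lateral = lateral, seed = NA)
  rows <- lapply(seq_along(series), function(i) {
    ot <- observeThallus(series[[i]], obs, time = i + 1, seed = obsSeeds[i])
    n <- ot@counts
    meanLen <- n[["L_ob"]] / max(1, n[["N_V1ob"]] + n[["N_V3ob"]])
    data.frame(t = n[["t"]], N_V1ob = n[["N_V1ob"]], N_V3ob = n[["N_V3ob"]],
               L = n[["L_ob"]],
               sigma_V1 = sqrt(max(1, n[["N_V1ob"]])),
               sigma_V3 = sqrt(max(1, n[["N_V3ob"]])),
               sigma_L = sqrt(max(1, n[["N_V1ob"]] + n[["N_V3ob"]])) * meanLen,
               N_V3i = n[["N_V3i"]], N_V3o = n[["N_V3o"]],
               crossings = n[["crossings"]], merged = n[["merged"]])
  })
  do.call(rbind, rows)
}
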