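.swc_type <- c(germ = 1L, V3 = 2L, V3l = 3L, V1 = 4L, V1l = 5L)

#' Export a thallus to disk
#'
#' Two interchange formats are supported.  `"swc"` writes the rooted tree
#' as an SWC morphology file (one row per vertex: id, type code, x, y, z=0,
#' radius = half the hyphal width, parent id), with vertices renumbered in
#' breadth-first order so parents precede children; the type codes map the
#' vertex kinds as germ=1, V3=2, V3l=3, V1=4, V1l=5.  `"csv"` writes a
#' CSV pair (`<file>_vertices.csv`, `<file>_segments.csv`) that preserves
#' everything SWC cannot express (branch types, generations, branch ids).
#'
#' @param thallus A [Thallus-class] object.
#' @param file Output path (for `"csv"` the stem of the pair).
#' @param format `"swc"` or `"csv"`.
#' @return The written file path(s), invisibly.
#' @seealso [importThallus()]
#' @export
exportThallus <- function(thallus, file, format = c("swc", "csv")) {
  format <- match.arg(format)
  v <- thallus@vertices; s <- thallus@segments
  if (format == "csv") {
    fv <- paste0(file, "_vertices.csv")
    fs <- paste0(file, "_segments.csv")
    write.csv(v, fv, row.names = FALSE)
    write.csv(s, fs, row.names = FALSE)
    return(invisible(c(fv, fs)))
  }
  parent <- rep(-1L, nrow(v))
  parent[match(s$head, v$id)] <- s$tail
  # breadth-first renumbering so every parent precedes its children
  ord <- integer(0)
  frontier <- v$id[parent == -1L]
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- s$head[s$tail %in% frontier]
  }
  newId <- match(v$id, ord)
  rows <- data.frame(
    id = newId, type = .swc_type[v$kind],
    x = v$x, y = v$y, z = 0,
    radius = thallus@parameters@hyphalWidth / 2,
    parent = ifelse(parent == -1L, -1L, newId[match(parent, v$id)]))
  rows <- rows[order(rows$id), ]
  con <- file(file, "w")
  writeLines("# SWC thallus export: type codes germ=1 V3=2 V3l=3 V1=4 V1l=5",
             con)
  writeLines(sprintf("%d %d %.10g %.10g %g %.6g %d", rows$id, rows$type,
                     rows$x, rows$y, rows$z, rows$radius, rows$parent), con)
  close(con)
  invisible(file)
}

#' Import a thallus from disk
#'
#' Inverse of [exportThallus()].  The CSV pair round-trips exactly
#' (positions to full double precision); the SWC path reconstructs vertex
#' kinds from the type codes and segment lengths from the endpoint
#' distances, and assigns generations by tree depth (exact for purely
#' apical growth).
#'
#' @param file Path written by [exportThallus()] (the stem for `"csv"`).
#' @param format `"swc"` or `"csv"`.
#' @param parameters [GrowthParameters-class] to attach (metadata such as
#'   probability-law parameters are not stored in either format).
#' @return A [Thallus-class] object.
#' @export
importThallus <- function(file, format = c("swc", "csv"),
                          parameters = growthParameters()) {
  format <- match.arg(format)
  if (format == "csv") {
    v <- read.csv(paste0(file, "_vertices.csv"), stringsAsFactors = FALSE)
    s <- read.csv(paste0(file, "_segments.csv"), stringsAsFactors = FALSE)
    g <- max(2, v$birthGen)
    return(new("Thallus", vertices = v, segments = s, generation = g,
               germinationPoint = c(v$x[v$kind == "germ"][1],
                                    v$y[v$kind == "germ"][1]),
               parameters = parameters))
  }
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data rows in SWC file: ", file)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("malformed SWC row at line ", bad[1], " of ", file)
  m <- matrix(as.numeric(unlist(parts)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC file: ", file)
  kinds <- names(.swc_type)[match(m[, 2], .swc_type)]
  if (anyNA(kinds)) stop("unknown SWC type code in ", file)
  v <- data.frame(id = as.integer(m[, 1]), kind = kinds,
                  x = m[, 3], y = m[, 4], birthGen = NA_integer_,
                  dir = NA_real_, stringsAsFactors = FALSE)
  hasParent <- m[, 7] > 0
  tailId <- as.integer(m[hasParent, 7]); headId <- as.integer(m[hasParent, 1])
  x0 <- v$x[match(tailId, v$id)]; y0 <- v$y[match(tailId, v$id)]
  x1 <- v$x[match(headId, v$id)]; y1 <- v$y[match(headId, v$id)]
  s <- data.frame(id = seq_along(tailId), tail = tailId, head = headId,
                  x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                  length = sqrt((x1 - x0)^2 + (y1 - y0)^2),
                  type = NA_character_, generation = NA_integer_,
                  branchId = seq_along(tailId), stringsAsFactors = FALSE)
  # depth-based generations (root depth 1)
  depth <- setNames(rep(NA_integer_, nrow(v)), v$id)
  depth[as.character(v$id[!v$id %in% headId])] <- 1L
  repeat {
    idx <- is.na(depth[as.character(headId)]) &
      !is.na(depth[as.character(tailId)])
    if (!any(idx)) break
    depth[as.character(headId[idx])] <- depth[as.character(tailId[idx])] + 1L
  }
  v$birthGen <- as.integer(depth[as.character(v$id)])
  s$generation <- v$birthGen[match(s$head, v$id)]
  s$type <- ifelse(s$generation <= 2, "germinal", "exploratory")
  v$dir[match(s$head, v$id)] <- atan2(s$y1 - s$y0, s$x1 - s$x0)
  g <- max(2, v$birthGen, na.rm = TRUE)
  new("Thallus", vertices = v, segments = s, generation = g,
      germinationPoint = c(v$x[v$kind == "germ"][1],
                           v$y[v$kind == "germ"][1]),
      parameters = parameters)
}

#' Read and write growth parameters as YAML
#'
#' Configuration keys are the [growthParameters()] argument names; missing
#' keys take the documented defaults.
#'
#' @param file YAML path.
#' @return [readGrowthConfig()]: a [GrowthParameters-class];
#'   [writeGrowthConfig()]: the path, invisibly.
#' @export
readGrowthConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- names(formals(growthParameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(growthParameters, cfg)
}

#' @rdname readGrowthConfig
#' @param params A [GrowthParameters-class] object.
#' @export
writeGrowthConfig <- function(params, file) {
  vals <- lapply(setdiff(slotNames(params), character()), slot, object = params)
  names(vals) <- slotNames(params)
  vals$seed <- if (is.na(params@seed)) NULL else params@seed
  yaml::write_yaml(vals[!vapply(vals, is.null, logical(1))], file)
  invisible(file)
}

#' Generate synthetic fixtures
#'
#' Stand-ins for the undeposited experimental inputs, generated from their
#' published parametric descriptions:
#' \describe{
#'   \item{growth_series}{Base-2 growth curves
#'     \eqn{X_0 2^{(t+t_0)/\tau}} for apex count, 3-degree count and total
#'     length, with Poisson noise on counts and Gaussian noise of s.d.
#'     \eqn{\sigma_L} on length; written as a CSV observation series.}
#'   \item{junction_raster}{A binary Y-junction mask with prescribed arc
#'     angles between its three arms, written as a PNG.}
#'   \item{angle_samples}{A Gaussian mixture of signed angle samples,
#'     written as a CSV.}
#' }
#'
#' @param kind Fixture family.
#' @param spec Named list of parameters.  `growth_series`: `X0` (length-3:
#'   apexes, 3-degree vertices, length), `tau` (length-3, h), `t0` (h),
#'   `t` (time grid, h).  `junction_raster`: `arcs` (length-3, degrees,
#'   summing to 360), `armPx` (arm length), `widthPx`.  `angle_samples`:
#'   `means`, `widths`, `n` (per component, degrees).
#' @param seed RNG seed.
#' @param file Output path (optional; when `NULL` the object is returned
#'   without writing).
#' @return The fixture object (data.frame or `rasterMask`), invisibly when
#'   written.
#' @export
makeFixtures <- function(kind = c("growth_series", "junction_raster",
                                  "angle_samples"),
                         spec = list(), seed = 1, file = NULL) {
  kind <- match.arg(kind)
  if (!is.na(seed)) set.seed(as.integer(seed))
  if (kind == "growth_series") {
    X0 <- spec$X0 %||% c(2.6, 1.4, 0.85)
    tau <- spec$tau %||% c(1.81, 1.42, 1.75)
    t0 <- spec$t0 %||% 1.7
    tt <- spec$t %||% seq(2, 15, by = 0.5)
    mu <- function(i) X0[i] * 2^((tt + t0) / tau[i])
    n1 <- rpois(length(tt), mu(1))
    n3 <- rpois(length(tt), mu(2))
    meanLen <- spec$meanLength %||% 0.2
    sigL <- sqrt(pmax(1, n1 + n3)) * meanLen
    L <- pmax(0.01, rnorm(length(tt), mu(3), sigL))
    out <- data.frame(t = tt, N_V1ob = n1, N_V3ob = n3, L = L,
                      sigma_V1 = sqrt(pmax(1, n1)),
                      sigma_V3 = sqrt(pmax(1, n3)), sigma_L = sigL)
    if (!is.null(file)) {
      write.csv(out, file, row.names = FALSE)
      return(invisible(out))
    }
    return(out)
  }
  if (kind == "junction_raster") {
    arcs <- spec$arcs %||% c(105, 118, 137)
    stopifnot(abs(sum(arcs) - 360) < 1e-6)
    armPx <- spec$armPx %||% 40
    widthPx <- spec$widthPx %||% 5
    dirs <- (cumsum(c(0, arcs[1:2]))) * pi / 180
    n <- 2L * (armPx + widthPx + 6L) + 1L
    ctr <- (n + 1) / 2
    mask <- matrix(FALSE, n, n)
    px <- seq_len(n); halfw <- widthPx / 2
    for (d in dirs) {
      gx <- rep(px, each = n); gy <- rep(px, times = n)
      dd <- .point_segment_dist(gx, gy, ctr, ctr,
                                ctr + armPx * cos(d), ctr + armPx * sin(d))
      hit <- dd <= halfw
      mask[cbind(rep(px, times = n)[hit], rep(px, each = n)[hit])] <- TRUE
    }
    out <- structure(list(mask = mask, pixelSize = 1, origin = c(0, 0),
                          widthPx = widthPx,
                          provenance = sprintf("synthetic junction %s",
                                               paste(arcs, collapse = "/"))),
                     class = "rasterMask")
    if (!is.null(file)) {
      png::writePNG(mask[nrow(mask):1, ] * 1, file)
      return(invisible(out))
    }
    return(out)
  }
  means <- spec$means %||% c(-10, 71)
  widths <- spec$widths %||% c(8.7, 12)
  nper <- spec$n %||% 66
  if (length(nper) == 1) nper <- rep(nper, length(means))
  ang <- unlist(mapply(function(m, w, k) rnorm(k, m, w), means, widths, nper,
                       SIMPLIFY = FALSE))
  out <- data.frame(angle = ang,
                    component = rep(seq_along(means), nper))
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a binary mask from a PNG file
#'
#' @param file PNG path (any nonzero channel value is foreground).
#' @param pixelSize Pixel edge (mm/px) to attach.
#' @return A `rasterMask`.
#' @export
readMaskPNG <- function(file, pixelSize = 1) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- img[nrow(img):1, , drop = FALSE] > 0.5  # PNG rows start at the top
  structure(list(mask = mask, pixelSize = pixelSize, origin = c(0, 0),
                 widthPx = NA, provenance = file),
            class = "rasterMask")
}

#' Write an observation series as CSV
#'
#' @param series data.frame from [observedSeries()] or [makeFixtures()].
#' @param file Output path.
#' @export
writeObservationSeries <- function(series, file) {
  write.csv(series, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeObservationSeries
#' @return A validated observation-series data.frame.
#' @export
readObservationSeries <- function(file) {
  d <- read.csv(file)
  need <- c("t", "N_V1ob", "N_V3ob", "L")
  if (!all(need %in% names(d)))
    stop("observation series must have columns ", paste(need, collapse = ", "))
  if (is.unsorted(d$t, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(d$N_V1ob < 0) || any(d$N_V3ob < 0)) stop("counts must be >= 0")
  d
}
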