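# Exact brute-force crossing oracle on integer coordinates.
# With integer endpoints all products below stay well inside the exactly
# representable double range, so every sign test and rational comparison
# is exact.  Returns one row per properly crossing pair (i < j).
oracleCrossings <- function(x0, y0, x1, y1, tail = seq_along(x0) * 2L - 1L,
                            head = seq_along(x0) * 2L) {
  n <- length(x0)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tail[i] == tail[j] || tail[i] == head[j] ||
        head[i] == tail[j] || head[i] == head[j]) next
    rx <- x1[i] - x0[i]; ry <- y1[i] - y0[i]
    sx <- x1[j] - x0[j]; sy <- y1[j] - y0[j]
    denom <- rx * sy - ry * sx
    qpx <- x0[j] - x0[i]; qpy <- y0[j] - y0[i]
    if (denom == 0) next                      # parallel or collinear
    tn <- qpx * sy - qpy * sx
    un <- qpx * ry - qpy * rx
    # strict 0 < tn/denom < 1 via exact integer comparisons
    inOpen <- function(num, den)
      if (den > 0) num > 0 && num < den else num < 0 && num > den
    if (!inOpen(tn, denom) || !inOpen(un, denom)) next
    t <- tn / denom
    out[[length(out) + 1L]] <- data.frame(
      i = i, j = j, x = x0[i] + t * rx, y = y0[i] + t * ry,
      angle = atan2(abs(denom), abs(rx * sx + ry * sy)) / pi * 180)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(), j = integer(), x = numeric(),
                  y = numeric(), angle = numeric())
}

randomIntSegments <- function(n, lim = 60L) {
  repeat {
    x0 <- sample.int(lim, n, replace = TRUE)
    y0 <- sample.int(lim, n, replace = TRUE)
    x1 <- x0 + sample(c(-15:-1, 1:15), n, replace = TRUE)
    y1 <- y0 + sample(c(-15:-1, 1:15), n, replace = TRUE)
    if (all(x1 != x0 | y1 != y0)) break
  }
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             tail = seq_len(n) * 2L - 1L, head = seq_len(n) * 2L)
}

# minimal hand-built Thallus from vertex/segment tables
mkThallus <- function(v, s, params = growthParameters(), g = 3) {
  v$dir <- if ("dir" %in% names(v)) v$dir else NA_real_
  new("Thallus", vertices = v, segments = s, generation = g,
      germinationPoint = c(0, 0), parameters = params)
}

# H-shaped network with one forced crossing: two long bars and a rung that
# crosses the upper bar only
hThallus <- function() {
  v <- data.frame(
    id = 1:6,
    kind = c("germ", "V1", "V1", "V1", "V1", "V1"),
    x = c(0, 4, 0, 4, 2, 2),
    y = c(0, 0, 2, 2, 1, 3),
    birthGen = c(1L, 2L, 2L, 2L, 2L, 2L),
    dir = NA_real_, stringsAsFactors = FALSE)
  s <- data.frame(
    id = 1:3,
    tail = c(1L, 3L, 5L), head = c(2L, 4L, 6L),
    x0 = c(0, 0, 2), y0 = c(0, 2, 1),
    x1 = c(4, 4, 2), y1 = c(0, 2, 3),
    length = c(4, 4, 2),
    type = "germinal", generation = 2L, branchId = 1:3,
    stringsAsFactors = FALSE)
  mkThallus(v, s)
}

# signed operating/exploratory deviations of every apical branching
signedDeviations <- function(th) {
  s <- th@segments
  segDir <- atan2(s$y1 - s$y0, s$x1 - s$x0)
  motherDir <- segDir[match(s$tail, s$head)]
  ok <- !is.na(motherDir) & s$type %in% c("operating", "exploratory")
  dev <- (segDir[ok] - motherDir[ok]) / pi * 180
  dev <- ((dev + 180) %% 360) - 180
  data.frame(type = s$type[ok], deviation = dev)
}
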