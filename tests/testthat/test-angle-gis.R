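test_that("rasterization draws ribbons of the requested footprint", {
  v <- data.frame(id = 1:2, kind = c("germ", "V1"),
                  x = c(0, 100), y = c(0, 0), birthGen = 1:2,
                  dir = NA_real_, stringsAsFactors = FALSE)
  s <- data.frame(id = 1L, tail = 1L, head = 2L, x0 = 0, y0 = 0,
                  x1 = 100, y1 = 0, length = 100, type = "germinal",
                  generation = 2L, branchId = 1L, stringsAsFactors = FALSE)
  th <- mkThallus(v, s)
  m <- rasterizeThallus(th, pixelSize = 1, widthPx = 7)
  rows <- range(which(rowSums(m$mask) > 0))
  cols <- range(which(colSums(m$mask) > 0))
  expect_lte(abs(diff(cols) + 1 - 107), 1)  # 100 px plus the end caps
  expect_lte(abs(diff(rows) + 1 - 7), 1)

  empty <- mkThallus(v[1, ], s[0, ])
  expect_error(rasterizeThallus(empty, pixelSize = 1), "empty")
})

test_that("skeletonization thins a bar to a line and a Y to a triple point", {
  bar <- matrix(FALSE, 31, 80)
  bar[13:19, 10:70] <- TRUE
  sk <- skeletonizeMask(structure(list(mask = bar, pixelSize = 1,
                                       origin = c(0, 0), widthPx = 7,
                                       provenance = "bar"),
                                  class = "rasterMask"))
  nb <- thallus:::.neighbor_count(sk$mask)
  expect_true(all(colSums(sk$mask)[15:65] == 1))  # 1-px centerline (tips trimmed)
  expect_identical(sum(sk$mask & nb == 1), 2L)       # exactly two endpoints
  expect_identical(sum(sk$mask & nb >= 3), 0L)

  yj <- makeFixtures("junction_raster",
                     list(arcs = c(105, 118, 137), armPx = 40, widthPx = 5))
  sky <- skeletonizeMask(yj, trimErosionPx = 2)
  vt <- detectSkeletonVertices(sky)
  expect_identical(sum(vt$kind == "V1ob"), 3L)
  expect_identical(sum(vt$kind == "V3ob"), 1L)
  expect_identical(vt$degree[vt$kind == "V3ob"], 3L)

  # idempotence: the skeleton of a skeleton is itself
  expect_warning(sk2 <- skeletonizeMask(sk), "thinner")
  expect_identical(sk2$mask, sk$mask)
})

test_that("an X-crossing is dissolved into one flagged multi-arm cluster", {
  m <- matrix(FALSE, 61, 61)
  for (i in 1:61) {
    m[max(1, i - 3):min(61, i + 3), i] <- TRUE
    m[max(1, 62 - i - 3):min(61, 62 - i + 3), i] <- TRUE
  }
  sk <- skeletonizeMask(structure(list(mask = m, pixelSize = 1,
                                       origin = c(0, 0), widthPx = 7,
                                       provenance = "x"),
                                  class = "rasterMask"))
  vt <- detectSkeletonVertices(sk)
  expect_identical(sum(vt$kind == "V1ob"), 4L)
  v3 <- vt[vt$kind == "V3ob", ]
  expect_identical(nrow(v3), 1L)
  expect_identical(v3$degree, 4L)
  expect_identical(v3$flag, "multi-arm")

  spec <- bufferSpectrum(sk, vt, bufferRadiusPx = 8)
  arcs <- spec$angles$angle[spec$angles$vertexId == v3$id]
  expect_identical(length(arcs), 4L)
  expect_true(all(abs(arcs - 90) < 12))
})

test_that("buffer arcs recover drawn junction angles and apex circles", {
  yj <- makeFixtures("junction_raster",
                     list(arcs = c(105, 118, 137), armPx = 40, widthPx = 5))
  sk <- skeletonizeMask(yj, trimErosionPx = 2)
  vt <- detectSkeletonVertices(sk)
  spec <- bufferSpectrum(sk, vt, bufferRadiusPx = 8)
  v3id <- vt$id[vt$kind == "V3ob"]
  arcs <- sort(spec$angles$angle[spec$angles$vertexId == v3id])
  expect_identical(length(arcs), 3L)
  expect_true(all(abs(arcs - c(105, 118, 137)) <= 5))
  expect_equal(sum(arcs), 360, tolerance = 1e-9)
  # apexes away from the border contribute a single full-circle sample
  apex <- spec$angles[spec$angles$kind == "V1ob", ]
  expect_true(all(apex$angle == 360))
})

test_that("constrained three-Gaussian fit recovers mixture means", {
  set.seed(55)
  ang <- c(rnorm(800, 106, 8.4), rnorm(800, 137, 15), rnorm(800, 117, 12))
  spec <- structure(list(angles = data.frame(angle = ang, vertexId = 1L,
                                             kind = "V3ob", flag = "ok"),
                         bufferRadiusPx = 5, minSeparationPx = 10,
                         skipped = integer()),
                    class = "angleSpectrum")
  f <- fitSpectrum(spec, window = c(20, 340), binWidth = 10)
  # with this much overlap the component labels are not identifiable, but
  # the fitted mean triple must match the generating one
  mus <- sort(c(f$mu1, f$mu2, f$mu3))
  expect_true(all(abs(mus - c(106, 117, 137)) < 6))
  expect_equal(f$mu1 + f$mu2 + f$mu3, 360)   # constraint holds exactly
  expect_equal(f$w3, sqrt(f$w1^2 + f$w2^2))

  expect_error(fitSpectrum(structure(list(angles = data.frame(
    angle = rnorm(50, 100, 5), vertexId = 1L, kind = "V3ob", flag = "ok")),
    class = "angleSpectrum")), "at least")
})

test_that("scenario resolution maps arc means to branching angles", {
  r <- resolveScenario(list(mu1 = 106, mu2 = 137, seMu1 = 1, seMu2 = 3))
  expect_equal(r$thetaE, 43)
  expect_equal(r$thetaO, 74)
  expect_true(r$consistent)
  expect_equal(r$seThetaE, 3)

  inv <- resolveScenario(list(mu1 = 170, mu2 = 109, seMu1 = 1, seMu2 = 1))
  expect_equal(inv$thetaE, 10)
  expect_equal(inv$thetaO, 71)

  expect_error(resolveScenario(list(mu1 = 60, mu2 = 137, seMu1 = 1,
                                    seMu2 = 1)), "candidates")
})

test_that("raster pipeline recovers generator angles end to end", {
  # zero-variance run: the two mother arcs appear at 180 - theta
  p0 <- growthParameters(thetaE = 15, thetaO = 80, sigmaE = 0, sigmaO = 0)
  th0 <- simulateThallus(p0, 6, seed = 23)
  mask0 <- rasterizeThallus(th0)
  sk0 <- skeletonizeMask(mask0, trimErosionPx = 2)
  vt0 <- detectSkeletonVertices(sk0)
  sp0 <- bufferSpectrum(sk0, vt0, bufferRadiusPx = 10)
  a0 <- sp0$angles$angle[sp0$angles$kind == "V3ob" & sp0$angles$angle < 360]
  expect_gt(sum(abs(a0 - 165) < 12), 10)
  expect_gt(sum(abs(a0 - 100) < 12), 10)

  # realistic widths: full pipeline within +-8 degrees of the truth
  p <- growthParameters(sigmaE = 6, sigmaO = 6)
  th <- simulateThallus(p, 7, seed = 24)
  res <- measureAnglesGIS(th, binWidth = 10, minSamples = 200)
  expect_lt(abs(res$scenario$thetaE - 10), 8)
  expect_lt(abs(res$scenario$thetaO - 71), 8)
  # skeleton length close to ground truth
  skl <- res$skeleton$mask
  nb <- thallus:::.neighbor_count(skl)
  px <- sum(skl)
  # count 8-neighbour adjacencies once: orthogonal 1, diagonal sqrt(2)
  horiz <- sum(skl[, -1] & skl[, -ncol(skl)])
  vert <- sum(skl[-1, ] & skl[-nrow(skl), ])
  d1 <- sum(skl[-1, -1] & skl[-nrow(skl), -ncol(skl)])
  d2 <- sum(skl[-nrow(skl), -1] & skl[-1, -ncol(skl)])
  lenPx <- horiz + vert + sqrt(2) * (d1 + d2) - sqrt(2) * 0  # rough chain length
  truthPx <- summarizeThallus(th)$totalLength / res$mask$pixelSize
  expect_lt(abs(lenPx / truthPx - 1), 0.08)
})
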