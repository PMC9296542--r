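test_that("circle method reads back constructed daughter angles", {
  # germ -> mother along +x -> V3 at (1,0) with daughters at +71 and -10
  v <- data.frame(
    id = 1:4,
    kind = c("germ", "V3", "V1", "V1"),
    x = c(0, 1, 1 + cos(71 * pi / 180), 1 + cos(-10 * pi / 180)),
    y = c(0, 0, sin(71 * pi / 180), sin(-10 * pi / 180)),
    birthGen = c(1L, 2L, 3L, 3L), dir = NA_real_,
    stringsAsFactors = FALSE)
  s <- data.frame(
    id = 1:3, tail = c(1L, 2L, 2L), head = c(2L, 3L, 4L),
    x0 = c(0, 1, 1), y0 = c(0, 0, 0),
    x1 = v$x[2:4], y1 = v$y[2:4],
    length = 1, type = c("germinal", "operating", "exploratory"),
    generation = c(2L, 3L, 3L), branchId = 1:3,
    stringsAsFactors = FALSE)
  th <- mkThallus(v, s)
  for (R in c(0.1, 0.5, 0.9)) {
    a <- circleAngles(th, vertexIds = 2, radius = R)
    expect_identical(a$flag, "ok")
    expect_equal(a$thetaO, 71, tolerance = 1e-9)
    expect_equal(a$thetaE, -10, tolerance = 1e-9)
  }
  # straight pass-through daughter reads exactly zero
  v2 <- v; v2$x[4] <- 2; v2$y[4] <- 0
  s2 <- s; s2$x1[3] <- 2; s2$y1[3] <- 0
  a0 <- circleAngles(mkThallus(v2, s2), vertexIds = 2, radius = 0.5)
  expect_equal(a0$thetaE, 0, tolerance = 1e-12)
})

test_that("population means of a zero-variance thallus recover the inputs", {
  p <- growthParameters(sigmaE = 0, sigmaO = 0)
  th <- simulateThallus(p, 8, seed = 7)
  a <- circleAngles(th)
  ok <- a[a$flag == "ok" & !is.na(a$thetaO), ]
  # the clean-neighbourhood selection keeps a minority of vertices, as in
  # the manual protocol
  expect_gt(nrow(ok), 10)
  expect_lt(abs(mean(ok$thetaO) - 71), 1)
  expect_lt(abs(abs(mean(ok$thetaE)) - 10), 1)
  # invariance under rigid motion
  th2 <- th
  rot <- pi / 5
  v <- th2@vertices
  xr <- v$x * cos(rot) - v$y * sin(rot) + 3
  yr <- v$x * sin(rot) + v$y * cos(rot) - 1
  th2@vertices$x <- xr; th2@vertices$y <- yr
  th2@segments$x0 <- xr[match(th2@segments$tail, v$id)]
  th2@segments$y0 <- yr[match(th2@segments$tail, v$id)]
  th2@segments$x1 <- xr[match(th2@segments$head, v$id)]
  th2@segments$y1 <- yr[match(th2@segments$head, v$id)]
  a2 <- circleAngles(th2)
  expect_equal(a2$thetaO, a$thetaO, tolerance = 1e-9)
  expect_equal(a2$thetaE, a$thetaE, tolerance = 1e-9)
})

test_that("Gaussian population fit separates and deconvolves the widths", {
  set.seed(30)
  x <- c(rnorm(66, 71, 12), rnorm(66, -10, 8.7))
  f <- fitGaussianPopulations(x, deltaTheta = 4)
  expect_lt(abs(f$wide$mean - 71), 3 * f$wide$uncertainty)
  expect_lt(abs(f$small$mean + 10), 3 * f$small$uncertainty)
  expect_lt(f$wide$width, sqrt(mean((x[1:66] - mean(x[1:66]))^2)))
  expect_identical(f$wide$n, 66L)

  same <- fitGaussianPopulations(c(rep(70, 20), rep(-9, 20)), deltaTheta = 0)
  expect_equal(same$wide$mean, 70)
  expect_equal(same$wide$width, 0)
  expect_error(fitGaussianPopulations(rnorm(30, 50, 2)), "separable")
})

test_that("pooling reproduces the published combination arithmetic", {
  small <- lapply(c(-8.5, -10.2, -9.2), populationEstimate, uncertainty = 4.2)
  ps <- combineEstimates(small, deltaTheta = 4)
  expect_equal(ps$magnitude, 9.3, tolerance = 1e-9)
  expect_equal(ps$statUncertainty, 4.2 / sqrt(3), tolerance = 1e-9)
  expect_equal(round(ps$statUncertainty, 1), 2.4)

  wide <- mapply(populationEstimate, c(72.6, 67.1, 73.2), c(4.1, 4.3, 4.2),
                 SIMPLIFY = FALSE)
  pw <- combineEstimates(wide, deltaTheta = 4)
  expect_identical(pw$meanRounded, 71)
  expect_identical(pw$uncertaintyRounded, 5)
  expect_equal(pw$totalUncertainty,
               sqrt((mean(c(4.1, 4.3, 4.2)) / sqrt(3))^2 + 16),
               tolerance = 1e-9)

  # permutation invariance and the single-estimate identity
  pw2 <- combineEstimates(rev(wide), deltaTheta = 4)
  expect_equal(pw2$mean, pw$mean)
  one <- combineEstimates(wide[2], deltaTheta = 4)
  expect_equal(one$mean, 67.1)
  expect_error(combineEstimates(list()), "empty")
})

test_that("end-to-end circle measurement recovers the generator angles", {
  p <- growthParameters()   # thetaE 10, thetaO 71, measured sigmas
  set.seed(40)
  hits <- vapply(1:30, function(i) {
    ests <- lapply(1:3, function(k) {
      # one experiment pools the clean vertices of two fields of view
      a <- do.call(rbind, lapply(1:2, function(f)
        circleAngles(simulateThallus(p, 8, seed = 10000 * i + 10 * k + f))))
      a <- a[a$flag == "ok" & !is.na(a$thetaO), ]
      idx <- seq_len(min(66, nrow(a)))
      fitGaussianPopulations(c(a$thetaO[idx], a$thetaE[idx]), deltaTheta = 4)
    })
    pw <- combineEstimates(lapply(ests, `[[`, "wide"), deltaTheta = 4)
    ps <- combineEstimates(lapply(ests, `[[`, "small"), deltaTheta = 4)
    abs(pw$magnitude - 71) <= pw$totalUncertainty &&
      abs(ps$magnitude - 10) <= ps$totalUncertainty
  }, logical(1))
  expect_gte(sum(hits), 27)
})
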