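test_that("branch lengths follow the Gamma law and its special cases", {
  set.seed(5)
  p1 <- growthParameters(gammaShape = 1, gammaScale = 0.3)
  x <- sampleBranchLength(p1, 1e4)
  expect_true(all(x > 0))
  # k = 1 is the exponential law
  ks <- suppressWarnings(stats::ks.test(x, stats::pexp, rate = 1 / 0.3))
  expect_gt(ks$p.value, 1e-3)

  # sample mean close to k * theta
  p2 <- growthParameters(gammaShape = 3, gammaScale = 0.1)
  y <- sampleBranchLength(p2, 1e5)
  se <- sqrt(3) * 0.1 / sqrt(1e5)
  expect_lt(abs(mean(y) - 0.3), 3 * se)

  # k = 3/2, theta = 2 a^2 is the Maxwell-Boltzmann law: sqrt(draws) follow
  # the MB speed density, checked against its numerically integrated cdf
  a <- 0.5
  p3 <- growthParameters(gammaShape = 1.5, gammaScale = 2 * a^2)
  v <- sqrt(sampleBranchLength(p3, 1e4))
  mbCdf <- function(q) vapply(q, function(z)
    stats::integrate(function(u) sqrt(2 / pi) * u^2 / a^3 *
                       exp(-u^2 / (2 * a^2)), 0, z)$value, numeric(1))
  ks2 <- suppressWarnings(stats::ks.test(v, mbCdf))
  expect_gt(ks2$p.value, 1e-3)
})

test_that("lateral branching probability follows the power law", {
  p <- growthParameters(lateralP0 = 0.5, lateralAlpha = 2, lateralX0 = 1)
  expect_equal(lateralProbability(1, p), 0.5)
  expect_equal(lateralProbability(0, p), 0)
  expect_equal(lateralProbability(0.5, p), 0.125)
  expect_warning(res <- lateralProbability(2, p), "clamped")
  expect_equal(res, 0.5)
  expect_error(lateralProbability(-1, p))
})

test_that("apical branching places daughters per the side convention", {
  p <- growthParameters(thetaE = 10, thetaO = 71, sigmaE = 0, sigmaO = 0)
  set.seed(2)
  d <- apicalBranch(0, p)
  expect_setequal(round(d$signedAngle, 9), c(71, -10) * sign(d$signedAngle[1]))
  # same-side convention keeps one rotation sense
  p2 <- growthParameters(thetaE = 15, thetaO = 80, sigmaE = 0, sigmaO = 0,
                         apicalSameSide = TRUE)
  d2 <- apicalBranch(0, p2)
  expect_equal(sign(d2$signedAngle[1]), sign(d2$signedAngle[2]))

  # chirality Bernoulli is balanced
  set.seed(3)
  sides <- replicate(2000, sign(apicalBranch(0, p)$signedAngle[1]))
  frac <- mean(sides > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))

  # collinear daughters when both angle means and variances vanish
  p0 <- growthParameters(thetaE = 0, thetaO = 0, sigmaE = 0, sigmaO = 0)
  d0 <- apicalBranch(0.7, p0)
  expect_equal(d0$direction, c(0.7, 0.7))
})

test_that("simulation satisfies the binary-tree counts and determinism", {
  p <- growthParameters()
  for (sd in c(1, 2)) for (g in c(2, 5, 9)) {
    s <- summarizeThallus(simulateThallus(p, g, lateral = (sd == 2),
                                          seed = sd))
    expect_identical(s$nV1, as.integer(3 * 2^(g - 2)))
  }
  a <- simulateThallus(p, 7, lateral = TRUE, seed = 99)
  b <- simulateThallus(p, 7, lateral = TRUE, seed = 99)
  expect_identical(a@vertices, b@vertices)
  expect_identical(a@segments, b@segments)

  off <- simulateThallus(growthParameters(lateralP0 = 0), 7, lateral = TRUE,
                         seed = 1)
  s0 <- summarizeThallus(off)
  expect_identical(s0$nV1l, 0L)
  expect_identical(s0$nV3l, 0L)

  expect_error(simulateThallus(p, 1), "generations")
})

test_that("lateral branching respects the censorship zone and its rate", {
  p <- growthParameters(censorshipFraction = 0.2, lateralP0 = 1,
                        lateralAlpha = 0, seed = NA)
  # single fixed host segment of the germination state, branched repeatedly
  set.seed(8)
  u <- replicate(400, {
    st <- thallus:::.germinate(growthParameters(nGerm = 1L), fixedLength = 1)
    st2 <- thallus:::.lateral_pass(st, p, gg = 3)
    v3l <- st2$v[st2$v$kind == "V3l", ]
    if (nrow(v3l)) sqrt(v3l$x^2 + v3l$y^2) else NA_real_
  })
  u <- u[!is.na(u)]
  expect_gt(length(u), 350)   # p0 = 1, alpha = 0 branches almost every pass
  expect_true(all(u >= 0.2 - 1e-12 & u <= 0.8 + 1e-12))
  expect_gt(max(u), 0.7)      # placement spans the allowed range
  expect_lt(min(u), 0.3)

  # Monte-Carlo rate matches lateralProbability of the host length
  p2 <- growthParameters(lateralP0 = 0.4, lateralAlpha = 2)
  len <- 0.15
  pExp <- lateralProbability(len, p2)
  set.seed(9)
  hits <- replicate(2000, {
    st <- thallus:::.germinate(growthParameters(nGerm = 1L),
                               fixedLength = len)
    st2 <- thallus:::.lateral_pass(st, p2, gg = 3)
    sum(st2$v$kind == "V3l")
  })
  expect_lt(abs(mean(hits) - pExp),
            3 * sqrt(pExp * (1 - pExp) / 2000))
})

test_that("balanced chirality gives a mirror-symmetric angle ensemble", {
  p <- growthParameters(seed = NA)
  set.seed(21)
  d1 <- signedDeviations(simulateThallus(p, 8, seed = 31))
  d2 <- signedDeviations(simulateThallus(p, 8, seed = 32))
  ks <- suppressWarnings(
    stats::ks.test(d1$deviation[d1$type == "operating"],
                   -d2$deviation[d2$type == "operating"]))
  expect_gt(ks$p.value, 1e-3)
})

test_that("thallusSeries reproduces the simulateThallus growth path", {
  p <- growthParameters()
  ser <- thallusSeries(p, 6, lateral = TRUE, seed = 5)
  expect_length(ser, 5)
  final <- simulateThallus(p, 6, lateral = TRUE, seed = 5)
  expect_identical(ser[["6"]]@segments, final@segments)
  expect_identical(vapply(ser, function(t) t@generation, numeric(1)),
                   c("2" = 2, "3" = 3, "4" = 4, "5" = 5, "6" = 6))
})
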