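test_that("base-2 fit recovers noiseless parameters exactly", {
  t <- 2:15
  s <- data.frame(t = t, N_V1ob = 3 * 2^((t + 1.7) / 1.8))
  f <- fitBase2Growth(s, "N_V1ob", t0 = 1.7)
  expect_equal(f$X0, 3, tolerance = 1e-6)
  expect_equal(f$tau, 1.8, tolerance = 1e-6)
  expect_lt(f$chi2, 1e-10)
})

test_that("fitted doubling time covers the truth on Poisson-noised series", {
  t <- seq(2, 15, by = 0.5)
  mu <- 3 * 2^((t + 1.7) / 1.8)
  set.seed(14)
  hits <- vapply(1:100, function(i) {
    s <- data.frame(t = t, N_V1ob = rpois(length(t), mu))
    f <- tryCatch(fitBase2Growth(s, "N_V1ob", t0 = 1.7),
                  error = function(e) NULL)
    if (is.null(f)) return(FALSE)
    abs(f$tau - 1.8) <= qnorm(0.975) * f$seTau
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("the saturating law reduces to the binary-tree law while c >> b", {
  t <- seq(2, 10, by = 0.5)
  a <- 1 / 1.8; b <- 1e-5; cc <- 0.3
  x <- 1 / (b + cc * 2^(-a * t))
  s <- data.frame(t = t, N_V1ob = x, sigma_V1 = 0.01 * x)
  fp <- fitBase2Growth(s, "N_V1ob", t0 = 0, range = c(2, 10))
  pure <- fp$X0 * 2^(t / fp$tau)
  expect_true(all(abs(pure / x - 1) < 0.01))

  fs <- fitBase2Growth(s, "N_V1ob", t0 = 0, range = c(2, 10),
                       model = "saturating")
  expect_equal(fs$a, a, tolerance = 1e-3)
  expect_equal(fs$c, cc, tolerance = 1e-2)
})

test_that("polynomial-corrected law fits the 3-degree count form", {
  t <- seq(2, 12, by = 0.5)
  x <- 2^((t + 1) / 1.5) * (0.8 + 0.12 * t)
  s <- data.frame(t = t, N_V3ob = x, sigma_V3 = sqrt(x))
  f <- fitBase2Growth(s, "N_V3ob", t0 = 1, range = c(2, 12),
                      model = "v3_polynomial")
  expect_equal(f$tau, 1.5, tolerance = 1e-4)
  expect_equal(f$c1, 0.12, tolerance = 1e-3)
})

test_that("time-scale map equates the fitted growth laws", {
  t <- 2:15
  s <- data.frame(t = t, N_V1ob = 3 * 2^((t + 1.7) / 1.8))
  f <- fitBase2Growth(s, "N_V1ob", t0 = 1.7)
  m0 <- timeScaleMap(f, f)
  expect_equal(m0$slope, 1)
  expect_equal(m0$offset, 0)

  g <- 2:9
  sim <- data.frame(t = g, N_V1ob = 3 * 2^(g - 2))
  fs <- fitBase2Growth(sim, "N_V1ob", t0 = 0, range = c(2, 9))
  m <- timeScaleMap(f, fs)
  expect_equal(m$slope, fs$tau / 1.8, tolerance = 1e-6)
  # round trip: the mapped simulation curve reproduces the data curve
  A <- function(ff) ff$X0 * 2^(ff$t0 / ff$tau)
  tt <- seq(3, 12, by = 0.5)
  dataCurve <- A(f) * 2^(tt / f$tau)
  simCurve <- A(fs) * 2^((m$slope * tt + m$offset) / fs$tau)
  expect_equal(simCurve, dataCurve, tolerance = 1e-9)
  expect_error(timeScaleMap(f, list(tau = -1)), "base2Fit")
})

test_that("length-per-apex ratio matches the binary-tree closed form", {
  p <- growthParameters()
  th <- simulateThallus(p, 9, seed = 2)
  s <- summarizeThallus(th)
  r <- lengthRatios(th)
  expect_equal(r$r1 / s$meanBranchLength, 2 - 2^(2 - 9), tolerance = 1e-12)
  g2 <- simulateThallus(p, 2, seed = 3)
  r2 <- lengthRatios(g2)
  expect_equal(r2$r1, summarizeThallus(g2)$meanBranchLength)

  # lateral branching: plateau at 2 <l> (1 + p) / (1 + 2 p)
  for (g in c(8, 9, 10)) {
    th <- simulateThallus(p, g, lateral = TRUE, seed = g)
    s <- summarizeThallus(th)
    r <- lengthRatios(th)
    expected <- expectedLengthRatio(g, s$pLateral, s$meanBranchLength)
    expect_lt(abs(r$r1 / expected - 1), 0.05)
  }
})

test_that("inertia tensor, sphericity and principal axis are correct", {
  hand <- inertiaSphericity(rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2)))
  expect_equal(hand$eigenvalues, c(8, 2))
  expect_equal(hand$sphericity, 0.4)
  expect_equal(abs(hand$axisAngle), 90)

  line <- inertiaSphericity(cbind(1:10, 2 * (1:10) + 3))
  expect_equal(line$sphericity, 0, tolerance = 1e-12)
  expect_equal(line$axisAngle, atan(2) / pi * 180, tolerance = 1e-9)

  set.seed(6)
  r <- sqrt(runif(1e4)); a <- runif(1e4, 0, 2 * pi)
  disk <- inertiaSphericity(cbind(r * cos(a), r * sin(a)))
  expect_gt(disk$sphericity, 0.95)
  expect_lte(disk$sphericity, 1)

  expect_error(inertiaSphericity(rbind(c(1, 1), c(1, 1), c(1, 1))),
               "coincident")
})

test_that("apex-cloud sphericity is stationary in the developed regime", {
  p <- growthParameters()
  slopes <- vapply(c(17, 3, 8), function(sd) {
    ser <- thallusSeries(p, 10, seed = sd)
    s <- vapply(ser[as.character(6:10)], function(th) {
      v <- th@vertices
      inertiaSphericity(cbind(v$x, v$y)[v$kind == "V1", ])$sphericity
    }, numeric(1))
    expect_true(all(s > 0.5 & s <= 1))   # stays disk-like, never elongates
    unname(coef(lm(s ~ seq_along(s)))[2])
  }, numeric(1))
  # per-generation drift is small and inconsistent in sign across seeds
  expect_lt(abs(mean(slopes)), 0.03)

  # principal axis is stable between consecutive developed generations
  ser <- thallusSeries(p, 9, seed = 17)
  ax <- vapply(ser[as.character(8:9)], function(th) {
    v <- th@vertices
    inertiaSphericity(cbind(v$x, v$y)[v$kind == "V1", ])$axisAngle
  }, numeric(1))
  drift <- abs(diff(ax)) %% 180
  expect_lt(min(drift, 180 - drift), 40)
})

test_that("bootstrap interval behaves like the CLT on a Gaussian mean", {
  set.seed(10)
  x <- rnorm(1000)
  b <- bootstrapCI(x, mean, B = 500, seed = 1)
  expect_equal(b$estimate, mean(x))
  expect_lt(abs(diff(b$ci) - 2 / sqrt(1000)), 0.4 * 2 / sqrt(1000))
  b2 <- bootstrapCI(x, mean, B = 500, seed = 1)
  expect_identical(b$ci, b2$ci)

  same <- bootstrapCI(rep(3.3, 150), mean, B = 100, seed = 2)
  expect_equal(diff(same$ci), 0)
  expect_equal(same$se, 0)
})
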