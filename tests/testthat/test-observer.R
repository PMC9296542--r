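nullObs <- observationParameters(resolutionSigma = 0, mergeDistance = 0,
                                 ghostRate = 0, fuseProb = 0)

test_that("observation with null artifact parameters is the identity on counts", {
  th <- simulateThallus(growthParameters(), 7, lateral = TRUE, seed = 3)
  s <- summarizeThallus(th)
  ot <- observeThallus(th, nullObs, seed = 1)
  n <- ot@counts
  expect_equal(n[["N_V1ob"]], s$nV1 + s$nV1l)
  expect_equal(n[["merged"]], 0)
  expect_equal(n[["N_V3o"]], 0)
  expect_equal(n[["N_V1g"]] + n[["N_V3g"]], 0)
  expect_equal(n[["L_ob"]], s$totalLength)
  # 3-degree observed count = true branchings + two per pure crossing
  expect_equal(n[["N_V3ob"]], s$nV3 + s$nV3l + 2 * n[["crossings"]])
})

test_that("a hand-built H network yields exactly one crossing record", {
  th <- hThallus()
  cr <- detectGeometricVertices(th)
  expect_identical(nrow(cr), 1L)
  expect_equal(c(cr$x, cr$y), c(2, 2))
  expect_equal(cr$angle, 90)
  ot <- observeThallus(th, nullObs, seed = 1)
  expect_equal(ot@counts[["N_V3i"]], 1)
})

test_that("crossing records match the brute-force oracle on a grown thallus", {
  th <- simulateThallus(growthParameters(), 8, seed = 12)
  s <- th@segments
  sc <- 1e6  # scale to integers: positions are O(1) mm with ~1e-9 tolerance
  got <- detectGeometricVertices(th)
  want <- oracleCrossings(round(s$x0 * sc), round(s$y0 * sc),
                          round(s$x1 * sc), round(s$y1 * sc),
                          as.integer(s$tail), as.integer(s$head))
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$segA[order(got$segA, got$segB)],
               want$i[order(want$i, want$j)])
})

test_that("apex-branch merges are counted as geometric vertices", {
  th <- hThallus()
  # apex 6 at (2,3): a merge window large enough to swallow every apex
  big <- observationParameters(resolutionSigma = 0, mergeDistance = 10)
  ot <- observeThallus(th, big, seed = 1)
  expect_equal(ot@counts[["N_V1ob"]], 0)
  expect_equal(ot@counts[["merged"]], 5)
  expect_equal(ot@counts[["N_V3i"]], 1 + 5)

  # invariant: N_V3i = crossings + merged, for several seeds
  p <- growthParameters()
  obs <- observationParameters(resolutionSigma = 0.002, mergeDistance = 0.01)
  for (sd in c(2, 6)) {
    ot <- observeThallus(simulateThallus(p, 7, lateral = TRUE, seed = sd),
                         obs, seed = sd)
    n <- ot@counts
    expect_equal(n[["N_V3i"]], n[["crossings"]] + n[["merged"]])
  }
})

test_that("fusion bookkeeping matches the Bernoulli expectation", {
  th <- simulateThallus(growthParameters(), 7, seed = 4)
  nCross <- nrow(detectGeometricVertices(th))
  expect_gt(nCross, 20)
  obs <- observationParameters(resolutionSigma = 0, mergeDistance = 0,
                               fuseProb = 0.3)
  fused <- vapply(1:150, function(sd)
    observeThallus(th, obs, seed = sd)@counts[["N_V3o"]], numeric(1))
  expect_true(all(fused <= nCross))
  se <- sqrt(nCross * 0.3 * 0.7 / 150)
  expect_lt(abs(mean(fused) - 0.3 * nCross), 3 * se)
})

test_that("ghost vertices are Poisson and split between kinds", {
  th <- simulateThallus(growthParameters(), 5, seed = 4)
  obs <- observationParameters(resolutionSigma = 0, mergeDistance = 0,
                               ghostRate = 6)
  n <- vapply(1:200, function(sd) {
    ct <- observeThallus(th, obs, seed = sd)@counts
    c(ct[["N_V1g"]] + ct[["N_V3g"]], ct[["N_V1g"]])
  }, numeric(2))
  expect_lt(abs(mean(n[1, ]) - 6), 3 * sqrt(6 / 200))
  expect_lt(abs(mean(n[2, ]) / mean(n[1, ]) - 0.5), 0.1)
})

test_that("observed series doubles per generation and is reproducible", {
  p <- growthParameters()
  ser <- observedSeries(p, nullObs, gMax = 9, lateral = FALSE, seed = 5)
  fit <- lm(log2(N_V1ob) ~ t, data = ser)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-12)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)

  ser2 <- observedSeries(p, nullObs, gMax = 9, lateral = FALSE, seed = 5)
  expect_identical(ser, ser2)

  # lateral branching raises the amplitude, not the doubling rate
  serL <- observedSeries(p, nullObs, gMax = 9, lateral = TRUE, seed = 5)
  fitL <- lm(log2(N_V1ob) ~ t, data = serL[serL$t >= 4, ])
  expect_lt(abs(coef(fitL)[2] - 1), 0.1)
  ampRatio <- serL$N_V1ob[serL$t == 9] / ser$N_V1ob[ser$t == 9]
  pl <- serL$N_V1ob[serL$t == 9] / ser$N_V1ob[ser$t == 9] - 1
  expect_gt(ampRatio, 1)
  expect_lt(ampRatio, 2)

  # crossing density grows with the network
  obs2 <- observationParameters(resolutionSigma = 0, mergeDistance = 0)
  serC <- observedSeries(p, obs2, gMax = 9, lateral = FALSE, seed = 6)
  ratio <- serC$N_V3ob / serC$N_V1ob
  expect_gt(ratio[length(ratio)], ratio[2])
})
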