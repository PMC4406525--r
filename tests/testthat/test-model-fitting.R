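test_that("subsampled discovery curves match hypergeometric expectations", {
  s <- ObservedSample(c(a = 3, b = 2, c = 1))
  # full sample: all categories, no randomness
  full <- empiricalDiscoveryCurve(s, grid = 6, reps = 2, seed = 1)
  expect_equal(curvePoints(full)$uObs, 3)
  # one draw: always one category
  one <- empiricalDiscoveryCurve(s, grid = 1, reps = 50, seed = 1)
  expect_equal(curvePoints(one)$uObs, 1)
  # two draws: exact expectation sum_j 1 - C(6-y_j,2)/C(6,2) = 26/15
  two <- empiricalDiscoveryCurve(s, grid = 2, reps = 4000, seed = 2)
  expect_equal(curvePoints(two)$uObs, 26 / 15, tolerance = 0.03)
  # determinism and error paths
  c1 <- empiricalDiscoveryCurve(s, grid = c(2, 4), reps = 3, seed = 9)
  c2 <- empiricalDiscoveryCurve(s, grid = c(2, 4), reps = 3, seed = 9)
  expect_identical(curvePoints(c1), curvePoints(c2))
  expect_error(empiricalDiscoveryCurve(s, grid = 10), "total draws")
})

test_that("fit cost is the log-weighted squared log residual", {
  m <- canonicalModel()
  r <- round(10^seq(2, 5, length.out = 8))
  exact <- DiscoveryCurve(r, expectedUnique(m, r))
  expect_lt(fitCost(c(1.5, 1e-6, 1e-2), exact), 1e-12)
  # doubling observations strictly increases the cost at the true params
  doubled <- DiscoveryCurve(r, 2 * expectedUnique(m, r))
  expect_gt(fitCost(c(1.5, 1e-6, 1e-2), doubled), 0.1)
  # two-point hand computation
  hand <- DiscoveryCurve(c(1e3, 1e4), c(400, 3000))
  u <- expectedUnique(m, c(1e3, 1e4))
  expect_equal(fitCost(c(1.5, 1e-6, 1e-2), hand),
               sum((log(u) - log(c(400, 3000)))^2 * log(c(400, 3000))),
               tolerance = 1e-12)
  # points below 2 observed categories carry no weight
  low <- DiscoveryCurve(c(1, 2, 1e3, 1e4), c(1, 1.5, 400, 3000))
  expect_equal(fitCost(c(1.5, 1e-6, 1e-2), low),
               fitCost(c(1.5, 1e-6, 1e-2), hand), tolerance = 1e-12)
  expect_error(fitCost(c(1.5, 1e-6, 1e-2),
                       DiscoveryCurve(c(1, 2), c(1, 1.9))), ">= 2")
})

test_that("noiseless curves are inverted to the generating parameters", {
  n <- 1e6
  m <- TruncatedPowerLaw(1.5, 1 / n, xmaxUpperBound(1.5, n), nTotal = n)
  r <- round(10^seq(2, 5, length.out = 20))
  curve <- DiscoveryCurve(r, expectedUnique(m, r), freqMin = 1 / n,
                          freqMax = m@xMax, alphaGuess = 1.8)
  fit <- fitModel(curve, n)
  expect_true(fit@converged)
  expect_equal(alphaHat(fit), 1.5, tolerance = 1e-3)
  expect_equal(fit@xMinHat, m@xMin, tolerance = 0.02)
  expect_equal(fit@xMaxHat, m@xMax, tolerance = 0.01)
  expect_equal(fit@hHat, totalUnique(m), tolerance = 0.01)
  expect_lt(fit@cost, 1e-6)
})

test_that("parameters are recovered from simulated registry samples", {
  # 10% sampling depth of a feasibility-bounded population
  pop <- generatePopulation(1.5, 1e6, seed = 7)
  h <- populationSize(pop)
  alphas <- numeric(3); hs <- numeric(3)
  for (sd in 1:3) {
    s <- drawSample(pop, 1e5, seed = sd)
    fit <- fitModel(empiricalDiscoveryCurve(s, seed = sd + 50), 1e6)
    expect_true(fit@converged)
    alphas[sd] <- alphaHat(fit); hs[sd] <- fit@hHat
  }
  expect_lt(mean(abs(alphas - 1.5)), 0.1)
  expect_lt(mean(abs(hs - h) / h), 0.15)
})

test_that("fits are stable between 10% and 50% sampling depth", {
  pop <- generatePopulation(1.5, 1e6, seed = 8)
  f10 <- fitModel(empiricalDiscoveryCurve(drawSample(pop, 1e5, seed = 1),
                                          seed = 2), 1e6)
  f50 <- fitModel(empiricalDiscoveryCurve(drawSample(pop, 5e5, seed = 3),
                                          seed = 4), 1e6)
  expect_lt(abs(alphaHat(f10) - alphaHat(f50)), 0.05)
})

test_that("extrapolation exposes both realized and asymptotic richness", {
  n <- 1e6
  m <- TruncatedPowerLaw(1.5, 1 / n, xmaxUpperBound(1.5, n), nTotal = n)
  r <- round(10^seq(2, 5, length.out = 20))
  fit <- fitModel(DiscoveryCurve(r, expectedUnique(m, r), freqMin = 1 / n,
                                 freqMax = m@xMax, alphaGuess = 1.8), n)
  proj <- extrapolate(fit, c(n, 1e3 / fit@xMinHat))
  expect_named(proj, c("r", "uTarget", "coverage", "probUnseen", "hHat"))
  # U at the deep-sampling proxy approaches the asymptotic richness
  expect_equal(proj$uTarget[2], fit@hHat, tolerance = 1e-3)
  # realized richness at nTotal stays below the asymptote
  expect_lt(proj$uTarget[1], fit@hHat)
  expect_equal(proj$coverage[1] + proj$probUnseen[1], 1, tolerance = 1e-15)
  # inverse query is self-inverse to 0.5%
  r0 <- 2e5
  cov0 <- fractionCovered(fit, r0)
  expect_equal(sampleSizeForCoverage(fit, cov0), r0, tolerance = 0.005)
  # unreachable coverage errors out (only testable when the deep-sampling
  # cap itself leaves residual unseen mass)
  covMax <- fractionCovered(fit, 1e3 / fit@xMinHat)
  if (covMax < 1)
    expect_error(sampleSizeForCoverage(fit, (1 + covMax) / 2),
                 "not reachable")
  bad <- fit; bad@converged <- FALSE
  expect_error(extrapolate(bad, n), "converge")
})

test_that("projection at the full population matches the realized count", {
  pop <- generatePopulation(1.5, 1e6, seed = 9)
  s <- drawSample(pop, 1e5, seed = 1)
  fit <- fitModel(empiricalDiscoveryCurve(s, seed = 2), 1e6)
  realized <- nUnique(drawSample(pop, 1e6, seed = 3))
  proj <- extrapolate(fit, 1e6)
  expect_equal(proj$uTarget, realized, tolerance = 0.05)
})
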