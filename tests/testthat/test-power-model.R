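# grid of valid exponents spanning both regimes, avoiding the guarded
# singular values
.alphaGrid <- c(0.25, 0.5, 0.9, 1.1, 1.5, 1.8, 1.94)

test_that("model validity rejects degenerate and singular parameters", {
  expect_error(TruncatedPowerLaw(1.5, 1e-2, 1e-2), "xMin < xMax")
  expect_error(TruncatedPowerLaw(1.5, 1e-2, 1e-6), "xMin < xMax")
  expect_error(TruncatedPowerLaw(1.0, 1e-6, 1e-2), "guard")
  expect_error(TruncatedPowerLaw(1.0005, 1e-6, 1e-2), "guard")
  expect_error(TruncatedPowerLaw(2.0, 1e-6, 1e-2), "singular exponent 2")
  expect_error(TruncatedPowerLaw(2.5, 1e-6, 1e-2), "singular exponent 2")
  expect_error(TruncatedPowerLaw(1.5, 1e-8, 1e-2, nTotal = 1e6), "1/nTotal")
  expect_silent(TruncatedPowerLaw(1.5, 1e-6, 1e-2, nTotal = 1e6))
})

test_that("normalization constant matches the quadrature oracle", {
  m <- canonicalModel()
  expect_equal(normalizationConstant(m), quadNormConst(1.5, 1e-6, 1e-2),
               tolerance = 1e-9)
  expect_equal(normalizationConstant(m), 5.0505, tolerance = 1e-4)
  set.seed(3)
  for (a in .alphaGrid) {
    xmin <- 10^stats::runif(1, -7, -3)
    xmax <- xmin * 10^stats::runif(1, 1, 3)
    m <- TruncatedPowerLaw(a, xmin, xmax)
    # defining identity: unit probability mass
    mass <- stats::integrate(function(x) x * countDensity(m, x),
                             xmin, xmax, rel.tol = 1e-12)$value
    expect_equal(mass, 1, tolerance = 1e-9)
  }
})

test_that("count density has the power-law form and integrates to H", {
  m <- canonicalModel()
  A <- quadNormConst(1.5, 1e-6, 1e-2)
  expect_equal(countDensity(m, 1e-4), A * (1e-4)^(-1.5), tolerance = 1e-9)
  expect_equal(countDensity(m, 1e-4), 5.0505e6, tolerance = 1e-4)
  # endpoint ratio fixed by the exponent
  expect_equal(countDensity(m, m@xMin) / countDensity(m, m@xMax),
               (m@xMax / m@xMin)^1.5, tolerance = 1e-10)
  expect_error(countDensity(m, 0.5), "support")
  set.seed(4)
  for (a in .alphaGrid) {
    xmin <- 10^stats::runif(1, -7, -3)
    xmax <- xmin * 10^stats::runif(1, 1, 3)
    m <- TruncatedPowerLaw(a, xmin, xmax)
    hQuad <- stats::integrate(function(x) countDensity(m, x), xmin, xmax,
                              rel.tol = 1e-12)$value
    expect_equal(totalUnique(m), hQuad, tolerance = 1e-9)
  }
})

test_that("exceedance runs from H down to zero with the right derivative", {
  m <- canonicalModel()
  expect_equal(exceedance(m, m@xMin), totalUnique(m), tolerance = 1e-10)
  expect_equal(exceedance(m, m@xMax), 0, tolerance = 1e-8)
  x <- 10^seq(-6, -2, length.out = 30)
  expect_true(all(diff(exceedance(m, x)) < 0))
  # differential identity: v(x) - v(x (1+eps)) ~ mu(x) x eps
  eps <- 1e-6
  for (x0 in c(1e-5, 1e-4, 1e-3)) {
    expect_equal(exceedance(m, x0) - exceedance(m, x0 * (1 + eps)),
                 countDensity(m, x0) * x0 * eps, tolerance = 1e-4)
  }
})

test_that("total richness matches quadrature in both exponent regimes", {
  expect_equal(totalUnique(canonicalModel()), 10000, tolerance = 1e-9)
  # sub-unit exponent (allele regime)
  m <- TruncatedPowerLaw(0.5, 1e-6, 1e-2)
  expect_equal(totalUnique(m), quadTotalUnique(0.5, 1e-6, 1e-2),
               tolerance = 1e-6)
})

test_that("quantile inverts the analytic CDF exactly", {
  m <- canonicalModel()
  expect_identical(quantile(m, 0), m@xMin)
  expect_identical(quantile(m, 1), m@xMax)
  u <- seq(0.01, 0.99, length.out = 25)
  expect_true(all(diff(quantile(m, u)) > 0))
  expect_equal(freqCDF(m, quantile(m, u)), u, tolerance = 1e-10)
  # bisection oracle at the median
  f <- function(x) freqCDF(m, x) - 0.5
  med <- stats::uniroot(f, c(m@xMin, m@xMax), tol = 1e-16)$root
  expect_equal(quantile(m, 0.5), med, tolerance = 1e-9)
  expect_error(quantile(m, 1.5), "\\[0, 1\\]")
})

test_that("xmaxUpperBound solves the one-category-at-the-top condition", {
  # independent bisection on the absolute-count-scale equation
  a <- 1.5; n <- 1e6
  f <- function(u) u^2 * (1 - u^(a - 2)) - (2 - a) * n
  uRoot <- stats::uniroot(f, c(2, n), tol = 1e-10)$root
  b <- xmaxUpperBound(a, n)
  expect_equal(b, uRoot / n, tolerance = 1e-8)
  expect_equal(b, 7.2e-4, tolerance = 0.01)
  # defining condition: density mass in the top 1/n bin equals one category
  m <- TruncatedPowerLaw(a, 1 / n, b, nTotal = n)
  expect_equal(countDensity(m, b) / n, 1, tolerance = 1e-6)
  # continuity in alpha up to the guard
  bs <- vapply(c(1.5, 1.7, 1.9, 1.99 - 0.05, 1.949), xmaxUpperBound,
               numeric(1), nTotal = n)
  expect_true(all(diff(bs) < 0))
  expect_true(all(is.finite(bs)))
  # infeasible pair errors
  expect_error(xmaxUpperBound(0.21, 2), "feasible")
})

test_that("sampleFrequencies materializes round(H) normalized draws", {
  m <- canonicalModel()
  pop <- sampleFrequencies(m, seed = 5)
  p <- probabilities(pop)
  expect_length(p, 10000)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  # reproducibility
  expect_identical(p, probabilities(sampleFrequencies(m, seed = 5)))
  expect_false(identical(p, probabilities(sampleFrequencies(m, seed = 6))))
})

test_that("inverse-CDF draws follow the analytic frequency law", {
  # the distributional check runs on the raw quantile transform: the
  # final sum-normalization rescales every draw by the same factor
  # (1 plus a few percent of heavy-tail noise), which shifts the whole
  # empirical CDF and would mask genuine distributional errors
  m <- canonicalModel()
  set.seed(12)
  q <- quantile(m, stats::runif(10000))
  d <- max(abs(freqCDF(m, sort(q)) - seq_along(q) / length(q)))
  expect_lt(d, 1.63 / sqrt(length(q)))   # 1% KS critical value
})

test_that("model show method prints the key parameters", {
  out <- capture.output(show(canonicalModel()))
  expect_true(any(grepl("alpha", out)))
  expect_true(any(grepl("10000", out)))
})
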