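# Shared fixtures and independent oracles. All oracles evaluate the model
# quantities by a route independent of the package's closed forms
# (numeric quadrature, bisection, exact finite-population sums).

canonicalModel <- function() TruncatedPowerLaw(1.5, 1e-6, 1e-2)

# normalization constant by quadrature: the A with int x * A x^-alpha = 1
quadNormConst <- function(alpha, xmin, xmax) {
  1 / stats::integrate(function(x) x^(1 - alpha), xmin, xmax,
                       rel.tol = 1e-12)$value
}

# total richness by quadrature of the count density
quadTotalUnique <- function(alpha, xmin, xmax) {
  quadNormConst(alpha, xmin, xmax) *
    stats::integrate(function(x) x^(-alpha), xmin, xmax,
                     rel.tol = 1e-12)$value
}

# analytic CDF of the frequency distribution (for quantile inversion checks)
freqCDF <- function(model, x) {
  a <- model@alpha
  (x^(1 - a) - model@xMin^(1 - a)) /
    (model@xMax^(1 - a) - model@xMin^(1 - a))
}

# exact finite-population occupancy sums on a probability vector
oracleUnique   <- function(p, r) sum(1 - exp(r * log1p(-p)))
oracleCoverage <- function(p, r) sum(p * (1 - exp(r * log1p(-p))))
oracleUnseen   <- function(p, r) sum(p * exp(r * log1p(-p)))

# Sampler of random valid models for oracle-equivalence checks, and a
# depth-selection rule: the finite-population oracle on one realized
# population fluctuates around the closed form with a coefficient of
# variation computable from the model (Poisson approximation over the
# count density); evaluation depths are chosen so that CV stays well
# below the comparison band, making the check probe the continuum
# approximation rather than realization noise.
randomOracleModel <- function() {
  repeat {
    a <- sample(c(1.3, 1.45, 1.6, 1.75, 1.85), 1)
    xmin <- 10^stats::runif(1, -6.1, -5.4)
    xmax <- xmin * 10^stats::runif(1, 2.2, 2.9)
    m <- TruncatedPowerLaw(a, xmin, xmax)
    h <- totalUnique(m)
    if (h >= 2.5e4 && h <= 5e4) return(m)
  }
}

.densityIntegral <- function(m, f) {
  stats::integrate(function(x) f(x) * countDensity(m, x), m@xMin, m@xMax,
                   rel.tol = 1e-9)$value
}

cvUniqueOracle <- function(m, r) {
  sqrt(.densityIntegral(m, function(x) exp(-r * x) * (1 - exp(-r * x)))) /
    .densityIntegral(m, function(x) 1 - exp(-r * x))
}

cvUnseenOracle <- function(m, r) {
  sqrt(.densityIntegral(m, function(x) x^2 * exp(-2 * r * x))) /
    .densityIntegral(m, function(x) x * exp(-r * x))
}

pickOracleDepth <- function(m, cvf, gridFracs) {
  grid <- gridFracs / m@xMin
  for (r in rev(grid)) if (cvf(m, r) < 0.004) return(round(r))
  round(grid[1])
}

# iid counts from a discrete power law with exponent alpha and lower
# support yMin, by inverse-CDF on the continuous approximation; an
# independent generator for exponent-estimator tests
rZipfCounts <- function(n, alpha, yMin = 1) {
  u <- stats::runif(n)
  floor((yMin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}
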