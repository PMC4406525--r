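#' @include classicalEstimators.R
NULL

#' Generate a synthetic population
#'
#' End-to-end generator mirroring the validation design the estimators
#' assume: choose \eqn{\alpha} and a population draw count `nTotal`, set
#' \eqn{x_{min} = 1/n_{total}} (unless a fixed value is supplied), solve
#' the feasibility bound for \eqn{x_{max}} ([xmaxUpperBound()], unless a
#' fixed value is supplied), compute the implied richness \eqn{H}
#' ([totalUnique()]), and materialize `round(H)` category probabilities by
#' inverse-CDF sampling ([sampleFrequencies()]).  Fully reproducible from
#' the arguments.
#'
#' @param alpha Density exponent.
#' @param nTotal Population draw count.
#' @param xMin Fixed lower bound, or `NULL` (default) for
#'   \eqn{1/n_{total}}.
#' @param xMax Fixed upper bound, or `NULL` (default) to solve the
#'   feasibility bound.
#' @param seed Integer RNG seed.
#' @return A [SyntheticPopulation].
#' @examples
#' pop <- generatePopulation(1.5, 1e6, seed = 7)
#' populationSize(pop)   # ~ 3.7e4 categories
#' @export
generatePopulation <- function(alpha, nTotal, xMin = NULL, xMax = NULL,
                               seed = 1L) {
  if (is.null(xMin)) xMin <- 1 / nTotal
  if (is.null(xMax)) xMax <- xmaxUpperBound(alpha, nTotal)
  model <- TruncatedPowerLaw(alpha, xMin, xMax, nTotal)
  sampleFrequencies(model, seed)
}

#' Draw a categorical sample from a population
#'
#' Takes `r` independent draws from the population's category
#' probabilities (one multinomial draw; the draws are exchangeable) and
#' returns the observed nonzero counts.  Deterministic given `seed`.
#'
#' @param population A [SyntheticPopulation].
#' @param r Sample size (number of draws, >= 1).
#' @param seed Integer RNG seed.
#' @return An [ObservedSample] whose counts total `r`.
#' @export
drawSample <- function(population, r, seed = 1L) {
  stopifnot(is(population, "SyntheticPopulation"))
  if (r < 1) stop("'r' must be >= 1")
  p <- probabilities(population)
  y <- withSeed(seed, as.numeric(stats::rmultinom(1, r, p)))
  names(y) <- sprintf("cat%06d", seq_along(y))
  ObservedSample(y[y > 0])
}

## estimator wrappers for the benchmark sweep; each returns a one-row
## record, capturing failures as NA + reason instead of aborting
.benchRow <- function(depth, estimator, truth, fn) {
  res <- tryCatch(list(est = fn(), note = ""),
                  error = function(e)
                    list(est = NA_real_, note = conditionMessage(e)))
  data.frame(depth = depth, estimator = estimator,
             estimate = as.numeric(res$est), truth = truth,
             note = res$note)
}

#' Convergence benchmark across sampling depths
#'
#' The estimator-comparison experiment: generate a population, then for
#' each sampling depth draw a sample of `depth * nTotal` draws and compute
#' every exponent estimator (Clauset continuous/discrete, KS-cutoff,
#' singleton-ratio, and the discovery-curve fit) and every richness
#' estimator (observed count, discovery-curve fit, capture-recapture on a
#' random half-split, first-order jackknife, Chao1, ACE).  Estimator
#' failures are recorded per-row as `NA` with a reason, never aborting the
#' sweep.  Exponent rows carry `truth = alpha`; richness rows carry
#' `truth = ` the realized number of categories.
#'
#' @param alpha,nTotal,xMin,xMax,seed Population settings, as in
#'   [generatePopulation()].
#' @param depths Sample fractions in \eqn{(0, 1]}.
#' @param curveReps Subsample replicates for the discovery curves
#'   (default 5).
#' @return A `data.frame` with columns `depth`, `estimator`, `estimate`,
#'   `truth`, `note`.
#' @export
convergenceBenchmark <- function(alpha, nTotal, depths, xMin = NULL,
                                 xMax = NULL, seed = 1L, curveReps = 5L) {
  if (any(depths <= 0) || any(depths > 1))
    stop("'depths' must lie in (0, 1]")
  pop <- generatePopulation(alpha, nTotal, xMin = xMin, xMax = xMax,
                            seed = seed)
  hTrue <- populationSize(pop)
  rows <- list()
  for (i in seq_along(depths)) {
    d <- depths[i]
    r <- max(2, round(d * nTotal))
    smp <- drawSample(pop, r, seed = seed + i)
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "observed", hTrue, function() nUnique(smp))
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "clausetContinuous", alpha,
                function() clausetContinuous(smp))
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "clausetDiscrete", alpha,
                function() clausetDiscrete(smp))
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "ksCutoff", alpha, function() selectCutoffKS(smp)$alpha)
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "ohannessian", alpha,
                function() suppressWarnings(as.numeric(ohannessian(smp))))
    fit <- tryCatch({
      curve <- empiricalDiscoveryCurve(smp, reps = curveReps,
                                       seed = seed + 1000L + i)
      fitModel(curve, nTotal)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      msg <- conditionMessage(fit)
      rows[[length(rows) + 1L]] <-
        .benchRow(d, "fitAlpha", alpha, function() stop(msg))
      rows[[length(rows) + 1L]] <-
        .benchRow(d, "fitH", hTrue, function() stop(msg))
    } else {
      rows[[length(rows) + 1L]] <-
        .benchRow(d, "fitAlpha", alpha, function() alphaHat(fit))
      rows[[length(rows) + 1L]] <-
        .benchRow(d, "fitH", hTrue, function() fit@hHat)
    }
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "captureRecapture", hTrue, function() {
        halves <- splitSample(smp, seed = seed + 2000L + i)
        captureRecapture(halves$A, halves$B)
      })
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "jackknife1", hTrue, function() jackknife1(smp))
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "chao1", hTrue, function() chao1(smp))
    rows[[length(rows) + 1L]] <-
      .benchRow(d, "ace", hTrue,
                function() suppressWarnings(as.numeric(ace(smp))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
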