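#' @include alphaEstimators.R
NULL

## subsample `rPrime` of the `r` draws behind `counts` without replacement
## and return the number of distinct categories observed.  Draw indices are
## mapped to categories through the cumulative count boundaries, so the
## expanded draw vector is never materialized.
.subsampleUnique <- function(counts, r, rPrime) {
  if (rPrime >= r) return(length(counts))
  idx <- sample.int(r, rPrime)
  cum <- cumsum(counts)
  length(unique(findInterval(idx - 1L, cum)))
}

#' Build an empirical discovery curve by subsampling
#'
#' For each grid value \eqn{R'}, takes `reps` subsamples of \eqn{R'} draws
#' without replacement (multivariate hypergeometric) from the sample's
#' draws and records the mean number of distinct categories observed.  The
#' returned curve also carries the sample's observed frequency range and a
#' direct exponent estimate, which [fitModel()] uses for bounds and its
#' initial guess.  Deterministic given `seed`.
#'
#' @param sample An [ObservedSample].
#' @param grid Sample sizes \eqn{R'}; defaults to 30 log-spaced values from
#'   100 (or 1 for tiny samples) to the full sample size.
#' @param reps Subsample replicates per grid value (default 5).
#' @param seed Integer RNG seed.
#' @return A [DiscoveryCurve].
#' @export
empiricalDiscoveryCurve <- function(sample, grid = NULL, reps = 5L,
                                    seed = 1L) {
  stopifnot(is(sample, "ObservedSample"))
  r <- totalDraws(sample)
  if (is.null(grid)) {
    lo <- min(100, r)
    grid <- unique(round(exp(seq(log(lo), log(r), length.out = 30))))
  }
  grid <- sort(unique(round(grid)))
  if (any(grid < 1) || any(grid > r))
    stop("grid values must lie in [1, total draws = ", r, "]")
  if (reps < 1) stop("'reps' must be >= 1")
  counts <- categoryCounts(sample)
  uObs <- withSeed(seed, {
    vapply(grid, function(rp)
      mean(vapply(seq_len(reps), function(i)
        .subsampleUnique(counts, r, rp), numeric(1))), numeric(1))
  })
  alphaGuess <- tryCatch(clausetContinuous(sample),
                         error = function(e) NA_real_)
  DiscoveryCurve(grid, uObs, reps = reps,
                 freqMin = min(counts) / r, freqMax = max(counts) / r,
                 alphaGuess = alphaGuess,
                 provenance = sprintf("subsampled from %d categories, %g draws",
                                      nUnique(sample), r))
}

#' Log-weighted squared-log cost of a parameter triple
#'
#' The discovery-curve fitting objective:
#' \deqn{\sum_{R'} \left(\log U(R') - \log u_{obs}(R')\right)^2
#'   \cdot \log u_{obs}(R'),}
#' natural logarithms, summed over curve points with \eqn{u_{obs} \ge 2}
#' (points below 2 have nonpositive weight and are dropped).
#'
#' @param params Numeric triple `c(alpha, xMin, xMax)`.
#' @param curve A [DiscoveryCurve].
#' @return Nonnegative cost; zero iff the model reproduces every retained
#'   point exactly.
#' @export
fitCost <- function(params, curve) {
  stopifnot(is(curve, "DiscoveryCurve"), length(params) == 3L)
  pts <- curvePoints(curve)
  pts <- pts[pts$uObs >= 2, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("no curve points with observed unique count >= 2")
  model <- TruncatedPowerLaw(params[1], params[2], params[3])
  u <- expectedUnique(model, pts$r)
  if (any(u <= 0)) return(Inf)
  sum((log(u) - log(pts$uObs))^2 * log(pts$uObs))
}

## Transformed coordinates for the derivative-free search:
## theta = (alpha, log xMin, logit of xMax relative to its alpha-dependent
## feasibility bound), so xMax <= xmaxUpperBound(alpha, nTotal) holds by
## construction and the feasible region is a box.  Remaining bounds are
## enforced by clamping the evaluated parameters and adding a smooth
## quadratic penalty, which keeps the objective continuous (hard penalty
## cliffs stall the simplex).  The observed extreme frequencies are noisy,
## so the pMaxObs lower bound yields to the feasibility bound when the two
## conflict.
.thetaToParams <- function(theta, nTotal, pMinObs, pMaxObs) {
  pen <- 0
  a <- theta[1]
  if (a < 0.2) { pen <- pen + (0.2 - a)^2; a <- 0.2 }
  if (a > 1.95) { pen <- pen + (a - 1.95)^2; a <- 1.95 }
  g <- .ALPHA_GUARD * 1.01
  if (abs(a - 1) < g) a <- 1 + sign(a - 1 + 1e-12) * g
  xmin <- exp(theta[2])
  if (xmin < 1 / nTotal) {
    pen <- pen + log(1 / (nTotal * xmin))^2
    xmin <- 1 / nTotal
  }
  if (is.finite(pMinObs) && xmin > pMinObs) {
    pen <- pen + log(xmin / pMinObs)^2
    xmin <- pMinObs
  }
  ub <- xmaxUpperBound(a, nTotal)
  xmax <- ub * stats::plogis(theta[3])
  lb <- min(if (is.finite(pMaxObs)) pMaxObs else ub, ub)
  if (xmax < lb) {
    pen <- pen + log(lb / xmax)^2
    xmax <- lb
  }
  if (xmax <= xmin) return(NULL)
  list(alpha = a, xMin = xmin, xMax = xmax, penalty = pen)
}

.penalizedCost <- function(theta, curve, nTotal, pMinObs, pMaxObs) {
  par <- .thetaToParams(theta, nTotal, pMinObs, pMaxObs)
  if (is.null(par)) return(1e8)
  cost <- tryCatch(fitCost(c(par$alpha, par$xMin, par$xMax), curve),
                   error = function(e) Inf)
  if (!is.finite(cost)) return(1e8)
  cost + 100 * par$penalty
}

#' Fit the truncated power law to a discovery curve
#'
#' The headline estimator: recovers \eqn{(\alpha, x_{min}, x_{max})} by
#' derivative-free minimization of [fitCost()] against the closed-form
#' discovery curve [expectedUnique()].  The search runs in
#' \eqn{(\alpha, \log x_{min}, \log x_{max})} with Nelder-Mead from the
#' initial guess (the curve's direct exponent estimate clamped into the
#' box, \eqn{x_{min} = 1/n_{total}}, \eqn{x_{max}} at the highest observed
#' frequency) plus two additional starts (a perturbed copy and a mid-box
#' point); the best result is kept.  Feasibility -- \eqn{x_{min} \in
#' [1/n_{total}, \min p_j]}, \eqn{x_{max} \in [\max p_j,
#' } [xmaxUpperBound()]\eqn{(\alpha, n_{total})]}, \eqn{\alpha \in (0.2,
#' 1.95)} outside the guard interval -- is enforced by penalty, since the
#' \eqn{x_{max}} bound depends on \eqn{\alpha}.
#'
#' @param curve A [DiscoveryCurve] with at least 4 usable points.
#' @param nTotal Total number of draws in the target population; must
#'   exceed the largest curve sample size.
#' @param control Optional list: `alphaInit`, `pMinObs`, `pMaxObs`
#'   override the curve-derived defaults; `maxit` (default 2000) is passed
#'   to the optimizer.
#' @return A [FitResult][FitResult-class].
#' @export
fitModel <- function(curve, nTotal, control = list()) {
  stopifnot(is(curve, "DiscoveryCurve"))
  pts <- curvePoints(curve)
  usable <- sum(pts$uObs >= 2)
  if (usable < 4L)
    stop("need at least 4 curve points with observed unique count >= 2")
  if (nTotal <= max(pts$r))
    stop("'nTotal' must exceed the largest curve sample size")
  pMinObs <- if (!is.null(control$pMinObs)) control$pMinObs else
    curve@freqMin
  pMaxObs <- if (!is.null(control$pMaxObs)) control$pMaxObs else
    curve@freqMax
  alphaInit <- if (!is.null(control$alphaInit)) control$alphaInit else
    curve@alphaGuess
  if (is.na(alphaInit)) alphaInit <- 1.5
  alphaInit <- .clamp(alphaInit, 0.25, 1.9)
  if (abs(alphaInit - 1) <= .ALPHA_GUARD) alphaInit <- 1.05
  maxit <- if (!is.null(control$maxit)) control$maxit else 2000L
  if (is.na(pMaxObs)) pMaxObs <- min(10 / nTotal * max(pts$uObs), 0.5)
  ## starting xMax: the highest observed frequency, capped by the
  ## feasibility bound at the starting alpha
  thetaFor <- function(a) {
    ub <- xmaxUpperBound(a, nTotal)
    x0 <- min(pMaxObs, ub)
    c(a, log(1 / nTotal),
      .clamp(stats::qlogis(x0 / ub), -12, 12))
  }
  starts <- list(thetaFor(alphaInit),
                 thetaFor(.clamp(alphaInit - 0.35, 0.25, 1.9)),
                 thetaFor(1.5), thetaFor(0.7))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, .penalizedCost, curve = curve, nTotal = nTotal,
                        pMinObs = pMinObs, pMaxObs = pMaxObs,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    ## polish from the incumbent
    opt2 <- stats::optim(opt$par, .penalizedCost, curve = curve,
                         nTotal = nTotal, pMinObs = pMinObs,
                         pMaxObs = pMaxObs, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- .thetaToParams(best$par, nTotal, pMinObs, pMaxObs)
  feasible <- !is.null(par) && best$value < 1e7
  if (!feasible)
    stop("no feasible parameter triple found for this curve")
  conv <- best$convergence == 0
  init <- .thetaToParams(starts[[1]], nTotal, pMinObs, pMaxObs)
  model <- TruncatedPowerLaw(par$alpha, par$xMin, par$xMax, nTotal)
  new("FitResult", alphaHat = par$alpha, xMinHat = par$xMin,
      xMaxHat = par$xMax, hHat = totalUnique(model),
      cost = best$value,
      initialGuess = c(alpha = init$alpha, xMin = init$xMin,
                       xMax = init$xMax),
      nTotal = as.numeric(nTotal), converged = conv,
      nCurvePoints = as.integer(usable))
}

#' Project a fitted model to a target population size
#'
#' Evaluates the fitted discovery curve, coverage and unseen-mass at a
#' target number of draws -- e.g. the census population -- alongside the
#' model's total richness.  Note the distinction between `hHat` (the
#' model-implied total number of categories, at infinite sampling) and
#' `uTarget` (the number expected to be realized in `nTarget` draws).
#'
#' @param fit A converged [FitResult][FitResult-class].
#' @param nTarget Target population size(s) in draws.
#' @return A `data.frame` with columns `r`, `uTarget`, `coverage`,
#'   `probUnseen` and `hHat`.
#' @export
extrapolate <- function(fit, nTarget) {
  stopifnot(is(fit, "FitResult"))
  if (!fit@converged)
    stop("fit did not converge; refusing to extrapolate")
  model <- fittedModel(fit)
  data.frame(r = nTarget,
             uTarget = expectedUnique(model, nTarget),
             coverage = fractionCovered(model, nTarget),
             probUnseen = probUnseen(model, nTarget),
             hHat = fit@hHat)
}

#' Smallest sample size reaching a target coverage
#'
#' Inverse query on the fitted coverage curve: the smallest number of draws
#' \eqn{r} with \eqn{FractionCovered(r) \ge} `targetCoverage`, found by
#' monotone bisection on \eqn{\log r}.
#'
#' @param fit A converged [FitResult][FitResult-class].
#' @param targetCoverage Coverage fraction in \eqn{(0, 1)}.
#' @return The required sample size (draws).
#' @export
sampleSizeForCoverage <- function(fit, targetCoverage) {
  stopifnot(is(fit, "FitResult"))
  if (!fit@converged)
    stop("fit did not converge; refusing to extrapolate")
  if (targetCoverage <= 0 || targetCoverage >= 1)
    stop("'targetCoverage' must lie in (0, 1)")
  model <- fittedModel(fit)
  rMax <- 1e3 / fit@xMinHat
  if (fractionCovered(model, rMax) < targetCoverage)
    stop("target coverage ", targetCoverage,
         " is not reachable (coverage at r = ", rMax, " is ",
         signif(fractionCovered(model, rMax), 4), ")")
  f <- function(lr) fractionCovered(model, exp(lr)) - targetCoverage
  if (f(0) >= 0) return(1)
  exp(stats::uniroot(f, lower = 0, upper = log(rMax), tol = 1e-10)$root)
}
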