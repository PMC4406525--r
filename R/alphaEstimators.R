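#' @include occupancy.R
NULL

#' Continuous maximum-likelihood exponent estimate
#'
#' The Clauset-style continuous estimator applied to observed relative
#' frequencies:
#' \deqn{\hat\alpha = 1 + n\left[\sum_j \ln(p_j / p_{min})\right]^{-1},}
#' where \eqn{p_{min}} is the smallest observed relative frequency.  On
#' truncated populations this estimator is biased upward; it mainly serves
#' as the optimizer's initial guess (see [fitModel()]).
#'
#' @param sample An [ObservedSample] with at least two categories.
#' @return Exponent estimate (> 1).
#' @examples
#' clausetContinuous(ObservedSample(c(8, 4, 2, 1, 1)))
#' @export
clausetContinuous <- function(sample) {
  stopifnot(is(sample, "ObservedSample"))
  p <- relFrequencies(sample)
  if (length(p) < 2L) stop("at least two categories are required")
  s <- sum(log(p / min(p)))
  if (s == 0)
    stop("all categories have equal frequency; the estimator is undefined")
  1 + length(p) / s
}

#' Discrete maximum-likelihood exponent estimate
#'
#' The Clauset-style discrete estimator on absolute counts, optionally
#' restricted to counts at or above a cutoff \eqn{y^*}:
#' \deqn{\hat\alpha = 1 + n'\left[\sum_{y_j \ge y^*}
#'   \ln\frac{y_j}{y^* - 0.5}\right]^{-1},}
#' where \eqn{n'} is the number of retained categories.  With the default
#' \eqn{y^* = y_{min}} all categories are used; larger cutoffs discard the
#' smallest counts, which de-biases the estimate when the underlying
#' distribution is truncated from below.
#'
#' @param sample An [ObservedSample].
#' @param yStar Optional positive integer cutoff; default is the smallest
#'   observed count.
#' @return Exponent estimate (> 1).
#' @examples
#' clausetDiscrete(ObservedSample(c(8, 4, 2, 1, 1)))          # ~ 1.6558
#' clausetDiscrete(ObservedSample(c(8, 4, 2, 1, 1)), yStar = 2)
#' @export
clausetDiscrete <- function(sample, yStar = NULL) {
  stopifnot(is(sample, "ObservedSample"))
  y <- categoryCounts(sample)
  if (is.null(yStar)) yStar <- min(y)
  if (!is.numeric(yStar) || length(yStar) != 1L || yStar < 1)
    stop("'yStar' must be a single count >= 1")
  kept <- y[y >= yStar]
  if (length(kept) < 2L)
    stop("fewer than two categories at or above the cutoff")
  if (!any(kept > yStar))
    stop("no category strictly above the cutoff; the estimator is undefined")
  1 + length(kept) / sum(log(kept / (yStar - 0.5)))
}

#' Cutoff selection by Kolmogorov-Smirnov distance
#'
#' Scans every distinct observed count as a candidate lower cutoff
#' \eqn{y^*}, fits the discrete exponent above each candidate with
#' [clausetDiscrete()], and keeps the cutoff minimizing the KS distance
#' between the empirical distribution of the retained counts and the
#' fitted power law (continuous form with the \eqn{y^* - 0.5} offset,
#' evaluated at the observed count values).  Ties are broken toward the
#' smaller cutoff, i.e. the larger retained sample.
#'
#' @param sample An [ObservedSample] with at least four categories.
#' @return A list with elements `cutoff` (the selected \eqn{y^*}),
#'   `alpha` (the exponent fitted above it), `ks` (the attained KS
#'   distance) and `nKept` (categories retained).
#' @export
selectCutoffKS <- function(sample) {
  stopifnot(is(sample, "ObservedSample"))
  y <- categoryCounts(sample)
  if (length(y) < 4L) stop("at least four categories are required")
  candidates <- sort(unique(y))
  best <- NULL
  for (ys in candidates) {
    kept <- y[y >= ys]
    if (length(kept) < 3L || !any(kept > ys)) next
    a <- 1 + length(kept) / sum(log(kept / (ys - 0.5)))
    ## model complementary CDF at each observed distinct count
    vals <- sort(unique(kept))
    empCcdf <- vapply(vals, function(v) mean(kept >= v), numeric(1))
    modCcdf <- ((vals - 0.5) / (ys - 0.5))^(1 - a)
    ks <- max(abs(empCcdf - modCcdf))
    if (is.null(best) || ks < best$ks)   # strict '<' keeps smaller cutoff
      best <- list(cutoff = ys, alpha = a, ks = ks, nKept = length(kept))
  }
  if (is.null(best))
    stop("no candidate cutoff retains at least three categories")
  best
}

#' Singleton-ratio exponent estimate
#'
#' The Ohannessian-style regular-variation estimator: on the density scale,
#' \deqn{\hat\alpha = K_{n,1}/K_n + 1,} the fraction of observed
#' categories that are singletons, plus one.  (The exceedance-scale version
#' of the estimator is \eqn{\hat\beta = K_{n,1}/K_n}; the density exponent
#' is one unit larger.)  Values are confined to \eqn{[1, 2]}; boundary
#' samples (no singletons, or all singletons) return the boundary value
#' with a `"boundary"` attribute and a warning instead of an error so that
#' benchmark sweeps are never aborted.
#'
#' @param sample A nonempty [ObservedSample].
#' @return Exponent estimate in \eqn{[1, 2]}, with attribute `boundary`
#'   set to `TRUE` when the singleton ratio is 0 or 1.
#' @examples
#' ohannessian(ObservedSample(c(3, 2, 1, 1, 1)))  # 1.6
#' @export
ohannessian <- function(sample) {
  stopifnot(is(sample, "ObservedSample"))
  kn <- nUnique(sample)
  if (kn < 1L) stop("empty sample")
  ratio <- nSingletons(sample) / kn
  est <- 1 + ratio
  if (ratio == 0 || ratio == 1) {
    warning("singleton ratio at boundary (", ratio,
            "); estimate pinned to ", est)
    attr(est, "boundary") <- TRUE
  }
  est
}
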