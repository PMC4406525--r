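#' @include powerModel.R
NULL

## Shared engine for the three occupancy closed forms.  Each reduces to the
## cancellation-safe difference Gamma(s, r*xMin) - Gamma(s, r*xMax), with
## s = 1 - alpha (discovery) or s = 2 - alpha (coverage / unseen mass).
## Below r*xMax < 1e-8 the formulas are replaced by their analytic limits
## (U = 0, Z = 1): there U <= r <= 1e-8/xMax is negligible and the limit is
## exact to far better than any stated tolerance.
.SMALL_R_GUARD <- 1e-8

#' Expected number of unique categories in a sample
#'
#' The discovery curve of the truncated power law:
#' \deqn{U(R) = H - A\,R^{\alpha-1}\left[\gamma(1-\alpha, R x_{max}) -
#'   \gamma(1-\alpha, R x_{min})\right]}
#' with \eqn{A} the normalization constant, \eqn{H} the total richness and
#' \eqn{\gamma} the (analytically continued) lower incomplete gamma.  This
#' is the continuum limit of \eqn{\sum_j (1 - (1-p_j)^R)}.  Monotone
#' nondecreasing in `r`, with \eqn{U(0) = 0} and \eqn{U(R) \to H}.
#'
#' @param model A [TruncatedPowerLaw] (or a [FitResult][FitResult-class],
#'   which delegates to its fitted model).
#' @param r Sample size(s), nonnegative reals (number of haplotype draws).
#' @return Expected unique-category counts, same length as `r`.
#' @examples
#' m <- TruncatedPowerLaw(1.5, 1e-6, 1e-2)
#' expectedUnique(m, c(1e3, 1e5, 1e9))
#' @rdname expectedUnique
#' @export
setMethod("expectedUnique", "TruncatedPowerLaw", function(model, r) {
  validObject(model)
  if (any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and nonnegative")
  a <- model@alpha
  h <- totalUnique(model)
  A <- normalizationConstant(model)
  out <- numeric(length(r))
  live <- r * model@xMax >= .SMALL_R_GUARD
  if (any(live)) {
    rl <- r[live]
    missing <- A * rl^(a - 1) *
      .upperGammaDiff(1 - a, rl * model@xMin, rl * model@xMax)
    out[live] <- pmin(pmax(h - missing, 0), h)
  }
  out
})

#' Probability that a new draw is unseen
#'
#' The expected probability mass carried by categories absent from a sample
#' of size `r`:
#' \deqn{Z(R) = A\,R^{\alpha-2}\left[\gamma(2-\alpha, R x_{max}) -
#'   \gamma(2-\alpha, R x_{min})\right].}
#' Equals the chance that the haplotype of a newly sampled host is not yet
#' in the registry sample.  Monotone nonincreasing, \eqn{Z(0) = 1},
#' \eqn{Z(R) \to 0}.
#'
#' @param model A [TruncatedPowerLaw].
#' @param r Sample size(s), nonnegative reals.
#' @return Probabilities in \eqn{[0, 1]}, same length as `r`.
#' @rdname probUnseen
#' @export
setMethod("probUnseen", "TruncatedPowerLaw", function(model, r) {
  validObject(model)
  if (any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and nonnegative")
  a <- model@alpha
  A <- normalizationConstant(model)
  out <- rep(1, length(r))
  live <- r * model@xMax >= .SMALL_R_GUARD
  if (any(live)) {
    rl <- r[live]
    z <- A * rl^(a - 2) *
      .upperGammaDiff(2 - a, rl * model@xMin, rl * model@xMax)
    out[live] <- pmin(pmax(z, 0), 1)
  }
  out
})

#' Fraction of the population already covered
#'
#' The probability mass of the population carried by categories expected to
#' be present in a sample of size `r`.  Defined as the exact complement of
#' [probUnseen()] (one shared code path), so
#' `fractionCovered(m, r) + probUnseen(m, r) == 1` holds to machine
#' precision by construction.
#'
#' @param model A [TruncatedPowerLaw].
#' @param r Sample size(s), nonnegative reals.
#' @return Probabilities in \eqn{[0, 1]}, same length as `r`.
#' @rdname fractionCovered
#' @export
setMethod("fractionCovered", "TruncatedPowerLaw", function(model, r) {
  1 - probUnseen(model, r)
})

#' @rdname expectedUnique
#' @export
setMethod("expectedUnique", "FitResult", function(model, r)
  expectedUnique(fittedModel(model), r))

#' @rdname fractionCovered
#' @export
setMethod("fractionCovered", "FitResult", function(model, r)
  fractionCovered(fittedModel(model), r))

#' @rdname probUnseen
#' @export
setMethod("probUnseen", "FitResult", function(model, r)
  probUnseen(fittedModel(model), r))
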