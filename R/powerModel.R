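#' @include incompleteGamma.R
NULL

## shorthand used throughout: with A the normalization constant,
## mu(x) = A x^-alpha on [xMin, xMax] and int x mu(x) dx = 1.

#' Normalization constant of the truncated power law
#'
#' The constant \eqn{A} such that the count density
#' \eqn{\mu(x) = A x^{-\alpha}} carries unit probability mass,
#' \eqn{\int_{x_{min}}^{x_{max}} x\,\mu(x)\,dx = 1}.  Closed form
#' \eqn{A = (2-\alpha) / (x_{max}^{2-\alpha} - x_{min}^{2-\alpha})}.
#'
#' @param model A [TruncatedPowerLaw].
#' @return Positive scalar \eqn{A}.
#' @examples
#' normalizationConstant(TruncatedPowerLaw(1.5, 1e-6, 1e-2))  # ~ 5.0505
#' @rdname normalizationConstant
#' @export
setMethod("normalizationConstant", "TruncatedPowerLaw", function(model) {
  validObject(model)
  a <- model@alpha
  (2 - a) / (model@xMax^(2 - a) - model@xMin^(2 - a))
})

#' Count density of category frequencies
#'
#' \eqn{\mu(x) = A x^{-\alpha}}: the expected number of categories per unit
#' of relative frequency at frequency `x`.  Not a probability density --
#' its integral over the support is the total number of unique categories.
#'
#' @param model A [TruncatedPowerLaw].
#' @param x Relative frequencies inside the support.
#' @return Density values, same length as `x`.
#' @rdname countDensity
#' @export
setMethod("countDensity", "TruncatedPowerLaw", function(model, x) {
  validObject(model)
  if (any(x < model@xMin - 1e-15) || any(x > model@xMax + 1e-15))
    stop("'x' must lie within the model support [xMin, xMax]")
  normalizationConstant(model) * x^(-model@alpha)
})

#' Exceedance function
#'
#' The expected number of categories with relative frequency at least `x`:
#' \eqn{v(x) = \int_x^{x_{max}} \mu(t)\,dt}.  Under this convention
#' \eqn{v(x_{max}) = 0} and \eqn{v(x_{min}) = H}, the total number of
#' unique categories (the single top category is accounted for by the
#' \eqn{x_{max}} bound itself, see [xmaxUpperBound()]).
#'
#' @param model A [TruncatedPowerLaw].
#' @param x Relative frequencies inside the support.
#' @return Expected exceedance counts, same length as `x`.
#' @rdname exceedance
#' @export
setMethod("exceedance", "TruncatedPowerLaw", function(model, x) {
  validObject(model)
  if (any(x < model@xMin - 1e-15) || any(x > model@xMax + 1e-15))
    stop("'x' must lie within the model support [xMin, xMax]")
  a <- model@alpha
  normalizationConstant(model) *
    (model@xMax^(1 - a) - x^(1 - a)) / (1 - a)
})

#' Expected total number of unique categories
#'
#' The model-implied richness
#' \deqn{H = \frac{2-\alpha}{1-\alpha}\cdot
#'   \frac{x_{max}^{1-\alpha} - x_{min}^{1-\alpha}}
#'        {x_{max}^{2-\alpha} - x_{min}^{2-\alpha}},}
#' i.e. the integral of the count density over the support.  Real-valued;
#' rounding to an integer count happens only when a discrete population is
#' materialized ([sampleFrequencies()]).
#'
#' @param model A [TruncatedPowerLaw].
#' @return Positive scalar \eqn{H}.
#' @examples
#' totalUnique(TruncatedPowerLaw(1.5, 1e-6, 1e-2))  # 10000
#' @rdname totalUnique
#' @export
setMethod("totalUnique", "TruncatedPowerLaw", function(model) {
  validObject(model)
  a <- model@alpha
  (2 - a) / (1 - a) *
    (model@xMax^(1 - a) - model@xMin^(1 - a)) /
    (model@xMax^(2 - a) - model@xMin^(2 - a))
})

#' Quantile function of the frequency distribution
#'
#' Inverts the cumulative distribution of category relative frequencies,
#' \eqn{F(x) = (x^{1-\alpha} - x_{min}^{1-\alpha}) /
#' (x_{max}^{1-\alpha} - x_{min}^{1-\alpha})}:
#' \deqn{Q(u) = \left[(x_{max}^{1-\alpha} - x_{min}^{1-\alpha})\,u +
#'   x_{min}^{1-\alpha}\right]^{1/(1-\alpha)}.}
#' This is the inverse-CDF step used to materialize synthetic populations.
#'
#' @param x A [TruncatedPowerLaw].
#' @param probs Probabilities in \eqn{[0, 1]}.
#' @param ... Ignored (signature compatibility).
#' @return Relative frequencies, same length as `probs`;
#'   `Q(0) = xMin`, `Q(1) = xMax`.
#' @export
setMethod("quantile", "TruncatedPowerLaw", function(x, probs, ...) {
  validObject(x)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("'probs' must lie in [0, 1]")
  a <- x@alpha
  ((x@xMax^(1 - a) - x@xMin^(1 - a)) * probs + x@xMin^(1 - a))^(1 / (1 - a))
})

#' Feasible upper frequency bound for a finite population
#'
#' In a population of `nTotal` draws with \eqn{x_{min} = 1/n_{total}}, the
#' largest admissible \eqn{x_{max}} is fixed by requiring the count density
#' to place one category in the topmost frequency bin of width
#' \eqn{1/n_{total}}: \eqn{\mu(x_{max})/n_{total} = 1}.  On the absolute
#' count scale \eqn{u = n_{total}\,x_{max}} this is the root of
#' \deqn{u^2\,(1 - u^{\alpha-2}) = (2-\alpha)\,n_{total},}
#' solved numerically; the root divided by `nTotal` is returned.
#'
#' @param alpha Density exponent (valid, guarded range).
#' @param nTotal Total number of draws in the population (>= 2).
#' @return The bound \eqn{x_{max} \in (1/n_{total}, 1]}.
#' @examples
#' xmaxUpperBound(1.5, 1e6)  # ~ 7.21e-4
#' @export
xmaxUpperBound <- function(alpha, nTotal) {
  msg <- .checkAlpha(alpha)
  if (!is.null(msg)) stop(msg)
  if (!is.numeric(nTotal) || length(nTotal) != 1L || nTotal < 2)
    stop("'nTotal' must be a single number >= 2")
  cc <- (2 - alpha) * nTotal
  f <- function(u) u^2 - u^alpha - cc
  if (f(nTotal) <= 0)
    stop("no feasible xMax in (1/nTotal, 1] for alpha = ", alpha,
         ", nTotal = ", nTotal)
  root <- stats::uniroot(f, lower = 1 + 1e-12, upper = nTotal,
                         tol = .Machine$double.eps^0.75 * nTotal)$root
  root / nTotal
}

#' Materialize a synthetic population from a model
#'
#' Draws \eqn{H = \mathrm{round}(totalUnique(model))} category
#' probabilities by the inverse-CDF construction `quantile(model, u)` with
#' independent uniform `u`, then renormalizes them to sum exactly to one
#' (the raw inverse-CDF draws sum to one only in expectation).
#' Deterministic given `seed`.
#'
#' @param model A [TruncatedPowerLaw].
#' @param seed Integer RNG seed.
#' @return A [SyntheticPopulation] with `round(H)` probabilities.
#' @rdname sampleFrequencies
#' @export
setMethod("sampleFrequencies", "TruncatedPowerLaw", function(model, seed) {
  validObject(model)
  h <- round(totalUnique(model))
  if (h < 1) stop("model implies fewer than one category")
  if (h > 1e8) stop("model implies ", h,
                    " categories, above the 1e8 materialization cap")
  p <- withSeed(seed, {
    u <- stats::runif(h)
    quantile(model, u)
  })
  SyntheticPopulation(p / sum(p), model, seed)
})
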