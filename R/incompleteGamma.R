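#' @include AllClasses.R
NULL

## Incomplete gamma machinery for the occupancy closed forms.
##
## The discovery, coverage and unseen-probability formulas need
## gamma(s, x) at shape s = 1 - alpha, which is NEGATIVE whenever
## alpha > 1 (the usual haplotype regime).  The classical lower integral
## diverges there; the right object is the analytic continuation
## gamma(s, x) = Gamma(s) - Gamma(s, x), where the upper incomplete
## Gamma(s, x) = int_x^Inf t^(s-1) e^-t dt converges for every real s when
## x > 0.  stats::pgamma only covers s > 0, so for negative non-integer
## shapes Gamma(s, x) is computed here with the standard pair of expansions
## (lower series for small x, Lentz continued fraction otherwise), both of
## which remain valid for negative non-integer s.

.MAXIT_IGAMMA <- 600L
.EPS_IGAMMA <- .Machine$double.eps * 4
.FPMIN <- .Machine$double.xmin / .Machine$double.eps

## lower incomplete gamma by series: gamma(s,x) = x^s e^-x sum_n
## x^n / (s(s+1)...(s+n)); valid for any non-integer s, best for small x.
.gammaLowerSeries <- function(s, x) {
  ap <- s
  del <- 1 / s
  total <- del
  for (i in seq_len(.MAXIT_IGAMMA)) {
    ap <- ap + 1
    del <- del * x / ap
    total <- total + del
    if (abs(del) < abs(total) * .EPS_IGAMMA)
      return(total * exp(-x + s * log(x)))
  }
  stop("lower incomplete gamma series failed to converge (s=", s,
       ", x=", x, ")")
}

## upper incomplete gamma by modified Lentz continued fraction; valid for
## any real s when x is not small (used for x >= max(1, s + 1)).
.gammaUpperCF <- function(s, x) {
  b <- x + 1 - s
  c <- 1 / .FPMIN
  d <- 1 / b
  h <- d
  for (i in seq_len(.MAXIT_IGAMMA)) {
    an <- -i * (i - s)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < .FPMIN) d <- .FPMIN
    c <- b + an / c
    if (abs(c) < .FPMIN) c <- .FPMIN
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < .EPS_IGAMMA)
      return(exp(-x + s * log(x)) * h)
  }
  stop("upper incomplete gamma continued fraction failed to converge (s=",
       s, ", x=", x, ")")
}

## scalar upper incomplete gamma Gamma(s, x), any non-integer real s
## (positive s delegated to pgamma), x >= 0 (x > 0 required for s <= 0).
.upperGammaScalar <- function(s, x) {
  if (x < 0) stop("'x' must be nonnegative")
  if (s > 0) {
    if (x == 0) return(gamma(s))
    return(exp(lgamma(s) +
               stats::pgamma(x, s, lower.tail = FALSE, log.p = TRUE)))
  }
  if (s == round(s))
    stop("shape 's' must not be a nonpositive integer")
  if (x == 0)
    stop("upper incomplete gamma diverges at x = 0 for s <= 0")
  if (x >= max(1, s + 1)) return(.gammaUpperCF(s, x))
  gamma(s) - .gammaLowerSeries(s, x)
}

#' Lower incomplete gamma with analytic continuation to negative shape
#'
#' Evaluates \eqn{\gamma(s, x)}, the lower incomplete gamma function, for
#' shapes \eqn{s \in (-1, 0) \cup (0, \infty)}.  For \eqn{s > 0} this is
#' the classical integral \eqn{\int_0^x t^{s-1} e^{-t} dt}; for negative
#' non-integer \eqn{s} the integral diverges and the value returned is the
#' analytic continuation \eqn{\Gamma(s) - \Gamma(s, x)}, which is what the
#' occupancy closed forms require when \eqn{\alpha > 1}.  Satisfies the
#' recurrence \eqn{\gamma(s+1, x) = s\,\gamma(s, x) - x^s e^{-x}} across
#' the whole domain.
#'
#' @param s Shape, in \eqn{(-1, 0) \cup (0, \infty)}.
#' @param x Nonnegative evaluation point(s); strictly positive when
#'   \eqn{s < 0}.
#' @return Numeric vector, `length(x)` values of \eqn{\gamma(s, x)}.
#' @examples
#' lowerGammaExt(0.5, 1e8)   # ~ Gamma(1/2) = sqrt(pi)
#' lowerGammaExt(-0.5, 1)    # analytic continuation, ~ -3.7230
#' @export
lowerGammaExt <- function(s, x) {
  if (length(s) != 1L || !is.finite(s))
    stop("'s' must be a single finite number")
  if (s <= -1 || s == 0)
    stop("shape 's' must lie in (-1, 0) or (0, Inf); got ", s)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and nonnegative")
  if (s < 0 && any(x == 0))
    stop("gamma(s, 0) diverges for negative shape")
  if (s > 0)
    return(gamma(s) * stats::pgamma(x, s))
  gamma(s) - vapply(x, function(xi) .upperGammaScalar(s, xi), numeric(1))
}

## Gamma(s, a) - Gamma(s, b) for 0 <= a <= b, elementwise; equals
## gamma(s, b) - gamma(s, a) and is the cancellation-safe building block of
## the occupancy formulas (the a-term dominates, so no subtractive loss).
.upperGammaDiff <- function(s, a, b) {
  stopifnot(length(a) == length(b))
  if (any(b < a)) stop("'a' must not exceed 'b'")
  if (s > 0) {
    ## use upper tails so that large a, b (both tails ~ 0) stay accurate
    gamma(s) * (stats::pgamma(a, s, lower.tail = FALSE) -
                stats::pgamma(b, s, lower.tail = FALSE))
  } else {
    ga <- vapply(a, function(x) .upperGammaScalar(s, x), numeric(1))
    gb <- vapply(b, function(x) .upperGammaScalar(s, x), numeric(1))
    ga - gb
  }
}
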