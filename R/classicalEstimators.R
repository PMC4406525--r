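#' @include modelFitting.R
NULL

#' Capture-recapture (Lincoln-Petersen) richness estimate
#'
#' Treats two samples as capture occasions for category kinds:
#' \deqn{\hat S = \frac{|unique(A)| \cdot |unique(B)|}{|unique(A) \cap
#'   unique(B)|}.}
#' The intersection denominator is the Lincoln-Petersen analog and the
#' default; a union-denominator variant is available via `denominator`.
#'
#' @param sampleA,sampleB Two [ObservedSample]s (matched by category
#'   label).
#' @param denominator `"intersection"` (default) or `"union"`.
#' @return Richness estimate.
#' @seealso [splitSample()] to form the two halves from one sample.
#' @export
captureRecapture <- function(sampleA, sampleB,
                             denominator = c("intersection", "union")) {
  stopifnot(is(sampleA, "ObservedSample"), is(sampleB, "ObservedSample"))
  denominator <- match.arg(denominator)
  a <- names(categoryCounts(sampleA))
  b <- names(categoryCounts(sampleB))
  denom <- if (denominator == "intersection") length(intersect(a, b))
           else length(union(a, b))
  if (denom == 0)
    stop("the two samples share no category; the capture-recapture ",
         "estimate is undefined -- deepen the samples")
  length(a) * length(b) / denom
}

#' Split a sample into two random halves
#'
#' Divides the draws of one sample into two equal halves without
#' replacement (multivariate hypergeometric on the category counts; for an
#' odd total the halves differ by one draw).  The two halves always
#' reconstitute the input counts exactly.  Deterministic given `seed`.
#'
#' @param sample An [ObservedSample] with at least 2 draws.
#' @param seed Integer RNG seed.
#' @return A list of two [ObservedSample]s, `A` and `B`.
#' @export
splitSample <- function(sample, seed = 1L) {
  stopifnot(is(sample, "ObservedSample"))
  y <- categoryCounts(sample)
  r <- sum(y)
  if (r < 2) stop("at least two draws are required")
  half <- floor(r / 2)
  ## sequential conditional hypergeometric draw of the half-sample
  a <- withSeed(seed, {
    out <- numeric(length(y))
    remaining <- r
    k <- half
    for (j in seq_along(y)) {
      out[j] <- stats::rhyper(1, y[j], remaining - y[j], k)
      k <- k - out[j]
      remaining <- remaining - y[j]
    }
    out
  })
  names(a) <- names(y)
  b <- y - a
  list(A = ObservedSample(a[a > 0]), B = ObservedSample(b[b > 0]))
}

#' First-order jackknife richness estimate
#'
#' \deqn{\hat S = S_{obs} + K_{n,1}\,(R - 1)/R,} where \eqn{K_{n,1}} is
#' the singleton count and \eqn{R} the number of draws.
#'
#' @param sample An [ObservedSample] with at least 2 draws.
#' @return Richness estimate, at least the observed richness.
#' @export
jackknife1 <- function(sample) {
  stopifnot(is(sample, "ObservedSample"))
  r <- totalDraws(sample)
  if (r < 2) stop("at least two draws are required")
  nUnique(sample) + nSingletons(sample) * (r - 1) / r
}

#' Chao1 richness estimate
#'
#' \deqn{\hat S = S_{obs} + f_1^2 / (2 f_2)} with singleton count
#' \eqn{f_1} and doubleton count \eqn{f_2}; when \eqn{f_2 = 0} the
#' bias-corrected form \eqn{S_{obs} + f_1 (f_1 - 1) / 2} is used.
#'
#' @param sample A nonempty [ObservedSample].
#' @return Richness estimate, at least the observed richness.
#' @export
chao1 <- function(sample) {
  stopifnot(is(sample, "ObservedSample"))
  y <- categoryCounts(sample)
  f1 <- sum(y == 1)
  f2 <- sum(y == 2)
  s <- length(y)
  if (f2 > 0) s + f1^2 / (2 * f2)
  else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Abundance-based coverage estimator (ACE)
#'
#' Splits categories into rare (count <= `rareCutoff`, default 10) and
#' abundant groups; estimates the rare group's sample coverage as
#' \eqn{\hat C = 1 - f_1 / N_{rare}} and corrects for heterogeneity via
#' the squared coefficient of variation:
#' \deqn{\hat S = S_{abund} + S_{rare}/\hat C + (f_1/\hat C)\,
#'   \hat\gamma^2, \qquad \hat\gamma^2 = \max\left(\frac{S_{rare}}{\hat C}
#'   \frac{\sum_i i(i-1) f_i}{N_{rare}(N_{rare}-1)} - 1,\, 0\right).}
#' When every rare category is a singleton the coverage estimate is zero;
#' the function then falls back to [chao1()] with a warning and marks the
#' result with attribute `fallback = TRUE`.
#'
#' @param sample An [ObservedSample] with at least one rare category.
#' @param rareCutoff Count threshold defining the rare group (default 10).
#' @return Richness estimate.
#' @export
ace <- function(sample, rareCutoff = 10) {
  stopifnot(is(sample, "ObservedSample"))
  y <- categoryCounts(sample)
  rare <- y[y <= rareCutoff]
  if (length(rare) == 0L)
    stop("no category with count <= ", rareCutoff,
         "; ACE is undefined for this sample")
  sAbund <- sum(y > rareCutoff)
  sRare <- length(rare)
  nRare <- sum(rare)
  f1 <- sum(rare == 1)
  cHat <- 1 - f1 / nRare
  if (cHat <= 0) {
    warning("rare group is all singletons (coverage estimate 0); ",
            "falling back to Chao1")
    out <- chao1(sample)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  fi <- tabulate(rare, nbins = rareCutoff)
  i <- seq_len(rareCutoff)
  gamma2 <- max(sRare / cHat * sum(i * (i - 1) * fi) /
                  (nRare * (nRare - 1)) - 1, 0)
  sAbund + sRare / cHat + f1 / cHat * gamma2
}
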