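#' @include AllGenerics.R
NULL

## alpha values for which the closed forms are accepted.  The formulas have
## removable singularities at alpha = 1 and alpha = 2; rather than carrying
## limit branches we reject a narrow guard interval around 1 and everything
## at/above 2 - 1e-3.  Haplotype-regime fits live in (1.4, 1.9), allele-regime
## fits in (0.93, 1.3), so the guard excludes no case of practical interest.
.ALPHA_GUARD <- 1e-3

.checkAlpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    return("'alpha' must be a single finite number")
  if (alpha <= 0)
    return("'alpha' must be positive")
  if (alpha >= 2 - .ALPHA_GUARD)
    return(sprintf(
      "alpha = %g is at or above the singular exponent 2 (guarded at %g)",
      alpha, 2 - .ALPHA_GUARD))
  if (abs(alpha - 1) <= .ALPHA_GUARD)
    return(sprintf(
      "alpha = %g lies in the guard interval around the singular exponent 1",
      alpha))
  NULL
}

#' Truncated power-law frequency model
#'
#' The population model for category (haplotype or allele) relative
#' frequencies: a count density \eqn{\mu(x) = A x^{-\alpha}} supported on
#' \eqn{[x_{min}, x_{max}]}, normalized so that the total probability mass
#' \eqn{\int x \mu(x) dx = 1}.  `alpha` is the exponent on the density
#' scale (one more than the exceedance-scale exponent).  `nTotal`, when
#' given, is the total number of haplotype draws in the population (for
#' diploid persons, twice the census count -- the caller chooses whether to
#' apply the factor of two) and enforces \eqn{x_{min} \ge 1/n_{total}}.
#'
#' @param alpha Density exponent, in \eqn{(0, 2)} excluding a narrow guard
#'   interval around the singular value 1.
#' @param xMin,xMax Support bounds, \eqn{0 < x_{min} < x_{max} \le 1}.
#' @param nTotal Optional total number of draws in the population.
#' @return A `TruncatedPowerLaw` object.
#' @examples
#' m <- TruncatedPowerLaw(alpha = 1.5, xMin = 1e-6, xMax = 1e-2)
#' totalUnique(m)
#' @aliases TruncatedPowerLaw-class
#' @export
TruncatedPowerLaw <- function(alpha, xMin, xMax, nTotal = NA_real_) {
  new("TruncatedPowerLaw", alpha = as.numeric(alpha), xMin = as.numeric(xMin),
      xMax = as.numeric(xMax), nTotal = as.numeric(nTotal))
}

#' @rdname TruncatedPowerLaw
#' @exportClass TruncatedPowerLaw
setClass("TruncatedPowerLaw",
         representation(alpha = "numeric", xMin = "numeric",
                        xMax = "numeric", nTotal = "numeric"),
         prototype(nTotal = NA_real_))

setValidity("TruncatedPowerLaw", function(object) {
  msg <- .checkAlpha(object@alpha)
  if (!is.null(msg)) return(msg)
  if (length(object@xMin) != 1L || length(object@xMax) != 1L ||
      !is.finite(object@xMin) || !is.finite(object@xMax))
    return("'xMin' and 'xMax' must be single finite numbers")
  if (!(object@xMin > 0 && object@xMin < object@xMax && object@xMax <= 1))
    return("support bounds must satisfy 0 < xMin < xMax <= 1")
  if (length(object@nTotal) != 1L)
    return("'nTotal' must be a single number (or NA)")
  if (!is.na(object@nTotal)) {
    if (object@nTotal < 2 || object@nTotal != round(object@nTotal))
      return("'nTotal' must be a positive integer >= 2")
    if (object@xMin < 1 / object@nTotal - 1e-12)
      return("'xMin' must be at least 1/nTotal")
  }
  TRUE
})

setMethod("show", "TruncatedPowerLaw", function(object) {
  cat("TruncatedPowerLaw model\n")
  cat(sprintf("  alpha : %.6g\n", object@alpha))
  cat(sprintf("  xMin  : %.6g\n", object@xMin))
  cat(sprintf("  xMax  : %.6g\n", object@xMax))
  if (!is.na(object@nTotal))
    cat(sprintf("  nTotal: %.6g\n", object@nTotal))
  cat(sprintf("  H (expected unique categories): %.6g\n",
              totalUnique(object)))
  invisible(object)
})

#' Synthetic population of category probabilities
#'
#' A realized population: a vector of per-category probabilities summing to
#' one, the generating [TruncatedPowerLaw] model, and the RNG seed used.
#'
#' @param probabilities Numeric vector of per-category probabilities.
#' @param model Generating [TruncatedPowerLaw].
#' @param seed Integer seed used to generate `probabilities`.
#' @return A `SyntheticPopulation` object.
#' @seealso [generatePopulation()], [sampleFrequencies()]
#' @aliases SyntheticPopulation-class
#' @export
SyntheticPopulation <- function(probabilities, model, seed) {
  new("SyntheticPopulation", probabilities = as.numeric(probabilities),
      model = model, seed = as.integer(seed))
}

#' @rdname SyntheticPopulation
#' @exportClass SyntheticPopulation
setClass("SyntheticPopulation",
         representation(probabilities = "numeric",
                        model = "TruncatedPowerLaw",
                        seed = "integer"))

setValidity("SyntheticPopulation", function(object) {
  p <- object@probabilities
  if (length(p) < 1L) return("at least one category is required")
  if (any(!is.finite(p)) || any(p <= 0))
    return("all probabilities must be finite and > 0")
  if (abs(sum(p) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("probabilities", "SyntheticPopulation",
          function(x) x@probabilities)

#' Number of categories in a synthetic population
#' @param x A [SyntheticPopulation].
#' @return Integer category count.
#' @export
populationSize <- function(x) {
  stopifnot(is(x, "SyntheticPopulation"))
  length(x@probabilities)
}

setMethod("show", "SyntheticPopulation", function(object) {
  cat(sprintf("SyntheticPopulation: %d categories (seed %d)\n",
              length(object@probabilities), object@seed))
  cat(sprintf("  generating model: alpha=%.4g, xMin=%.4g, xMax=%.4g\n",
              object@model@alpha, object@model@xMin, object@model@xMax))
  invisible(object)
})

#' Observed category counts from one sample
#'
#' Holds positive integer counts per category label, the primitive consumed
#' by every estimator.  Derived quantities: `totalDraws` (the sample size
#' \eqn{R = \sum y_j}), `nUnique` (the number of observed categories
#' \eqn{K_n}), `nSingletons` (the number observed exactly once,
#' \eqn{K_{n,1}}) and `relFrequencies` (\eqn{p_j = y_j / R}).
#'
#' @param counts Named (or unnamed, then auto-labelled) vector of positive
#'   integer counts.
#' @return An `ObservedSample` object.
#' @examples
#' s <- ObservedSample(c(a = 8, b = 4, c = 2, d = 1, e = 1))
#' nUnique(s); nSingletons(s); totalDraws(s)
#' @aliases ObservedSample-class
#' @export
ObservedSample <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(names(counts) == ""))
    names(counts) <- sprintf("cat%06d", seq_along(counts))
  new("ObservedSample",
      counts = stats::setNames(as.numeric(counts), names(counts)))
}

#' @rdname ObservedSample
#' @exportClass ObservedSample
setClass("ObservedSample", representation(counts = "numeric"))

setValidity("ObservedSample", function(object) {
  y <- object@counts
  if (length(y) < 1L) return("sample must contain at least one category")
  if (any(!is.finite(y)) || any(y < 1) || any(y != round(y)))
    return("all counts must be positive integers")
  if (is.null(names(y)) || anyDuplicated(names(y)))
    return("category labels must be present and unique")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("categoryCounts", "ObservedSample", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("totalDraws", "ObservedSample", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("nUnique", "ObservedSample", function(x) length(x@counts))

#' @rdname accessors
#' @export
setMethod("nSingletons", "ObservedSample", function(x) sum(x@counts == 1))

#' @rdname accessors
#' @export
setMethod("relFrequencies", "ObservedSample",
          function(x) x@counts / sum(x@counts))

setMethod("show", "ObservedSample", function(object) {
  cat(sprintf(
    "ObservedSample: %d categories, %g draws (%d singletons, %.1f%%)\n",
    nUnique(object), totalDraws(object), nSingletons(object),
    100 * nSingletons(object) / nUnique(object)))
  invisible(object)
})

#' Empirical discovery curve
#'
#' Sample sizes paired with mean observed unique-category counts, the target
#' of the model fit.  `freqMin`/`freqMax` record the smallest and largest
#' observed relative frequency of the source sample and `alphaGuess` a
#' direct exponent estimate from it; they seed the optimizer's bounds and
#' initial point and may be `NA` for analytically constructed curves.
#'
#' @param r Strictly increasing sample sizes.
#' @param uObs Mean observed unique-category counts at each `r`.
#' @param reps Replicate count behind each mean (recycled).
#' @param freqMin,freqMax Range of observed relative frequencies in the
#'   source sample (optional).
#' @param alphaGuess Direct exponent estimate from the source sample
#'   (optional).
#' @param provenance Free-text source identifier.
#' @return A `DiscoveryCurve` object.
#' @seealso [empiricalDiscoveryCurve()], [fitModel()]
#' @aliases DiscoveryCurve-class
#' @export
DiscoveryCurve <- function(r, uObs, reps = 1L, freqMin = NA_real_,
                           freqMax = NA_real_, alphaGuess = NA_real_,
                           provenance = "") {
  pts <- data.frame(r = as.numeric(r), uObs = as.numeric(uObs),
                    reps = as.integer(rep_len(reps, length(r))))
  new("DiscoveryCurve", points = pts, freqMin = as.numeric(freqMin),
      freqMax = as.numeric(freqMax), alphaGuess = as.numeric(alphaGuess),
      provenance = as.character(provenance))
}

#' @rdname DiscoveryCurve
#' @exportClass DiscoveryCurve
setClass("DiscoveryCurve",
         representation(points = "data.frame", freqMin = "numeric",
                        freqMax = "numeric", alphaGuess = "numeric",
                        provenance = "character"))

setValidity("DiscoveryCurve", function(object) {
  pts <- object@points
  if (!all(c("r", "uObs", "reps") %in% names(pts)))
    return("points must have columns r, uObs, reps")
  if (nrow(pts) < 1L) return("curve must contain at least one point")
  if (any(diff(pts$r) <= 0)) return("sample sizes r must strictly increase")
  if (any(pts$uObs < 1)) return("observed unique counts must be >= 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("curvePoints", "DiscoveryCurve", function(x) x@points)

setMethod("show", "DiscoveryCurve", function(object) {
  pts <- object@points
  cat(sprintf("DiscoveryCurve: %d points, r in [%g, %g]\n",
              nrow(pts), min(pts$r), max(pts$r)))
  if (nzchar(object@provenance))
    cat("  source:", object@provenance, "\n")
  invisible(object)
})

#' Result of a discovery-curve model fit
#'
#' Fitted truncated power-law parameters together with the implied total
#' richness, the final cost, the optimizer's starting point and a
#' convergence flag.  Use [fittedModel()] to obtain the corresponding
#' [TruncatedPowerLaw], and [extrapolate()] to project richness and
#' coverage to other population sizes.
#'
#' @aliases FitResult-class
#' @seealso [fitModel()]
#' @name FitResult
NULL

#' @rdname FitResult
#' @exportClass FitResult
setClass("FitResult",
         representation(alphaHat = "numeric", xMinHat = "numeric",
                        xMaxHat = "numeric", hHat = "numeric",
                        cost = "numeric", initialGuess = "numeric",
                        nTotal = "numeric", converged = "logical",
                        nCurvePoints = "integer"))

setValidity("FitResult", function(object) {
  if (object@cost < 0) return("cost must be nonnegative")
  if (!is.na(object@nTotal) && object@xMinHat < 1 / object@nTotal - 1e-12)
    return("xMinHat must be at least 1/nTotal")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("alphaHat", "FitResult", function(x) x@alphaHat)

#' @rdname accessors
#' @export
setMethod("fittedModel", "FitResult", function(x)
  TruncatedPowerLaw(x@alphaHat, x@xMinHat, x@xMaxHat, x@nTotal))

setMethod("show", "FitResult", function(object) {
  cat("FitResult (truncated power-law discovery-curve fit)\n")
  cat(sprintf("  alphaHat : %.4f\n", object@alphaHat))
  cat(sprintf("  xMinHat  : %.4g\n", object@xMinHat))
  cat(sprintf("  xMaxHat  : %.4g\n", object@xMaxHat))
  cat(sprintf("  hHat     : %.6g\n", object@hHat))
  cat(sprintf("  cost     : %.4g over %d curve points\n",
              object@cost, object@nCurvePoints))
  cat(sprintf("  converged: %s\n", object@converged))
  invisible(object)
})

#' Population frequency table
#'
#' A delimited-text-backed table of category relative frequencies (and
#' optionally counts) for one population.  `kind` distinguishes six-locus
#' haplotype tables (categories are `~`-joined allele strings) from
#' single-locus allele tables.
#'
#' @param records `data.frame` with columns `category`, `frequency` and
#'   optionally `count`.
#' @param population Population label.
#' @param kind `"haplotype"` or `"allele"`.
#' @param locus Locus label for allele tables.
#' @return A `FrequencyTable` object.
#' @seealso [readFrequencyTable()], [allelesFromHaplotypes()]
#' @aliases FrequencyTable-class
#' @export
FrequencyTable <- function(records, population = "", kind = "haplotype",
                           locus = NA_character_) {
  if (!"count" %in% names(records)) records$count <- NA_real_
  records <- records[, c("category", "frequency", "count")]
  records$category <- as.character(records$category)
  o <- order(-records$frequency, records$category)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  new("FrequencyTable", records = records,
      population = as.character(population), kind = as.character(kind),
      locus = as.character(locus))
}

#' @rdname FrequencyTable
#' @exportClass FrequencyTable
setClass("FrequencyTable",
         representation(records = "data.frame", population = "character",
                        kind = "character", locus = "character"))

setValidity("FrequencyTable", function(object) {
  rec <- object@records
  if (!all(c("category", "frequency") %in% names(rec)))
    return("records must have 'category' and 'frequency' columns")
  if (anyDuplicated(rec$category))
    return("category labels must be unique within a table")
  if (any(!is.finite(rec$frequency)) || any(rec$frequency < 0))
    return("frequencies must be finite and nonnegative")
  if (abs(sum(rec$frequency) - 1) > 1e-6)
    return("frequencies must sum to 1 within 1e-6")
  if ("count" %in% names(rec) && any(!is.na(rec$count) & rec$count <= 0))
    return("counts, when present, must be positive")
  if (!object@kind %in% c("haplotype", "allele"))
    return("kind must be 'haplotype' or 'allele'")
  TRUE
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable (%s%s): %d categories",
              object@kind,
              if (!is.na(object@locus)) paste0(", locus ", object@locus)
              else "",
              nrow(object@records)))
  if (nzchar(object@population))
    cat(", population", object@population)
  cat("\n")
  invisible(object)
})

#' Records of a frequency table
#' @param x A [FrequencyTable].
#' @return `data.frame` with columns `category`, `frequency`, `count`.
#' @export
tableRecords <- function(x) {
  stopifnot(is(x, "FrequencyTable"))
  x@records
}
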