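#' @rdname normalizationConstant
#' @export
setGeneric("normalizationConstant",
           function(model) standardGeneric("normalizationConstant"))

#' @rdname countDensity
#' @export
setGeneric("countDensity",
           function(model, x) standardGeneric("countDensity"))

#' @rdname exceedance
#' @export
setGeneric("exceedance",
           function(model, x) standardGeneric("exceedance"))

#' @rdname totalUnique
#' @export
setGeneric("totalUnique",
           function(model) standardGeneric("totalUnique"))

#' @rdname sampleFrequencies
#' @export
setGeneric("sampleFrequencies",
           function(model, seed) standardGeneric("sampleFrequencies"))

#' @rdname expectedUnique
#' @export
setGeneric("expectedUnique",
           function(model, r) standardGeneric("expectedUnique"))

#' @rdname fractionCovered
#' @export
setGeneric("fractionCovered",
           function(model, r) standardGeneric("fractionCovered"))

#' @rdname probUnseen
#' @export
setGeneric("probUnseen",
           function(model, r) standardGeneric("probUnseen"))

#' Accessors for package classes
#'
#' Small typed accessors used instead of direct slot access.
#'
#' @param x An object of the documented class.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname accessors
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

#' @rdname accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname accessors
#' @export
setGeneric("totalDraws", function(x) standardGeneric("totalDraws"))

#' @rdname accessors
#' @export
setGeneric("nUnique", function(x) standardGeneric("nUnique"))

#' @rdname accessors
#' @export
setGeneric("nSingletons", function(x) standardGeneric("nSingletons"))

#' @rdname accessors
#' @export
setGeneric("relFrequencies", function(x) standardGeneric("relFrequencies"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))
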