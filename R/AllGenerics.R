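#' @importFrom BiocGenerics counts sizeFactors sizeFactors<-
#'   estimateSizeFactors conditions
NULL

#' Fitted variance functions stored in a CountDataSet
#'
#' @param object a \linkS4class{CountDataSet}.
#' @return named list of \linkS4class{VarianceFunction} objects, one per
#'   condition (empty before \code{\link{estimateVarianceFunctions}} is run).
#' @export
setGeneric("varianceFunctions",
    function(object) standardGeneric("varianceFunctions"))

#' Estimate per-condition variance-mean functions
#'
#' @param object a \linkS4class{CountDataSet} with size factors.
#' @param ... further arguments; see the method for
#'   \linkS4class{CountDataSet}.
#' @export
setGeneric("estimateVarianceFunctions",
    function(object, ...) standardGeneric("estimateVarianceFunctions"))

#' Evaluate the fitted sample-variance function w(q)
#'
#' @param object a \linkS4class{VarianceFunction}.
#' @param q vector of common-scale means (q >= 0) at which to evaluate.
#' @return fitted w(q), linearly interpolated in log q between knots and
#'   continued at constant squared coefficient of variation outside the
#'   fitted domain.
#' @export
setGeneric("fittedW", function(object, q) standardGeneric("fittedW"))

#' Evaluate the estimated raw (biological) variance v(q)
#'
#' @param object a \linkS4class{VarianceFunction}.
#' @param q vector of common-scale means (q >= 0).
#' @return max(0, fittedW(q) - q * biasCoefficient): the fitted variance with
#'   the expected shot-noise contribution removed, clamped at zero so that
#'   the negative binomial constraint variance >= mean always holds.
#' @export
setGeneric("rawVariance", function(object, q) standardGeneric("rawVariance"))
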