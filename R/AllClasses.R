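#' @import methods
#' @importFrom stats approx median p.adjust pchisq pgamma quantile rgamma
#'   rpois runif sd var dnbinom dpois setNames ks.test rnbinom dist
#'   glm.fit lm.wfit Gamma
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CountDataSet: counts, conditions, size factors and fitted variance functions
#'
#' The central container of the package. It extends
#' \linkS4class{SummarizedExperiment} with a single assay \code{"counts"}
#' holding the n-genes x m-samples matrix of non-negative integer read
#' counts, a \code{condition} column in \code{colData} assigning each sample
#' to an experimental condition, an optional \code{sizeFactor} column with
#' the per-sample coverage factors, and a \code{fitInfo} slot holding the
#' per-condition fitted \linkS4class{VarianceFunction} objects.
#'
#' @slot fitInfo list of \linkS4class{VarianceFunction} objects, one per
#'   condition, filled by \code{\link{estimateVarianceFunctions}}.
#'
#' @seealso \code{\link{newCountDataSet}}, \code{\link{estimateSizeFactors}},
#'   \code{\link{estimateVarianceFunctions}}, \code{\link{nbinomTest}}
#' @export
setClass("CountDataSet",
    contains = "SummarizedExperiment",
    representation(fitInfo = "list"),
    prototype(fitInfo = list()))

setValidity("CountDataSet", function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is missing")
    else {
        k <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(k))
            msg <- c(msg, "counts must be numeric")
        else {
            bad <- which(!is.finite(k) | k < 0 | k != round(k))
            if (length(bad) > 0) {
                ij <- arrayInd(bad[1], dim(k))
                msg <- c(msg, sprintf(
                    "counts must be non-negative integers; offending cell: row %d ('%s'), column %d ('%s')",
                    ij[1], rownames(k)[ij[1]], ij[2], colnames(k)[ij[2]]))
            }
        }
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicate gene IDs")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicate sample names")
    }
    if (!("condition" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain a 'condition' column")
    if ("sizeFactor" %in% colnames(SummarizedExperiment::colData(object))) {
        sf <- object$sizeFactor
        if (!all(is.na(sf)) && any(!is.na(sf) & (!is.finite(sf) | sf <= 0)))
            msg <- c(msg, "size factors must be strictly positive and finite")
    }
    if (is.null(msg)) TRUE else msg
})

#' VarianceFunction: smooth raw-variance-versus-mean fit for one condition
#'
#' Represents the smooth function w(q) obtained by gamma-family local
#' regression of the common-scale sample variances on the common-scale means,
#' together with the per-condition shot-noise (bias) coefficient needed to
#' recover the raw variance estimate v(q) = max(0, w(q) - q * biasCoefficient).
#' The fit is stored as a grid of knots equally spaced in log q with linear
#' interpolation between them; outside the fitted domain the function is
#' continued at constant squared coefficient of variation, with the
#' shot-noise part re-added.
#'
#' @slot condition condition label the function applies to.
#' @slot logQKnots knot positions on the log(q) scale.
#' @slot fittedW fitted values of w at the knots.
#' @slot biasCoefficient sum over the condition's samples of 1/s_j, divided
#'   by the number of replicates; multiplies q to give the expected
#'   shot-noise contribution to the sample variance.
#' @slot fitDomain range c(qmin, qmax) of the means used in the fit.
#' @slot settings list of fit settings (span, nKnots, minGenes, fallbacks).
#'
#' @seealso \code{\link{fitVarianceFunction}}, \code{\link{fittedW}},
#'   \code{\link{rawVariance}}
#' @export
setClass("VarianceFunction",
    representation(
        condition = "character",
        logQKnots = "numeric",
        fittedW = "numeric",
        biasCoefficient = "numeric",
        fitDomain = "numeric",
        settings = "list"))

setValidity("VarianceFunction", function(object) {
    msg <- NULL
    if (length(object@logQKnots) != length(object@fittedW))
        msg <- c(msg, "knot and fitted-value vectors differ in length")
    if (length(object@logQKnots) >= 2 && is.unsorted(object@logQKnots))
        msg <- c(msg, "knots must be sorted")
    if (any(!is.finite(object@fittedW)) || any(object@fittedW < 0))
        msg <- c(msg, "fitted w must be finite and non-negative")
    if (length(object@biasCoefficient) != 1 || object@biasCoefficient < 0)
        msg <- c(msg, "biasCoefficient must be a single non-negative number")
    if (length(object@fitDomain) != 2 || any(object@fitDomain <= 0))
        msg <- c(msg, "fitDomain must be two positive numbers")
    if (is.null(msg)) TRUE else msg
})

#' VSTransform: variance-stabilizing transformation from a variance function
#'
#' Stores the monotone mapping tau(kappa) = integral_0^kappa dq / sqrt(w(q))
#' as cumulative-integral knots, parameterized in u = sqrt(kappa) so that the
#' Poisson limit (w(q) = q, tau = 2 sqrt(kappa)) is represented exactly by
#' linear interpolation. The integrand's variance law is kept as a function
#' slot so that evaluation beyond the precomputed knot range can extend the
#' integral on demand.
#'
#' @slot uKnots knots on the u = sqrt(kappa) scale (first knot is 0).
#' @slot tauKnots cumulative integral values at the knots; tau(0) = 0.
#' @slot wfun the variance law w(q) integrated against.
#' @slot source identifier of the variance function the transform came from.
#' @export
setClass("VSTransform",
    representation(
        uKnots = "numeric",
        tauKnots = "numeric",
        wfun = "function",
        source = "character"))

setValidity("VSTransform", function(object) {
    msg <- NULL
    if (length(object@uKnots) != length(object@tauKnots))
        msg <- c(msg, "knot vectors differ in length")
    if (length(object@uKnots) < 2)
        msg <- c(msg, "need at least two knots")
    if (object@uKnots[1] != 0 || object@tauKnots[1] != 0)
        msg <- c(msg, "tau must be anchored at tau(0) = 0")
    if (is.unsorted(object@uKnots) || is.unsorted(object@tauKnots))
        msg <- c(msg, "tau must be non-decreasing")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CountDataSet", function(object) {
    cat("CountDataSet with", nrow(object), "genes and", ncol(object),
        "samples\n")
    cond <- conditions(object)
    cat("conditions:",
        paste(sprintf("%s (m=%d)", names(table(cond)), table(cond)),
              collapse = ", "), "\n")
    sf <- suppressWarnings(sizeFactors(object))
    if (is.null(sf) || all(is.na(sf)))
        cat("size factors: not estimated\n")
    else
        cat("size factors:", paste(format(sf, digits = 4), collapse = " "),
            "\n")
    if (length(object@fitInfo))
        cat("variance functions fitted for:",
            paste(names(object@fitInfo), collapse = ", "), "\n")
})

setMethod("show", "VarianceFunction", function(object) {
    cat("VarianceFunction for condition '", object@condition, "'\n", sep = "")
    cat(sprintf("  fit domain: q in [%.4g, %.4g], %d knots\n",
        object@fitDomain[1], object@fitDomain[2], length(object@logQKnots)))
    cat(sprintf("  bias coefficient: %.4g\n", object@biasCoefficient))
})

setMethod("show", "VSTransform", function(object) {
    cat("VSTransform (", length(object@uKnots), " knots, kappa up to ",
        format(max(object@uKnots)^2, digits = 4), ") from ", object@source,
        "\n", sep = "")
})
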