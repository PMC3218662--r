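#' Per-condition common-scale moments
#'
#' For one experimental condition, computes per gene the common-scale mean
#' \eqn{\hat{q}_{i\rho}} (average of k_ij / s_j over the condition's
#' replicates), the common-scale sample variance \eqn{w_{i\rho}}, and the
#' shot-noise bias term
#' \eqn{z_{i\rho} = (\hat{q}_{i\rho}/m_\rho)\sum_j 1/\hat{s}_j}.
#' The difference w - z is an unbiased estimator of the raw variance.
#'
#' @param object a \linkS4class{CountDataSet} with size factors.
#' @param condition condition label.
#' @param requireVariance if TRUE (default), error when the condition has
#'   fewer than 2 replicates so that no sample variance exists; if FALSE,
#'   return the means with NA variances.
#' @return \link[S4Vectors]{DataFrame} with columns baseMean,
#'   sampleVariance, biasTerm; metadata holds condition, nReplicates and
#'   biasCoefficient (\eqn{\sum_j (1/\hat{s}_j) / m_\rho}).
#' @export
conditionMoments <- function(object, condition, requireVariance = TRUE) {
    sf <- sizeFactors(object)
    if (is.null(sf))
        stop("size factors not available; run estimateSizeFactors() first")
    sel <- conditions(object) == condition
    if (!any(sel))
        stop("condition '", condition, "' not present in the design")
    m <- sum(sel)
    if (m < 2 && requireVariance)
        stop("condition '", condition, "' has no replicates (m=1); no ",
             "sample variance can be computed. Use variance estimation ",
             "method 'blind' or 'pooled'.")
    cs <- commonScale(counts(object)[, sel, drop = FALSE], sf[sel])
    q <- unname(rowMeans(cs))
    w <- if (m >= 2) unname(apply(cs, 1, var)) else rep(NA_real_, length(q))
    bcoef <- sum(1 / sf[sel]) / m
    out <- S4Vectors::DataFrame(baseMean = q, sampleVariance = w,
                                biasTerm = q * bcoef,
                                row.names = rownames(object))
    S4Vectors::metadata(out) <- list(condition = condition, nReplicates = m,
                                     biasCoefficient = bcoef)
    out
}

#' Unbiased per-gene raw-variance estimates
#'
#' Returns w - z per gene. Individual values may be negative (expected for
#' shot-noise-dominated genes); clamping happens only at the fitted-function
#' level.
#'
#' @param moments output of \code{\link{conditionMoments}}.
#' @return numeric vector of per-gene raw-variance estimates.
#' @export
unbiasedRawVariance <- function(moments) {
    setNames(moments$sampleVariance - moments$biasTerm, rownames(moments))
}

# Local likelihood fit of a gamma-family GLM: response w (identity scale),
# local quadratic in the predictor log q (degree 2 is the local-regression
# convention and is needed to track the curvature of the shot-noise to
# overdispersion transition under wide bandwidths), tricube kernel weights
# with nearest-neighbour bandwidth, evaluated at each knot. Falls back to
# weighted least squares on log(w) (with half-residual-variance
# back-transform correction) where the IRLS does not converge.
localGammaRegression <- function(logq, w, knots, span) {
    N <- length(logq)
    kNN <- min(N, max(4L, ceiling(span * N)))
    fitted <- numeric(length(knots))
    nFallback <- 0L
    for (k in seq_along(knots)) {
        x0 <- knots[k]
        d <- abs(logq - x0)
        h <- sort(d, partial = kNN)[kNN]
        if (h <= 0) h <- .Machine$double.eps + max(d) * 1e-12
        sel <- which(d < h)
        if (length(sel) < 3) sel <- order(d)[seq_len(min(4L, N))]
        tri <- (1 - pmin(abs(logq[sel] - x0) / h, 1)^3)^3
        tri[tri <= 0] <- min(tri[tri > 0], 1e-8)
        dx <- logq[sel] - x0
        X <- cbind(1, dx, dx^2)
        y <- w[sel]
        val <- tryCatch({
            fit <- suppressWarnings(
                glm.fit(X, y, weights = tri,
                        family = Gamma(link = "log"),
                        control = list(maxit = 50)))
            if (!fit$converged || !is.finite(fit$coefficients[1]))
                stop("IRLS did not converge")
            exp(fit$coefficients[1])
        }, error = function(e) NA_real_)
        if (is.na(val)) {
            # weighted least squares on the log scale, bias-corrected
            nFallback <- nFallback + 1L
            ly <- log(y)
            fit <- lm.wfit(X, ly, tri)
            s2 <- sum(tri * fit$residuals^2) / sum(tri)
            val <- exp(fit$coefficients[1] + s2 / 2)
        }
        fitted[k] <- val
    }
    if (nFallback > 0)
        message("gamma-family local fit fell back to log-scale weighted ",
                "least squares at ", nFallback, " of ", length(knots),
                " knots")
    fitted
}

#' Fit the smooth variance-mean function w(q) by local regression
#'
#' Fits the conditional mean of the common-scale sample variances w given
#' the common-scale means q, using a local likelihood gamma-family GLM
#' (response w, predictor log q) with tricube kernel weights and a
#' nearest-neighbour bandwidth, evaluated on a knot grid equally spaced in
#' log q between the 0.1\% and 99.9\% quantiles of q; between knots the fit
#' is interpolated linearly in log q. A gamma response family is used
#' because sample variances are sums of squares with strongly right-skewed
#' residuals, which a least-squares fit would handle poorly. Genes with
#' q = 0 carry no variance information and are excluded, as are genes with
#' w = 0 (the gamma likelihood has no mass at zero).
#'
#' @param moments output of \code{\link{conditionMoments}}, or a list/data
#'   frame with elements baseMean and sampleVariance.
#' @param biasCoefficient per-condition shot-noise coefficient
#'   \eqn{\sum_j (1/\hat{s}_j)/m_\rho}; taken from the moments metadata when
#'   omitted.
#' @param condition label stored in the result.
#' @param span nearest-neighbour bandwidth as a fraction of the fitted
#'   points (default 0.7).
#' @param nKnots number of evaluation knots (default 200).
#' @param minGenes minimum number of usable genes (default 50).
#' @return a \linkS4class{VarianceFunction}.
#' @export
fitVarianceFunction <- function(moments, biasCoefficient = NULL,
                                condition = NULL, span = 0.7, nKnots = 200,
                                minGenes = 50) {
    md <- tryCatch(S4Vectors::metadata(moments), error = function(e) list())
    if (is.null(biasCoefficient)) biasCoefficient <- md$biasCoefficient
    if (is.null(biasCoefficient))
        stop("biasCoefficient neither supplied nor found in moments metadata")
    if (is.null(condition))
        condition <- if (!is.null(md$condition)) md$condition else ""
    q <- moments$baseMean
    w <- moments$sampleVariance
    if (all(is.na(w)))
        stop("no sample variances available (unreplicated condition); use ",
             "method 'blind' or 'pooled'")
    use <- which(is.finite(q) & is.finite(w) & q > 0 & w > 0)
    if (length(use) < minGenes)
        stop("too few genes with positive mean and variance to fit (",
             length(use), " < ", minGenes, ")")
    logq <- log(q[use])
    qr <- quantile(q[use], c(0.001, 0.999), names = FALSE)
    if (qr[1] >= qr[2]) qr <- range(q[use])
    knots <- seq(log(qr[1]), log(qr[2]), length.out = nKnots)
    fitted <- localGammaRegression(logq, w[use], knots, span)
    if (any(!is.finite(fitted)))
        stop("variance-function fit failed: non-finite fitted values at ",
             sum(!is.finite(fitted)), " knots")
    new("VarianceFunction", condition = as.character(condition),
        logQKnots = knots, fittedW = pmax(fitted, 0),
        biasCoefficient = biasCoefficient, fitDomain = qr,
        settings = list(span = span, nKnots = nKnots, minGenes = minGenes,
                        nGenesUsed = length(use)))
}

# Boundary continuation at constant raw squared coefficient of variation:
# outside the fitted domain, w(q) = q * biasCoefficient + SCV_b * q^2 with
# SCV_b taken from the boundary knot. Prevents negative or explosive
# extrapolation for extreme-count genes.
.evalFittedW <- function(object, q) {
    stopifnot(all(is.finite(q)), all(q >= 0))
    out <- numeric(length(q))
    lo <- exp(object@logQKnots[1])
    hi <- exp(object@logQKnots[length(object@logQKnots)])
    b <- object@biasCoefficient
    inside <- q >= lo & q <= hi
    if (any(inside))
        out[inside] <- approx(object@logQKnots, object@fittedW,
                              xout = log(q[inside]), rule = 2)$y
    for (side in c("lo", "hi")) {
        idx <- if (side == "lo") which(q < lo & q > 0) else which(q > hi)
        if (!length(idx)) next
        qb <- if (side == "lo") lo else hi
        wb <- if (side == "lo") object@fittedW[1]
              else object@fittedW[length(object@fittedW)]
        scv <- max(0, wb - qb * b) / qb^2
        out[idx] <- q[idx] * b + scv * q[idx]^2
    }
    out[q == 0] <- 0
    out
}

#' @rdname fittedW
#' @export
setMethod("fittedW", "VarianceFunction", function(object, q)
    .evalFittedW(object, q))

#' @rdname rawVariance
#' @export
setMethod("rawVariance", "VarianceFunction", function(object, q)
    pmax(0, .evalFittedW(object, q) - q * object@biasCoefficient))

#' @rdname estimateVarianceFunctions
#' @param method how replicate information is shared across conditions:
#'   \describe{
#'     \item{per-condition}{one fit per condition from its own replicates
#'       (every condition needs at least 2).}
#'     \item{pooled (alias shared-from-replicated)}{one fit from the
#'       combined (q, w) points of all replicated conditions, assigned to
#'       every condition, including unreplicated ones.}
#'     \item{blind}{all samples treated as replicates of one condition;
#'       usable without any replication, conservative when true differential
#'       expression exists.}
#'   }
#' @param span,nKnots,minGenes fit settings, see
#'   \code{\link{fitVarianceFunction}}.
#' @return the \linkS4class{CountDataSet} with one
#'   \linkS4class{VarianceFunction} per condition stored in its fitInfo.
#' @export
setMethod("estimateVarianceFunctions", "CountDataSet",
    function(object, method = c("per-condition", "pooled", "blind",
                                "shared-from-replicated"),
             span = 0.7, nKnots = 200, minGenes = 50) {
    method <- match.arg(method)
    if (method == "shared-from-replicated") method <- "pooled"
    sf <- sizeFactors(object)
    if (is.null(sf))
        stop("size factors not available; run estimateSizeFactors() first")
    conds <- levels(conditions(object))
    mrho <- replicateCounts(object)
    biasCoefOf <- function(cond) {
        sel <- conditions(object) == cond
        sum(1 / sf[sel]) / sum(sel)
    }
    fits <- switch(method,
        "per-condition" = {
            unrep <- names(mrho)[mrho < 2]
            if (length(unrep) > 0)
                stop("condition '", unrep[1], "' has no replicates; use ",
                     "method 'pooled' or 'blind'")
            lapply(setNames(conds, conds), function(cond)
                fitVarianceFunction(conditionMoments(object, cond),
                                    span = span, nKnots = nKnots,
                                    minGenes = minGenes))
        },
        "pooled" = {
            replicated <- names(mrho)[mrho >= 2]
            if (length(replicated) == 0)
                stop("no replicated condition to pool from; use method ",
                     "'blind'")
            pts <- do.call(rbind, lapply(replicated, function(cond) {
                mom <- conditionMoments(object, cond)
                data.frame(baseMean = mom$baseMean,
                           sampleVariance = mom$sampleVariance)
            }))
            lapply(setNames(conds, conds), function(cond)
                fitVarianceFunction(pts, biasCoefficient = biasCoefOf(cond),
                                    condition = cond, span = span,
                                    nKnots = nKnots, minGenes = minGenes))
        },
        "blind" = {
            if (ncol(object) < 2)
                stop("blind variance estimation needs at least 2 samples")
            pooledObj <- object
            pooledObj$condition <- factor(rep("_all_", ncol(object)))
            mom <- conditionMoments(pooledObj, "_all_")
            lapply(setNames(conds, conds), function(cond)
                fitVarianceFunction(mom, biasCoefficient = biasCoefOf(cond),
                                    condition = cond, span = span,
                                    nKnots = nKnots, minGenes = minGenes))
        })
    object@fitInfo <- fits
    object
})

#' Residual diagnostics for a fitted variance function
#'
#' Because sample variances are strongly right-skewed, raw residuals are
#' uninformative. Instead, per gene, the ratio w / w_fit(q) is referred to
#' its theoretical null distribution: for m replicates, a sample variance
#' behaves like a gamma variate with shape (m-1)/2 and mean 1 after scaling
#' by its expectation, so the gamma CDF of the ratio should be approximately
#' uniform on [0, 1] when the fit is well calibrated.
#'
#' @param moments output of \code{\link{conditionMoments}}.
#' @param vf fitted \linkS4class{VarianceFunction} for the same condition.
#' @return data.frame with per-gene columns ratio and quantile (NA for
#'   genes with zero mean or undefined variance).
#' @export
fitDiagnostics <- function(moments, vf) {
    m <- S4Vectors::metadata(moments)$nReplicates
    if (is.null(m) || m < 2)
        stop("diagnostics require a replicated condition")
    q <- moments$baseMean
    w <- moments$sampleVariance
    wf <- fittedW(vf, pmax(q, 0))
    ratio <- ifelse(q > 0 & wf > 0, w / wf, NA_real_)
    shape <- (m - 1) / 2
    data.frame(row.names = rownames(moments), ratio = ratio,
               quantile = pgamma(ratio, shape = shape, rate = shape))
}

#' Export a fitted variance function as a TSV grid with a JSON header
#'
#' The first line is a '#'-prefixed JSON object (condition,
#' bias_coefficient, fit_domain, settings); the body is a TSV of
#' (q, fitted_w, v_hat) rows at the fit knots. Re-importable with
#' \code{\link{readVarianceFunction}}.
#'
#' @param vf a \linkS4class{VarianceFunction}.
#' @param path output path.
#' @export
writeVarianceFunction <- function(vf, path) {
    hdr <- jsonlite::toJSON(list(
        condition = vf@condition,
        bias_coefficient = vf@biasCoefficient,
        fit_domain = vf@fitDomain,
        settings = vf@settings), auto_unbox = TRUE, digits = NA)
    q <- exp(vf@logQKnots)
    body <- data.frame(q = format(q, digits = 15, trim = TRUE),
                       fitted_w = format(vf@fittedW, digits = 15,
                                         trim = TRUE),
                       v_hat = format(rawVariance(vf, q), digits = 15,
                                      trim = TRUE))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeVarianceFunction
#' @return \code{readVarianceFunction}: the reconstructed
#'   \linkS4class{VarianceFunction}.
#' @export
readVarianceFunction <- function(path) {
    lines <- readLines(path)
    if (!startsWith(lines[1], "# "))
        stop("missing JSON header line")
    hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
    df <- read.delim(textConnection(lines[-1]), sep = "\t")
    new("VarianceFunction", condition = hdr$condition,
        logQKnots = log(df$q), fittedW = df$fitted_w,
        biasCoefficient = hdr$bias_coefficient,
        fitDomain = as.numeric(hdr$fit_domain),
        settings = as.list(hdr$settings))
}
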