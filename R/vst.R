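# Cumulative integral of 1/sqrt(w(q)) in the substitution u = sqrt(q):
# integral dq / sqrt(w(q)) = integral 2 u / sqrt(w(u^2)) du, which removes
# the integrable 1/sqrt(q) singularity at 0 (where w(q) ~ c q, the
# integrand tends to the finite limit 2 / sqrt(c)). Composite Simpson per
# interval of the u grid.
.cumIntegralU <- function(wfun, uGrid) {
    stopifnot(uGrid[1] == 0, !is.unsorted(uGrid))
    g <- function(u) {
        out <- numeric(length(u))
        pos <- u > 0
        out[pos] <- 2 * u[pos] / sqrt(wfun(u[pos]^2))
        if (any(!pos)) {
            # limit at 0 from the local slope of w
            u1 <- min(u[pos], uGrid[uGrid > 0][1])
            c0 <- wfun(u1^2) / u1^2
            out[!pos] <- 2 / sqrt(c0)
        }
        out
    }
    a <- uGrid[-length(uGrid)]
    b <- uGrid[-1]
    mid <- (a + b) / 2
    fa <- g(a); fb <- g(b); fm <- g(mid)
    pieces <- (b - a) / 6 * (fa + 4 * fm + fb)
    c(0, cumsum(pieces))
}

#' Build a variance-stabilizing transformation
#'
#' Constructs the monotone mapping
#' \deqn{\tau(\kappa) = \int_0^{\kappa} \frac{dq}{\sqrt{w(q)}}}
#' from a fitted variance function. The variance law integrated against is
#' the full common-scale variance at a reference size factor of one,
#' w(q) = q + v(q): shot noise plus the fitted raw variance. In the Poisson
#' limit (v = 0) this gives tau(kappa) = 2 sqrt(kappa); in the
#' constant-SCV limit (w = alpha q^2) it becomes logarithmic. tau is
#' anchored at tau(0) = 0.
#'
#' @param vf a fitted \linkS4class{VarianceFunction}, or NULL if \code{w}
#'   is given directly.
#' @param w optional variance law as a function of q, overriding the one
#'   derived from \code{vf} (useful for closed-form checks).
#' @param kappaMax upper end of the precomputed knot range; defaults to 10
#'   times the upper end of the fit domain (evaluation beyond it extends
#'   the integral on demand).
#' @param nKnots number of knots, log-spaced in kappa (default 20000; the
#'   density bounds the linear-interpolation error of evaluation well below
#'   1e-6 relative even for steeply logarithmic transforms).
#' @return a \linkS4class{VSTransform}.
#' @export
buildVST <- function(vf = NULL, w = NULL, kappaMax = NULL, nKnots = 20000) {
    if (is.null(w)) {
        if (is.null(vf))
            stop("supply a VarianceFunction or a variance law w")
        wfun <- function(q) q + rawVariance(vf, q)
        src <- paste0("VarianceFunction(", vf@condition, ")")
        if (is.null(kappaMax)) kappaMax <- vf@fitDomain[2] * 10
    } else {
        wfun <- w
        src <- "custom variance law"
        if (is.null(kappaMax))
            stop("kappaMax must be given with a custom variance law")
    }
    probe <- wfun(c(1e-12, kappaMax))
    if (any(probe <= 0))
        stop("w(q) must be strictly positive for q > 0")
    kappaMin <- kappaMax * 1e-10
    uGrid <- c(0, exp(seq(log(sqrt(kappaMin)), log(sqrt(kappaMax)),
                          length.out = nKnots - 1)))
    tau <- .cumIntegralU(wfun, uGrid)
    new("VSTransform", uKnots = uGrid, tauKnots = tau, wfun = wfun,
        source = src)
}

#' Evaluate a variance-stabilizing transformation
#'
#' @param t a \linkS4class{VSTransform}.
#' @param kappa common-scale values (>= 0).
#' @return tau(kappa), interpolated linearly on the u = sqrt(kappa) scale
#'   between the precomputed knots (exact in the Poisson limit); values
#'   beyond the knot range extend the integral numerically.
#' @export
evaluateVST <- function(t, kappa) {
    stopifnot(all(kappa >= 0))
    u <- sqrt(kappa)
    uMax <- t@uKnots[length(t@uKnots)]
    out <- approx(t@uKnots, t@tauKnots, xout = pmin(u, uMax))$y
    over <- which(u > uMax)
    if (length(over)) {
        # extend the cumulative integral from the last knot
        uExt <- c(uMax, exp(seq(log(uMax), log(max(u) * (1 + 1e-12)),
                                length.out = 512))[-1])
        tauExt <- t@tauKnots[length(t@tauKnots)] +
            .cumIntegralU2(t@wfun, uExt)
        out[over] <- approx(uExt, tauExt, xout = u[over], rule = 2)$y
    }
    out
}

# as .cumIntegralU but starting from uGrid[1] > 0
.cumIntegralU2 <- function(wfun, uGrid) {
    g <- function(u) 2 * u / sqrt(wfun(u^2))
    a <- uGrid[-length(uGrid)]
    b <- uGrid[-1]
    mid <- (a + b) / 2
    pieces <- (b - a) / 6 * (g(a) + 4 * g(mid) + g(b))
    c(0, cumsum(pieces))
}

#' Apply a variance-stabilizing transformation to count data
#'
#' Transforms the common-scale counts k_ij / s_j through tau, yielding
#' values whose variance is approximately independent of the mean
#' throughout the dynamic range.
#'
#' @param t a \linkS4class{VSTransform}.
#' @param object a \linkS4class{CountDataSet} with size factors, or a count
#'   matrix (then \code{sf} is required).
#' @param sf size factors (taken from the object when omitted).
#' @return numeric matrix of transformed values, same dimensions as the
#'   counts.
#' @export
applyVST <- function(t, object, sf = NULL) {
    cs <- commonScale(object, sf)
    out <- matrix(evaluateVST(t, as.vector(cs)), nrow = nrow(cs),
                  dimnames = dimnames(cs))
    out
}

#' Euclidean distances between samples
#'
#' Distance matrix between sample columns of a transformed matrix, the
#' input for sample clustering.
#'
#' @param transformed matrix (genes x samples), typically the output of
#'   \code{\link{applyVST}}.
#' @return symmetric m x m matrix with zero diagonal.
#' @export
sampleDistances <- function(transformed) {
    as.matrix(dist(t(transformed)))
}

#' Export tau as a two-column knot table (kappa, tau)
#' @param t a \linkS4class{VSTransform}.
#' @param path output path.
#' @export
writeVST <- function(t, path) {
    write.table(data.frame(kappa = format(t@uKnots^2, digits = 15,
                                          trim = TRUE),
                           tau = format(t@tauKnots, digits = 15,
                                        trim = TRUE)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
}
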