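#' Negative binomial parameters from mean and variance
#'
#' Plain moment matching: size r = mu^2 / (var - mu) and success probability
#' r / (r + mu). When var <= mu the distribution degenerates to Poisson
#' (marked by \code{poisson = TRUE}); when mu = 0 it is a point mass at 0.
#' Kept behind this one constructor so an alternative (bias-corrected)
#' parameterization could be swapped in.
#'
#' @param mean expected count (mu >= 0).
#' @param variance variance (any value <= mean falls back to Poisson).
#' @return list with elements mean, variance, size (NA in the Poisson
#'   limit) and poisson flag, of class "NBParams".
#' @export
nbParams <- function(mean, variance) {
    stopifnot(is.finite(mean), mean >= 0, is.finite(variance))
    poisson <- variance <= mean || mean == 0
    structure(list(
        mean = mean,
        variance = if (poisson) mean else variance,
        size = if (poisson) NA_real_ else mean^2 / (variance - mean),
        poisson = poisson), class = "NBParams")
}

# log pmf of an NBParams at integer x (vectorized in x)
.logPmf <- function(x, p) {
    if (p$mean == 0) return(ifelse(x == 0, 0, -Inf))
    if (p$poisson) dpois(x, p$mean, log = TRUE)
    else dnbinom(x, mu = p$mean, size = p$size, log = TRUE)
}

.logSumExp <- function(lx) {
    m <- max(lx)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(lx - m)))
}

#' Summed-count NB parameters for one condition
#'
#' Under the null hypothesis of equal expression strength, the total count
#' of a condition is a sum of NB variables; its distribution is
#' approximated by a single NB whose mean and variance are
#' \deqn{\hat\mu_{iA} = \sum_{j \in A} \hat{s}_j \hat{q}_{i0}, \qquad
#'       \hat\sigma^2_{iA} = \sum_{j \in A} \hat{s}_j \hat{q}_{i0}
#'       + \hat{s}_j^2 \hat{v}_A(\hat{q}_{i0}),}
#' with the raw variance evaluated at the pooled mean.
#'
#' @param q0 pooled common-scale mean (see \code{\link{pooledMean}}).
#' @param sf size factors of the condition's samples.
#' @param vf fitted \linkS4class{VarianceFunction} for the condition.
#' @return an \code{\link{nbParams}} object.
#' @export
conditionSumParams <- function(q0, sf, vf) {
    stopifnot(q0 >= 0)
    v <- rawVariance(vf, q0)
    nbParams(mean = sum(sf) * q0,
             variance = q0 * sum(sf) + v * sum(sf^2))
}

#' Pooled common-scale mean of one gene across two conditions
#'
#' The per-sample average of the common-scale counts over the union of the
#' two conditions' samples; the single expression strength both conditions
#' share under the null hypothesis.
#'
#' @param countsRow per-sample counts for one gene.
#' @param sf matching size factors.
#' @return the pooled mean (a single number).
#' @export
pooledMean <- function(countsRow, sf) {
    stopifnot(length(countsRow) == length(sf), length(sf) > 0)
    mean(countsRow / sf)
}

# log pmf over the contiguous range lo:hi by one anchored pmf evaluation
# plus a cumulative sum of log probability ratios (NB:
# p(a+1)/p(a) = (a+r)/(a+1) * mu/(r+mu); Poisson: mu/(a+1)). Far cheaper
# than per-point pmf calls over wide ranges, with rounding error well below
# reporting precision.
.logPmfRange <- function(lo, hi, p) {
    a <- lo:hi
    if (p$mean == 0) return(ifelse(a == 0, 0, -Inf))
    base <- .logPmf(lo, p)
    if (hi == lo) return(base)
    inc <- if (p$poisson)
        log(p$mean) - log((lo + 1):hi)
    else
        log(lo:(hi - 1) + p$size) - log((lo + 1):hi) +
            (log(p$mean) - log(p$size + p$mean))
    base + c(0, cumsum(inc))
}

# Evaluation window for the conditioned sums: all of 0..kS when kS is small;
# otherwise the contiguous region where log p(a, b) is within 36*ln(10) of
# its maximum (terms below 1e-36 relative are dropped), found by grid +
# binary search on the log-concave profile. Returns c(lo, hi); the observed
# split is added back by the caller when it falls outside.
.enumWindow <- function(kS, lpA, lpB, fullLimit = 10000L) {
    if (kS <= fullLimit) return(c(0L, kS))
    f <- function(a) lpA(a) + lpB(kS - a)
    grid <- unique(round(seq(0, kS, length.out = 201)))
    fg <- f(grid)
    aMax <- grid[which.max(fg)]
    span <- max(1L, grid[2] - grid[1])
    fine <- max(0, aMax - span):min(kS, aMax + span)
    ff <- f(fine)
    aMax <- fine[which.max(ff)]
    cutoff <- max(ff) - 36 * log(10)
    bsearch <- function(lo, hi, rising) {
        # first (rising) / last (falling) a with f(a) >= cutoff
        while (hi - lo > 1) {
            mid <- (lo + hi) %/% 2
            ok <- f(mid) >= cutoff
            if (ok == rising) hi <- mid else lo <- mid
        }
        if (rising) (if (f(lo) >= cutoff) lo else hi)
        else (if (f(hi) >= cutoff) hi else lo)
    }
    left <- if (f(0) >= cutoff) 0 else bsearch(0, aMax, TRUE)
    right <- if (f(kS) >= cutoff) kS else bsearch(aMax, kS, FALSE)
    c(left, right)
}

#' Exact conditioned p-value for a pair of condition count sums
#'
#' With kS = kA + kB, the p-value is the probability, conditional on the
#' total KA + KB = kS, of seeing a split (a, b) at most as probable as the
#' observed one:
#' \deqn{p = \frac{\sum_{a+b=k_S,\; p(a,b) \le p(k_A,k_B)} p(a,b)}
#'                {\sum_{a+b=k_S} p(a,b)},}
#' where p(a, b) is the product of the two (NB or Poisson-limit) pmfs. All
#' arithmetic is in log space. Ties with the observed probability are
#' admitted with a relative tolerance of 1e-8 on log probabilities.
#'
#' @param kA,kB observed count sums for the two conditions.
#' @param paramsA,paramsB \code{\link{nbParams}} for the two condition sums.
#' @return p-value in [0, 1].
#' @export
exactNBPvalue <- function(kA, kB, paramsA, paramsB) {
    stopifnot(kA >= 0, kB >= 0, kA == round(kA), kB == round(kB))
    kS <- kA + kB
    if (kS == 0) return(1)
    if (paramsA$mean == 0 && paramsB$mean == 0) return(1)
    lpA <- function(a) .logPmf(a, paramsA)
    lpB <- function(b) .logPmf(b, paramsB)
    win <- .enumWindow(kS, lpA, lpB)
    lp <- .logPmfRange(win[1], win[2], paramsA) +
        rev(.logPmfRange(kS - win[2], kS - win[1], paramsB))
    lpObs <- .logPmf(kA, paramsA) + .logPmf(kB, paramsB)
    if (!is.finite(lpObs)) return(0)  # observed split impossible under null
    outside <- kA < win[1] || kA > win[2]
    if (outside) lp <- c(lp, lpObs)   # always include the observed split
    keep <- lp <= lpObs + 1e-8 * abs(lpObs)
    num <- .logSumExp(lp[keep])
    den <- .logSumExp(lp)
    if (!is.finite(den))
        stop("degenerate conditioned distribution (all probabilities zero)")
    min(1, exp(num - den))
}

#' Test two conditions for differential expression
#'
#' For each gene: forms the condition count sums, the pooled mean, the NB
#' approximation of each condition sum (variance from the fitted variance
#' function, evaluated at the pooled mean), and the exact conditioned
#' p-value; then adjusts for multiple testing by Benjamini-Hochberg.
#'
#' @param object a \linkS4class{CountDataSet} with size factors and fitted
#'   variance functions (any estimation method).
#' @param condA,condB the two condition labels to contrast.
#' @return data.frame with one row per gene: id, baseMean (pooled
#'   common-scale mean), baseMeanA, baseMeanB, foldChange (B over A),
#'   log2FoldChange (infinite when one condition mean is 0, NA when both
#'   are), pval and padj. Genes with zero total count get p = 1 and are
#'   included in the BH denominator.
#' @examples
#' sim <- simulateCounts(nGenes = 300, conditions = c(A = 2, B = 2),
#'                       scv = 0.1, seed = 7)
#' cds <- estimateSizeFactors(sim$cds)
#' cds <- estimateVarianceFunctions(cds, minGenes = 30)
#' res <- nbinomTest(cds, "A", "B")
#' head(res)
#' @export
nbinomTest <- function(object, condA, condB) {
    sf <- sizeFactors(object)
    if (is.null(sf))
        stop("size factors not available; run estimateSizeFactors() first")
    vfs <- varianceFunctions(object)
    for (cond in c(condA, condB))
        if (is.null(vfs[[cond]]))
            stop("no fitted variance function for condition '", cond,
                 "'; run estimateVarianceFunctions() first")
    cond <- conditions(object)
    selA <- cond == condA
    selB <- cond == condB
    if (!any(selA) || !any(selB))
        stop("both conditions must be present in the design")
    k <- counts(object)
    sfA <- sf[selA]; sfB <- sf[selB]
    kA <- rowSums(k[, selA, drop = FALSE])
    kB <- rowSums(k[, selB, drop = FALSE])
    csAB <- commonScale(k[, selA | selB, drop = FALSE], sf[selA | selB])
    q0 <- rowMeans(csAB)
    vA <- rawVariance(vfs[[condA]], q0)
    vB <- rawVariance(vfs[[condB]], q0)
    muA <- sum(sfA) * q0; varA <- q0 * sum(sfA) + vA * sum(sfA^2)
    muB <- sum(sfB) * q0; varB <- q0 * sum(sfB) + vB * sum(sfB^2)
    pval <- vapply(seq_along(q0), function(i)
        exactNBPvalue(kA[i], kB[i],
                      nbParams(muA[i], varA[i]),
                      nbParams(muB[i], varB[i])),
        numeric(1))
    baseMeanA <- unname(rowMeans(commonScale(k[, selA, drop = FALSE], sfA)))
    baseMeanB <- unname(rowMeans(commonScale(k[, selB, drop = FALSE], sfB)))
    q0 <- unname(q0); kA <- unname(kA); kB <- unname(kB)
    fc <- ifelse(baseMeanA == 0 & baseMeanB == 0, NA_real_,
                 baseMeanB / baseMeanA)
    data.frame(id = rownames(object), baseMean = q0,
               baseMeanA = baseMeanA, baseMeanB = baseMeanB,
               foldChange = fc, log2FoldChange = log2(fc),
               pval = pval, padj = adjustBH(pval),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals vector of p-values in [0, 1] (NAs preserved).
#' @return BH-adjusted values in [0, 1].
#' @export
adjustBH <- function(pvals) {
    ok <- !is.na(pvals)
    if (any(pvals[ok] < 0 | pvals[ok] > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Per-gene Poisson chi-squared test (comparator)
#'
#' Goodness-of-fit test of the null of equal expression strength assuming
#' pure Poisson (shot-noise only) variability: per gene,
#' X^2 = sum_j (k_ij - s_j q0)^2 / (s_j q0) over the samples of both
#' conditions, referred to a chi-squared distribution with m - 1 degrees of
#' freedom. Anti-conservative in the presence of biological overdispersion;
#' provided as the comparator for type-I-error experiments.
#'
#' @inheritParams nbinomTest
#' @return vector of per-gene p-values (1 for all-zero genes).
#' @export
poissonChisqPvalues <- function(object, condA, condB) {
    sf <- sizeFactors(object)
    if (is.null(sf))
        stop("size factors not available; run estimateSizeFactors() first")
    cond <- conditions(object)
    sel <- cond %in% c(condA, condB)
    k <- counts(object)[, sel, drop = FALSE]
    sfs <- sf[sel]
    q0 <- rowMeans(sweep(k, 2, sfs, "/"))
    expd <- outer(q0, sfs)
    x2 <- rowSums((k - expd)^2 / expd)
    p <- pchisq(x2, df = sum(sel) - 1, lower.tail = FALSE)
    p[q0 == 0] <- 1
    setNames(p, rownames(k))
}

#' Write a result table as TSV
#'
#' Columns id, baseMean, baseMeanA, baseMeanB, foldChange, log2FoldChange,
#' pval, padj; infinities serialized as "Inf"/"-Inf", undefined values as
#' "NA".
#'
#' @param res output of \code{\link{nbinomTest}}.
#' @param path output path.
#' @export
writeResultTable <- function(res, path) {
    out <- res
    for (col in setdiff(colnames(out), "id"))
        out[[col]] <- vapply(out[[col]], function(x) {
            if (is.na(x)) "NA"
            else if (is.infinite(x)) ifelse(x > 0, "Inf", "-Inf")
            else format(x, digits = 12, trim = TRUE, scientific = FALSE)
        }, character(1))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
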