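# Independent oracles and fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal enumeration of the conditioned p-value: compute both pmfs on the
# natural scale for every split a + b = kS and sum the probabilities at most
# as large as the observed one. Deliberately naive; the implementation under
# test works in log space with windowing.
bruteForcePvalue <- function(kA, kB, pA, pB) {
    kS <- kA + kB
    if (kS == 0) return(1)
    pmf <- function(x, p) {
        if (p$mean == 0) return(as.numeric(x == 0))
        if (p$poisson) dpois(x, p$mean)
        else dnbinom(x, mu = p$mean, size = p$size)
    }
    a <- 0:kS
    pr <- pmf(a, pA) * pmf(kS - a, pB)
    pObs <- pmf(kA, pA) * pmf(kB, pB)
    sum(pr[pr <= pObs * (1 + 1e-12)]) / sum(pr)
}

# the worked 3 genes x 2 samples table whose size factors are
# (1/sqrt(2), sqrt(2)) exactly
workedCounts <- function() {
    matrix(c(1, 4, 9, 2, 8, 18), nrow = 3,
           dimnames = list(paste0("g", 1:3), c("s1", "s2")))
}

# VarianceFunction with a prescribed raw-variance law v(q) and bias
# coefficient, built on a dense knot grid so interpolation error is
# negligible over [qlo, qhi]
makeVF <- function(vfun, biasCoefficient = 1, qlo = 1e-3, qhi = 1e6,
                   condition = "A", nKnots = 3000, includeQ = numeric(0)) {
    knots <- sort(unique(c(seq(log(qlo), log(qhi), length.out = nKnots),
                           log(includeQ))))
    q <- exp(knots)
    new("VarianceFunction", condition = condition, logQKnots = knots,
        fittedW = q * biasCoefficient + vfun(q),
        biasCoefficient = biasCoefficient, fitDomain = c(qlo, qhi),
        settings = list())
}

# simulated data set with size factors and variance functions fitted,
# ready for testing
fittedSimulation <- function(nGenes = 2000, conditions = c(A = 2, B = 2),
                             scv = 0.1, seed = 42, method = "per-condition",
                             ...) {
    sim <- simulateCounts(nGenes = nGenes, conditions = conditions,
                          scv = scv, seed = seed, ...)
    cds <- estimateSizeFactors(sim$cds)
    cds <- estimateVarianceFunctions(cds, method = method)
    list(cds = cds, sim = sim)
}
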