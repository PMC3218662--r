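#' Simulate counts from the gamma-Poisson hierarchical model
#'
#' Generates counts from the model underlying the test: for gene i and
#' sample j of condition rho, a rate r_ij is drawn from a gamma distribution
#' with mean q_i,rho and variance v(q_i,rho) (degenerate at q when v = 0),
#' and the count k_ij is Poisson with rate s_j r_ij. Marginally the counts
#' are negative binomial with mean s_j q and variance
#' s_j q + s_j^2 v(q). Defaults emulate a bulk RNA-Seq experiment: means
#' log-uniform over [0.1, 1e5] (spanning the dynamic range of typical
#' libraries), unit size factors, constant squared coefficient of variation
#' 0.1 for the raw variance, and no true differential expression.
#'
#' @param nGenes number of genes.
#' @param conditions named integer vector: replicates per condition, e.g.
#'   c(A = 2, B = 2).
#' @param sizeFactors per-sample size factors (recycled per condition
#'   order); default all 1.
#' @param meanLaw either a function(n) drawing per-gene baseline means, or
#'   a fixed numeric vector of length nGenes; default
#'   10^runif(n, -1, 5).
#' @param rawVarianceLaw function q -> v(q) (>= 0); default constant-SCV
#'   \code{scv * q^2}.
#' @param scv convenience: squared coefficient of variation used by the
#'   default rawVarianceLaw (default 0.1).
#' @param differentialFraction fraction of genes truly differential between
#'   the first condition and each other condition (default 0).
#' @param effectLaw function(n) drawing log2 fold changes for differential
#'   genes; default uniform magnitude in [1, 3] with random sign.
#' @param seed integer seed; when given, output is reproducible
#'   bit-for-bit.
#' @return list with elements cds (a \linkS4class{CountDataSet}), isDE
#'   (logical truth labels), trueMeans (genes x conditions matrix of
#'   q_i,rho) and spec (the parameters used).
#' @export
simulateCounts <- function(nGenes, conditions = c(A = 2, B = 2),
                           sizeFactors = NULL, meanLaw = NULL,
                           rawVarianceLaw = NULL, scv = 0.1,
                           differentialFraction = 0, effectLaw = NULL,
                           seed = NULL) {
    stopifnot(nGenes >= 1, all(conditions >= 1),
              differentialFraction >= 0, differentialFraction <= 1)
    if (!is.null(seed)) set.seed(seed)
    m <- sum(conditions)
    condOfSample <- rep(names(conditions), conditions)
    if (is.null(sizeFactors)) sizeFactors <- rep(1, m)
    stopifnot(length(sizeFactors) == m, all(sizeFactors > 0))
    if (is.null(meanLaw)) meanLaw <- function(n) 10^runif(n, -1, 5)
    if (is.null(rawVarianceLaw)) rawVarianceLaw <- function(q) scv * q^2
    if (is.null(effectLaw))
        effectLaw <- function(n)
            sample(c(-1, 1), n, replace = TRUE) * runif(n, 1, 3)
    qBase <- if (is.function(meanLaw)) meanLaw(nGenes) else {
        stopifnot(length(meanLaw) == nGenes)
        as.numeric(meanLaw)
    }
    stopifnot(all(qBase >= 0))
    nDE <- round(differentialFraction * nGenes)
    isDE <- rep(FALSE, nGenes)
    if (nDE > 0) isDE[sample.int(nGenes, nDE)] <- TRUE
    trueMeans <- matrix(qBase, nrow = nGenes, ncol = length(conditions),
                        dimnames = list(NULL, names(conditions)))
    if (nDE > 0 && length(conditions) > 1)
        for (cn in names(conditions)[-1])
            trueMeans[isDE, cn] <- qBase[isDE] * 2^effectLaw(nDE)
    k <- matrix(0, nrow = nGenes, ncol = m)
    for (j in seq_len(m)) {
        q <- trueMeans[, condOfSample[j]]
        v <- rawVarianceLaw(q)
        stopifnot(all(v >= 0))
        r <- q
        pos <- q > 0 & v > 0
        if (any(pos))
            r[pos] <- rgamma(sum(pos), shape = q[pos]^2 / v[pos],
                             scale = v[pos] / q[pos])
        k[, j] <- rpois(nGenes, sizeFactors[j] * r)
    }
    rownames(k) <- paste0("gene", seq_len(nGenes))
    colnames(k) <- make.unique(paste0(condOfSample, "_",
                                      sequence(conditions)), sep = "")
    list(cds = newCountDataSet(k, condOfSample),
         isDE = setNames(isDE, rownames(k)),
         trueMeans = trueMeans,
         spec = list(nGenes = nGenes, conditions = conditions,
                     sizeFactors = sizeFactors, scv = scv,
                     differentialFraction = differentialFraction,
                     seed = seed))
}

#' Write a simulation to disk (count TSV plus JSON sidecar)
#'
#' @param sim output of \code{\link{simulateCounts}}.
#' @param countsPath path for the count table TSV.
#' @param sidecarPath path for the JSON sidecar (spec, seed, truth labels).
#' @export
writeSimulation <- function(sim, countsPath, sidecarPath) {
    writeCountTable(counts(sim$cds), countsPath)
    jsonlite::write_json(
        list(spec = sim$spec,
             conditions = as.list(setNames(
                 as.character(conditions(sim$cds)),
                 colnames(sim$cds))),
             isDE = as.list(sim$isDE)),
        sidecarPath, auto_unbox = TRUE, digits = NA)
}

# run the standard pipeline on a simulated data set and return the result
# table plus intermediates
.runPipeline <- function(cds, condA, condB, method = "per-condition", ...) {
    cds <- estimateSizeFactors(cds)
    cds <- estimateVarianceFunctions(cds, method = method, ...)
    list(cds = cds, res = nbinomTest(cds, condA, condB))
}

#' Type-I-error experiment on simulated null data
#'
#' Simulates counts with no true differential expression, runs the full
#' pipeline (size factors, variance-function fit, exact test), and reports
#' the empirical fraction of p-values at or below each threshold, overall
#' and stratified by pooled mean (below/above \code{meanSplit}). The same
#' fractions are reported for the Poisson chi-squared comparator, which is
#' expected to exceed its nominal levels whenever raw variance is present.
#'
#' @param nGenes,conditions,scv,sizeFactors,seed passed to
#'   \code{\link{simulateCounts}}.
#' @param alphaGrid thresholds at which the ECDF is evaluated.
#' @param meanSplit boundary between the low- and high-mean strata
#'   (default 100).
#' @param ... further fit settings for
#'   \code{\link{estimateVarianceFunctions}}.
#' @return list with the per-gene p-values (nb and poisson), pooled means,
#'   and \code{ecdf}: a data.frame of fractions by method, stratum and
#'   alpha.
#' @export
type1ErrorExperiment <- function(nGenes = 10000,
                                 conditions = c(A = 2, B = 2), scv = 0.1,
                                 sizeFactors = NULL,
                                 alphaGrid = c(0.01, 0.05, 0.1),
                                 meanSplit = 100, seed = NULL, ...) {
    sim <- simulateCounts(nGenes, conditions, sizeFactors = sizeFactors,
                          scv = scv, differentialFraction = 0, seed = seed)
    condA <- names(conditions)[1]; condB <- names(conditions)[2]
    run <- .runPipeline(sim$cds, condA, condB, ...)
    pPois <- poissonChisqPvalues(run$cds, condA, condB)
    q0 <- run$res$baseMean
    strata <- list(all = rep(TRUE, nGenes),
                   low = q0 < meanSplit, high = q0 >= meanSplit)
    rows <- do.call(rbind, lapply(names(strata), function(s)
        do.call(rbind, lapply(alphaGrid, function(a) data.frame(
            stratum = s, alpha = a,
            n = sum(strata[[s]]),
            nb = mean(run$res$pval[strata[[s]]] <= a),
            poisson = mean(pPois[strata[[s]]] <= a))))))
    list(pvalNB = run$res$pval, pvalPoisson = unname(pPois),
         baseMean = q0, ecdf = rows, sim = sim$spec)
}

#' Power experiment on simulated alternative data
#'
#' Simulates counts with a given fraction of truly differential genes, runs
#' the pipeline, and tabulates per mean bin the fraction of truly
#' differential genes detected at an FDR threshold and the smallest
#' detected absolute log2 fold change. Detection of a fixed fold change
#' improves with the mean: at low counts shot noise allows only very large
#' fold changes to reach significance.
#'
#' @param nGenes,conditions,scv,sizeFactors,seed,differentialFraction,
#'   effectLaw passed to \code{\link{simulateCounts}}.
#' @param fdr adjusted-p threshold for calling a hit (default 0.1).
#' @param meanBreaks bin boundaries for the true baseline mean.
#' @param ... further fit settings.
#' @return list with the result table, truth labels and \code{detection}: a
#'   data.frame per mean bin with nTrue, nDetected, fraction and
#'   minDetectedLFC.
#' @export
powerExperiment <- function(nGenes = 10000, conditions = c(A = 2, B = 2),
                            scv = 0.1, sizeFactors = NULL,
                            differentialFraction = 0.2, effectLaw = NULL,
                            fdr = 0.1,
                            meanBreaks = c(0, 10, 100, 1000, Inf),
                            seed = NULL, ...) {
    sim <- simulateCounts(nGenes, conditions, sizeFactors = sizeFactors,
                          scv = scv,
                          differentialFraction = differentialFraction,
                          effectLaw = effectLaw, seed = seed)
    condA <- names(conditions)[1]; condB <- names(conditions)[2]
    run <- .runPipeline(sim$cds, condA, condB, ...)
    hit <- !is.na(run$res$padj) & run$res$padj <= fdr
    qTrue <- sim$trueMeans[, condA]
    bin <- cut(qTrue, meanBreaks, include.lowest = TRUE)
    lfc <- abs(run$res$log2FoldChange)
    detection <- do.call(rbind, lapply(levels(bin), function(b) {
        inBin <- bin == b
        true <- inBin & sim$isDE
        det <- true & hit
        data.frame(bin = b, nTrue = sum(true), nDetected = sum(det),
                   fraction = ifelse(sum(true) > 0,
                                     sum(det) / sum(true), NA),
                   minDetectedLFC = ifelse(any(inBin & hit),
                                           min(lfc[inBin & hit],
                                               na.rm = TRUE), NA))
    }))
    list(res = run$res, isDE = sim$isDE, trueMeans = sim$trueMeans,
         detection = detection, hit = hit)
}
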