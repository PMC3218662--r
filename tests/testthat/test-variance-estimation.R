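test_that("condition moments match direct arithmetic", {
    k <- matrix(c(4, 6), nrow = 1, dimnames = list("g1", c("s1", "s2")))
    cds <- newCountDataSet(k, c("A", "A"))
    sizeFactors(cds) <- c(1, 1)
    mom <- conditionMoments(cds, "A")
    expect_equal(mom$baseMean, 5)
    expect_equal(mom$sampleVariance, 2)
    expect_equal(mom$biasTerm, 5)
    expect_equal(unname(unbiasedRawVariance(mom)), -3)  # negative allowed

    # same data at doubled depth: common scale (4, 6), z scales with 1/s
    k2 <- matrix(c(8, 12), nrow = 1, dimnames = list("g1", c("s1", "s2")))
    cds2 <- newCountDataSet(k2, c("A", "A"))
    sizeFactors(cds2) <- c(2, 2)
    mom2 <- conditionMoments(cds2, "A")
    expect_equal(mom2$baseMean, 5)
    expect_equal(mom2$sampleVariance, 2)
    expect_equal(mom2$biasTerm, 2.5)

    # identical replicate columns have zero sample variance
    k3 <- matrix(c(5, 9, 5, 9), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
    cds3 <- newCountDataSet(k3, c("A", "A"))
    sizeFactors(cds3) <- c(1, 1)
    expect_equal(conditionMoments(cds3, "A")$sampleVariance, c(0, 0))

    # unreplicated condition: explicit no-replicates error
    cds1 <- newCountDataSet(workedCounts(), c("A", "B"))
    sizeFactors(cds1) <- c(1, 1)
    expect_error(conditionMoments(cds1, "A"), "no replicates")
    expect_silent(momA <- conditionMoments(cds1, "A",
                                           requireVariance = FALSE))
    expect_true(all(is.na(momA$sampleVariance)))
})

test_that("w - z is an unbiased estimator of the raw variance", {
    # gamma-Poisson simulation at fixed (q, v, s); Monte-Carlo oracle
    q <- 100; v <- 400; sf <- c(1, 2)
    sim <- simulateCounts(nGenes = 20000, conditions = c(A = 2),
                          sizeFactors = sf, meanLaw = rep(q, 20000),
                          rawVarianceLaw = function(qq) rep(v, length(qq)),
                          seed = 301)
    cds <- sim$cds
    sizeFactors(cds) <- sf
    est <- unbiasedRawVariance(conditionMoments(cds, "A"))
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - v), 3 * mcse)
})

test_that("constant-SCV simulations are recovered by the local fit", {
    scv <- 0.1
    fs <- fittedSimulation(nGenes = 4000, conditions = c(A = 2), scv = scv,
                           seed = 5)
    vf <- varianceFunctions(fs$cds)$A
    q <- conditionMoments(fs$cds, "A")$baseMean
    qq <- quantile(q[q > 0], c(0.05, 0.95))
    grid <- exp(seq(log(qq[1]), log(qq[2]), length.out = 50))
    ratio <- fittedW(vf, grid) /
        (grid * vf@biasCoefficient + scv * grid^2)
    expect_true(all(ratio > 0.75 & ratio < 1.3))
})

test_that("pure Poisson data yield a near-zero raw variance", {
    fs <- fittedSimulation(nGenes = 10000, conditions = c(A = 2),
                           rawVarianceLaw = function(q) rep(0, length(q)),
                           seed = 6)
    vf <- varianceFunctions(fs$cds)$A
    q <- conditionMoments(fs$cds, "A")$baseMean
    q <- q[q > 0]
    relRaw <- rawVariance(vf, q) / q
    expect_lt(median(relRaw), 0.05)
    # full fitted variance approaches shot noise s*q at s = 1
    expect_lt(median(abs(fittedW(vf, q) - q) / q), 0.15)
})

test_that("fitted function is clamped, order-invariant and extrapolates at constant SCV", {
    set.seed(8)
    n <- 1000
    q <- 10^runif(n, 0, 3)
    w <- (q + 0.05 * q^2) * rgamma(n, shape = 0.5, rate = 0.5)
    mom <- data.frame(baseMean = q, sampleVariance = w)
    vf <- fitVarianceFunction(mom, biasCoefficient = 1, condition = "A")
    # gene-order invariance
    perm <- sample(n)
    vf2 <- fitVarianceFunction(mom[perm, ], biasCoefficient = 1,
                               condition = "A")
    expect_equal(vf@fittedW, vf2@fittedW, tolerance = 1e-12)
    # raw variance is never negative
    grid <- 10^seq(-3, 5, length.out = 200)
    expect_true(all(rawVariance(vf, grid) >= 0))
    expect_equal(rawVariance(vf, 0), 0)
    # outside the fit domain: constant-SCV continuation, shot noise re-added
    qlo <- exp(vf@logQKnots[1])
    scvLo <- max(0, vf@fittedW[1] - qlo * vf@biasCoefficient) / qlo^2
    qq <- qlo / 7
    expect_equal(fittedW(vf, qq), qq * vf@biasCoefficient + scvLo * qq^2,
                 tolerance = 1e-12)
    qhi <- exp(vf@logQKnots[length(vf@logQKnots)])
    scvHi <- max(0, vf@fittedW[length(vf@fittedW)] -
                 qhi * vf@biasCoefficient) / qhi^2
    expect_equal(fittedW(vf, qhi * 50),
                 qhi * 50 * vf@biasCoefficient + scvHi * (qhi * 50)^2,
                 tolerance = 1e-12)
    # too few genes is an explicit error
    expect_error(fitVarianceFunction(mom[1:10, ], biasCoefficient = 1),
                 "too few genes")
})

test_that("variance-sharing modes cover replicated and unreplicated designs", {
    fs <- fittedSimulation(nGenes = 800, conditions = c(A = 2, B = 2),
                           seed = 9)
    cds <- fs$cds
    # per-condition: two distinct fits
    vfs <- varianceFunctions(cds)
    expect_named(vfs, c("A", "B"))
    expect_false(isTRUE(all.equal(vfs$A@fittedW, vfs$B@fittedW)))

    # unreplicated condition in per-condition mode: error naming it
    sim11 <- simulateCounts(nGenes = 800, conditions = c(A = 1, B = 1),
                            seed = 10)
    cds11 <- estimateSizeFactors(sim11$cds)
    expect_error(estimateVarianceFunctions(cds11, method = "per-condition"),
                 "'A'|'B'")
    # blind mode runs on a 1+1 design and assigns a fit to every condition
    cds11 <- estimateVarianceFunctions(cds11, method = "blind")
    expect_named(varianceFunctions(cds11), c("A", "B"))
    expect_equal(varianceFunctions(cds11)$A@fittedW,
                 varianceFunctions(cds11)$B@fittedW)

    # shared-from-replicated on A:2, B:1 pools over A and serves both
    sim21 <- simulateCounts(nGenes = 800, conditions = c(A = 2, B = 1),
                            seed = 11)
    cds21 <- estimateSizeFactors(sim21$cds)
    cds21 <- estimateVarianceFunctions(cds21,
                                       method = "shared-from-replicated")
    vfs21 <- varianceFunctions(cds21)
    expect_equal(vfs21$A@fittedW, vfs21$B@fittedW)
    # but each condition keeps its own shot-noise coefficient
    sf <- sizeFactors(cds21)
    cond <- conditions(cds21)
    expect_equal(vfs21$B@biasCoefficient, mean(1 / sf[cond == "B"]))
})

test_that("blind variance estimation is conservative under true differences", {
    # with differential expression present, treating all samples as
    # replicates overestimates the variance relative to per-condition fits
    sim <- simulateCounts(nGenes = 3000, conditions = c(A = 2, B = 2),
                          scv = 0.05, differentialFraction = 0.3, seed = 12)
    cds <- estimateSizeFactors(sim$cds)
    perCond <- estimateVarianceFunctions(cds, method = "per-condition")
    blind <- estimateVarianceFunctions(cds, method = "blind")
    grid <- 10^seq(1, 4, length.out = 30)
    wPer <- fittedW(varianceFunctions(perCond)$A, grid)
    wBlind <- fittedW(varianceFunctions(blind)$A, grid)
    expect_gt(mean(wBlind / wPer), 1.2)
})

test_that("gamma-quantile diagnostics are calibrated under the fitted model", {
    # simulate sample variances exactly from the scaled-gamma null at the
    # fitted function: quantiles must be near-uniform
    set.seed(13)
    n <- 10000; m <- 2
    q <- 10^runif(n, 0, 4)
    vf <- makeVF(function(q) 0.1 * q^2, biasCoefficient = 1)
    shape <- (m - 1) / 2
    w <- fittedW(vf, q) * rgamma(n, shape = shape, rate = shape)
    mom <- S4Vectors::DataFrame(baseMean = q, sampleVariance = w,
                                biasTerm = q)
    S4Vectors::metadata(mom) <- list(condition = "A", nReplicates = m,
                                     biasCoefficient = 1)
    diag <- fitDiagnostics(mom, vf)
    ks <- max(abs(sort(diag$quantile) - (seq_len(n) - 0.5) / n))
    expect_lt(ks, 0.02)
    # all variances equal to the fitted values: all ratios 1
    momEq <- mom; momEq$sampleVariance <- fittedW(vf, q)
    expect_equal(fitDiagnostics(momEq, vf)$ratio, rep(1, n))
    # a fit forced to half the true variance skews the quantiles high;
    # with 4 replicates (shape 3/2) the skew is unmistakable
    m4 <- 4; shape4 <- (m4 - 1) / 2
    w4 <- fittedW(vf, q) * rgamma(n, shape = shape4, rate = shape4)
    mom4 <- S4Vectors::DataFrame(baseMean = q, sampleVariance = w4,
                                 biasTerm = q)
    S4Vectors::metadata(mom4) <- list(condition = "A", nReplicates = m4,
                                      biasCoefficient = 1)
    vfHalf <- makeVF(function(q) 0.05 * q^2 - q / 2, biasCoefficient = 1)
    diagHalf <- fitDiagnostics(mom4, vfHalf)
    ksHalf <- max(abs(sort(diagHalf$quantile) - (seq_len(n) - 0.5) / n))
    expect_gt(ksHalf, 0.2)
})

test_that("variance functions round trip through TSV + JSON export", {
    fs <- fittedSimulation(nGenes = 800, conditions = c(A = 2), seed = 14)
    vf <- varianceFunctions(fs$cds)$A
    path <- withr::local_tempfile(fileext = ".tsv")
    writeVarianceFunction(vf, path)
    back <- readVarianceFunction(path)
    grid <- 10^seq(-1, 5, length.out = 40)
    expect_equal(fittedW(back, grid), fittedW(vf, grid), tolerance = 1e-10)
    expect_equal(rawVariance(back, grid), rawVariance(vf, grid),
                 tolerance = 1e-10)
    expect_equal(back@biasCoefficient, vf@biasCoefficient)
})
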