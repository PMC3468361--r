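fn <- gammaVariateInput(40, onset = 10, peakTime = 25, shape = 3)
sch <- defaultFrameSchedule()

test_that("an all-zero curve yields an all-zero spectrum with zero residual", {
    tac <- timeActivityCurve(sch, rep(0, 10))
    sp <- spectralFit(tac, fn)
    expect_equal(alphaWeights(sp), rep(0, length(basisRates(spectralBasis()))))
    expect_equal(residualNorm(sp), 0)
})

test_that("a noise-free curve with k2 on the basis grid is recovered as a sparse spectrum", {
    basis <- spectralBasis()
    k2 <- basisRates(basis)[30L]    # an interior grid rate
    tac <- forwardModel(oneTissueParams(0.8, k2, 0), fn, sch)
    sp <- spectralFit(tac, fn, basis)
    expect_equal(perfusionSum(sp), 0.8, tolerance = 0.01)
    ## the active weight concentrates at the generating rate
    expect_gt(sum(alphaWeights(sp)[abs(basisRates(basis) - k2) < 1e-9]),
              0.5 * 0.8)
})

test_that("the NNLS solution matches an exhaustive grid-search oracle on a toy problem", {
    ## 3 frames, 2 basis rates
    toySch <- frameSchedule(c(0, 20, 40), c(20, 20, 20))
    toyBasis <- spectralBasis(nRates = 1, betaMax = 0.5)  # rates 0 and 0.5
    A <- waterPET:::spectralDesign(fn, toyBasis, toySch)
    for (target in list(c(0.4, 0.7), c(0.9, 0), c(0, 1.2))) {
        b <- as.numeric(A %*% target)
        got <- nnlsSolve(A, b)$x
        want <- gridNNLS2(A, b, upper = c(3, 3))
        expect_equal(got, want, tolerance = 1e-6)
    }
    ## a genuinely active-constraint case: data pulling one weight negative
    b <- as.numeric(A %*% c(0.8, 0)) - 0.5 * A[, 2L]
    expect_equal(nnlsSolve(A, b)$x, gridNNLS2(A, b, upper = c(3, 3)),
                 tolerance = 1e-6)
})

test_that("the in-package NNLS agrees with an independent active-set implementation", {
    skip_if_not_installed("pracma")
    set.seed(11)
    for (i in 1:20) {
        A <- matrix(rnorm(40), 8, 5)
        b <- rnorm(8)
        got <- nnlsSolve(A, b)
        ref <- pracma::lsqnonneg(A, b)
        expect_equal(got$x, as.numeric(ref$x), tolerance = 1e-8)
    }
})

test_that("spectral residual is non-increasing as basis rates are added", {
    tac <- forwardModel(oneTissueParams(0.8, 0.37, 0.05), fn, sch)
    res <- vapply(c(6, 12, 24, 48), function(n)
        residualNorm(spectralFit(tac, fn, spectralBasis(nRates = n))),
        numeric(1))
    expect_true(all(diff(res) <= 1e-9))
})

test_that("spectral and nonlinear fits agree on K1 for on-grid noise-free data", {
    basis <- spectralBasis()
    k2 <- basisRates(basis)[29L]
    tac <- forwardModel(oneTissueParams(1.1, k2, 0.08), fn, sch)
    sp <- spectralFit(tac, fn, basis)
    nl <- nonlinearFit(tac, fn)
    expect_equal(perfusionTissue(sp), nl$params@K1, tolerance = 0.01)
})

test_that("perfusion conventions decompose exactly and follow their definitions", {
    tac <- forwardModel(oneTissueParams(0.8, 0.4, 0.05), fn, sch)
    sp <- spectralFit(tac, fn)
    est <- perfusionFromSpectrum(sp)
    expect_identical(est$perfusion, est$perfusionTissue + est$vascularWeight)
    expect_identical(est$perfusion, perfusionSum(sp))

    ## hand-built spectrum: 0.5 at a slow rate + 0.1 at the top rate
    basis <- spectralBasis(nRates = 4, betaMax = 6, betaMin = 0.3)
    alpha <- numeric(5)
    alpha[abs(basisRates(basis) - 0.3) < 1e-9] <- 0.5
    alpha[abs(basisRates(basis) - 6) < 1e-9] <- 0.1
    res <- new("SpectralResult", alpha = alpha, basis = basis,
               fittedCurve = timeActivityCurve(sch, rep(0, 10)),
               residualNorm = 0, vascularCutoff = 2)
    expect_equal(perfusionSum(res), 0.6)
    expect_equal(perfusionTissue(res), 0.5)
    expect_equal(vascularWeight(res), 0.1)
})

test_that("nonlinear fit recovers noise-free parameters and flags the vascular-only case", {
    p <- oneTissueParams(0.8, 0.4, 0.05)
    tac <- forwardModel(p, fn, sch)
    nl <- nonlinearFit(tac, fn)
    expect_true(nl$converged)
    expect_equal(nl$params@K1, 0.8, tolerance = 5e-3)
    expect_equal(nl$params@k2, 0.4, tolerance = 5e-3)
    expect_equal(nl$params@V0, 0.05, tolerance = 5e-3)

    ## pure vascular signal: K1 -> 0, V0 -> true fraction
    vasc <- forwardModel(oneTissueParams(0, 0.4, 0.11), fn, sch)
    nlv <- nonlinearFit(vasc, fn)
    expect_lt(nlv$params@K1, 1e-3)
    expect_equal(nlv$params@V0, 0.11, tolerance = 1e-3)
})

test_that("nonlinear fit stays within 15% of truth at the default noise level", {
    p <- oneTissueParams(0.9, 0.35, 0.05)
    noisy <- addTACNoise(forwardModel(p, fn, sch), sigma0 = 2.1, seed = 5)
    nl <- nonlinearFit(noisy, fn)
    expect_true(nl$converged)
    expect_lt(abs(nl$params@K1 - 0.9) / 0.9, 0.15)
})

test_that("delay estimation recovers constructed delays and flags uninformative data", {
    tac0 <- forwardModel(oneTissueParams(0.8, 0.4, 0.05), fn, sch)
    expect_identical(estimateDelay(tac0, fn)$delay, 0)

    tac10 <- forwardModel(oneTissueParams(0.8, 0.4, 0.05, delay = 10), fn, sch)
    est <- estimateDelay(tac10, fn)
    expect_identical(est$delay, 10)
    expect_false(est$lowConfidence)

    ## pure noise: a value is returned but confidence is low
    set.seed(3)
    noise <- timeActivityCurve(sch, rnorm(10))
    estN <- estimateDelay(noise, fn)
    expect_true(estN$delay %in% seq(-10, 20, 2))
    expect_true(estN$lowConfidence)

    expect_error(estimateDelay(tac0, fn, numeric(0)), "empty")
})
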