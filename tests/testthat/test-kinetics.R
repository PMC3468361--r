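test_that("exponential convolution handles zero and constant inputs in closed form", {
    zero <- sampledInput(c(0, 200), c(0, 0))
    expect_equal(convolveExponential(zero, 0.5, c(10, 60, 150)),
                 rep(0, 3))

    ## constant c from t = 0: conv = (c/beta)(1 - exp(-beta t)), beta in 1/s
    const <- sampledInput(c(0, 400), c(3, 3))
    beta <- 0.6                       # 1/min
    bsec <- beta / 60
    tt <- c(20, 60, 180)
    expect_equal(convolveExponential(const, beta, tt),
                 (3 / bsec) * (1 - exp(-bsec * tt)), tolerance = 1e-3)

    ## beta = 0: running integral
    expect_equal(convolveExponential(const, 0, tt), 3 * tt,
                 tolerance = 1e-9)
})

test_that("exponential convolution matches adaptive quadrature within 0.1%", {
    fn <- gammaVariateInput(40, onset = 10, peakTime = 25, shape = 3)
    for (beta in c(0.05, 0.4, 2)) {
        tt <- c(30, 60, 120, 160)
        got <- convolveExponential(fn, beta, tt)
        want <- convOracle(fn, beta, tt)
        expect_equal(got, want, tolerance = 1e-3)
    }
})

test_that("convolution rejects invalid rates and out-of-support times", {
    fn <- gammaVariateInput(40, onset = 10)
    expect_error(convolveExponential(fn, -0.1, 30), "non-negative")
    samp <- sampledInput(c(0, 100), c(1, 1))
    expect_error(convolveExponential(samp, 0.5, 150), "support")
})

test_that("forward model reduces to its degenerate closed forms", {
    fn <- gammaVariateInput(40, onset = 10)
    sch <- defaultFrameSchedule()
    tg <- seq(0, 160.25, by = 0.5)
    ca <- evalInput(fn, tg)
    fravg <- function(v) waterPET:::frameAverage(tg, v, sch)

    ## K1 = 0: pure vascular signal
    vasc <- forwardModel(oneTissueParams(0, 0.4, 0.12), fn, sch)
    expect_equal(activity(vasc), 0.12 * fravg(ca), tolerance = 1e-9)

    ## k2 = 0, V0 = 0: irreversible trapping of the running integral
    trap <- forwardModel(oneTissueParams(0.6, 0, 0), fn, sch)
    expect_equal(activity(trap),
                 0.6 / 60 * fravg(convolveExponential(fn, 0, tg)),
                 tolerance = 1e-6)

    ## constant input: (K1 c / k2)(1 - exp(-k2 t)) + V0 c
    const <- sampledInput(c(0, 400), c(5, 5))
    p <- oneTissueParams(0.8, 0.4, 0.05)
    got <- forwardModel(p, const, sch)
    k2s <- 0.4 / 60
    closed <- function(t) (0.8 / 60) * 5 / k2s * (1 - exp(-k2s * t)) + 0.05 * 5
    want <- fravg(closed(tg))
    expect_equal(activity(got), want, tolerance = 1e-4)
})

test_that("forward model is additive in K1 (superposition of the tissue term)", {
    fn <- gammaVariateInput(40, onset = 10)
    sch <- defaultFrameSchedule()
    ab <- forwardModel(oneTissueParams(1.1, 0.4, 0.06), fn, sch)
    a <- forwardModel(oneTissueParams(0.7, 0.4, 0.06), fn, sch)
    b <- forwardModel(oneTissueParams(0.4, 0.4, 0), fn, sch)
    expect_equal(activity(ab), activity(a) + activity(b),
                 tolerance = 1e-10)
})

test_that("halving the quadrature step changes frame values by less than 0.1%", {
    fn <- gammaVariateInput(40, onset = 10)
    sch <- defaultFrameSchedule()
    p <- oneTissueParams(0.8, 0.4, 0.05)
    coarse <- activity(forwardModel(p, fn, sch, fineStep = 0.5))
    fine <- activity(forwardModel(p, fn, sch, fineStep = 0.25))
    expect_lt(max(abs(coarse - fine)) / max(abs(fine)), 1e-3)
})

test_that("decay correction doubles one-half-life frames, inverts exactly and refuses double application", {
    sch <- frameSchedule(c(0, 117.24), c(10, 10))  # 2nd frame mid = 122.24 s
    tac <- timeActivityCurve(sch, c(8, 4), decayCorrected = FALSE)
    corr <- decayCorrect(tac)
    expect_equal(activity(corr)[2L], 8, tolerance = 1e-12)
    expect_true(isDecayCorrected(corr))
    expect_error(decayCorrect(corr), "already")

    ## half-life -> infinity is the identity
    noop <- decayCorrect(tac, halfLife = 1e12)
    expect_equal(activity(noop), activity(tac), tolerance = 1e-9)

    ## round trip
    back <- decayUncorrect(corr)
    expect_equal(activity(back), activity(tac), tolerance = 1e-12)
    expect_error(decayUncorrect(back), "not decay-corrected")
})

test_that("percent change matches its definition and inverts a cohort-table row", {
    expect_equal(percentChange(1, 1), 0)
    expect_equal(percentChange(2, 3), 50)
    ## baseline 0.81 with -85% change implies follow-up 0.1215
    expect_equal(percentChange(0.81, 0.1215), -85, tolerance = 1e-12)
    expect_error(percentChange(0, 1), "positive")
    expect_error(percentChange(-1, 1), "positive")
})

test_that("frame schedules reject overlap, disorder and bad durations", {
    expect_error(frameSchedule(c(0, 4), c(5, 5)), "overlap")
    expect_error(frameSchedule(c(5, 0), c(2, 2)), "ordered")
    expect_error(frameSchedule(0, 0), "positive")
    expect_silent(validObject(defaultFrameSchedule()))
    expect_equal(max(frameEnd(defaultFrameSchedule())), 160)
    expect_equal(nFrames(defaultFrameSchedule()), 10L)
})
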