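test_that("the gamma-variate bolus peaks at the requested amplitude and is causal", {
    fn <- makeInputFunction(peakTime = 25, amplitude = 45, onset = 10)
    tt <- seq(0, 160, by = 0.01)
    v <- evalInput(fn, tt)
    expect_equal(max(v), 45, tolerance = 1e-4)
    expect_equal(tt[which.max(v)], 35, tolerance = 0.02)
    expect_true(all(v[tt <= 10] == 0))
    expect_true(all(v >= 0))

    ## integral against an adaptive-quadrature oracle
    got <- convolveExponential(fn, 0, 160)
    want <- integrate(function(s) evalInput(fn, s), 0, 160,
                      rel.tol = 1e-10)$value
    expect_equal(got, want, tolerance = 1e-4)

    expect_error(makeInputFunction(amplitude = -1), "positive")
    expect_error(makeInputFunction(peakTime = 0), "positive")
})

test_that("input-function jitter is seeded and leaves the caller's RNG stream alone", {
    a <- makeInputFunction(seed = 7)
    b <- makeInputFunction(seed = 7)
    expect_equal(evalInput(a, c(20, 40, 60)), evalInput(b, c(20, 40, 60)))
    set.seed(123)
    before <- rnorm(1)
    set.seed(123)
    invisible(makeInputFunction(seed = 7))
    expect_identical(rnorm(1), before)
})

test_that("the input fitted back from a frame-sampled blood curve matches the generator", {
    fn <- makeInputFunction()
    sch <- defaultFrameSchedule()
    tg <- seq(0, 160.25, by = 0.5)
    av <- waterPET:::frameAverage(tg, evalInput(fn, tg), sch)
    fit <- fitInputFunction(timeActivityCurve(sch, av))
    expect_true(attr(fit, "converged"))
    ## the identifiable quantity -- the frame averages -- is matched tightly
    refit <- waterPET:::frameAverage(tg, evalInput(fit, tg), sch)
    expect_lt(max(abs(refit - av)) / max(av), 1e-4)
    ## and the continuous curve is recovered to within 1% of the peak
    tt <- seq(0, 160, by = 1)
    expect_lt(max(abs(evalInput(fit, tt) - evalInput(fn, tt))) / 45, 0.01)
})

test_that("a noise-free phantom's tumour VOI mean reproduces the forward model exactly", {
    spec <- smallPhantomSpec(sigma0 = 0)
    sim <- simulatePatient(spec, seed = 1)
    ## mask of the true tumour sphere on the water grid
    voi <- thresholdVOI(sim$fdg)
    voiW <- transferVOI(voi, -spec@fdgShift)
    tac <- extractTAC(sim$water, voiW)
    expect_equal(activity(tac), activity(sim$truth$tumourTAC),
                 tolerance = 1e-12)
})

test_that("phantom simulation is bit-identical under a fixed seed and validates geometry", {
    spec <- smallPhantomSpec(sigma0 = 2.1)
    a <- simulatePatient(spec, seed = 42)
    b <- simulatePatient(spec, seed = 42)
    expect_identical(imageData(a$water), imageData(b$water))
    expect_identical(imageData(a$fdg), imageData(b$fdg))
    c <- simulatePatient(spec, seed = 43)
    expect_false(identical(imageData(a$water), imageData(c$water)))

    ## tumour centred on the aorta violates disjointness
    expect_error(phantomSpec(tumourCentre = c(16, 22, 24)), "disjoint")
    expect_error(phantomSpec(tumourCentre = c(2, 2, 2)), "inside")
})

test_that("raw-decay simulation mode is undone exactly by decay correction", {
    spec <- smallPhantomSpec(sigma0 = 0)
    raw <- simulatePatient(spec, seed = 1, rawDecay = TRUE)
    corrected <- simulatePatient(spec, seed = 1)
    expect_false(isDecayCorrected(raw$water))
    expect_false(isDecayCorrected(raw$truth$tumourTAC))
    got <- decayCorrect(raw$truth$tumourTAC)
    expect_equal(activity(got), activity(corrected$truth$tumourTAC),
                 tolerance = 1e-12)
})

test_that("TAC noise follows the stated frame model and is reproducible", {
    sch <- defaultFrameSchedule()
    tac <- timeActivityCurve(sch, rep(10, 10))
    n1 <- addTACNoise(tac, sigma0 = 2, seed = 8)
    n2 <- addTACNoise(tac, sigma0 = 2, seed = 8)
    expect_identical(activity(n1), activity(n2))
    ## long frames are quieter: empirical sd scales as 1/sqrt(duration)
    set.seed(31)
    devs <- replicate(400, activity(addTACNoise(tac, 2)) - 10)
    sds <- apply(devs, 1, sd)
    expect_equal(sds[9] / sds[1], sqrt(5 / 30), tolerance = 0.25)
})

test_that("simulated cohorts are reproducible, rule-consistent and degenerate ranges collapse", {
    ch <- simulateCohort(n = 7, seed = 3)
    ch2 <- simulateCohort(n = 7, seed = 3)
    expect_identical(ch$records, ch2$records)
    expect_equal(nrow(ch$records), 7)
    ## benefit label follows the stated threshold rule
    expect_identical(ch$records$clinical_benefit,
                     ifelse(ch$truth$change <= -50, "Yes", "No"))
    ## baseline perfusion within the configured range
    expect_true(all(ch$truth$K1 >= 0.74 & ch$truth$K1 <= 1.52))

    const <- simulateCohort(n = 5, seed = 1, K1Range = c(1, 1),
                            k2Range = c(0.4, 0.4), V0Range = c(0.05, 0.05),
                            changeMean = -60, changeSd = 0)
    expect_equal(length(unique(const$records$baseline_perfusion_ml_min_g)), 1)
    expect_equal(length(unique(const$records$perfusion_change_pct)), 1)
    expect_error(simulateCohort(n = 0), "at least 1")
    expect_error(simulateCohort(K1Range = c(2, 1)), "invalid")
})

test_that("cohorts generated with the benefit-group effect give the Welch test its power", {
    ## generating effect matching the packaged cohort's group means
    gm <- list(benefit = -67.25, nonBenefit = -37.7, sd = 18,
               pBenefit = 4 / 7)
    hits <- 0L
    nRep <- 200
    for (r in seq_len(nRep)) {
        ch <- simulateCohort(n = 7, seed = r, groupMeans = gm)
        ben <- ch$records$clinical_benefit == "Yes"
        if (sum(ben) < 2 || sum(!ben) < 2) next
        p <- welchTOneSided(ch$records$perfusion_change_pct[ben],
                            ch$records$perfusion_change_pct[!ben])$p
        hits <- hits + (p < 0.05)
    }
    ## with n = 7 and this effect size the test should reject in a clear
    ## majority of cohorts but not always
    expect_gt(hits / nRep, 0.35)
    expect_lt(hits / nRep, 0.95)
})

test_that("the packaged cohort table transcribes all seven patients and round-trips CSV", {
    df <- fixtureTable()
    expect_equal(nrow(df), 7)
    expect_equal(df$perfusion_change_pct[1], -85)
    expect_equal(df$baseline_fdg_suv[5], 12.3)
    expect_equal(df$baseline_perfusion_ml_min_g,
                 c(0.81, 1.18, 1.52, 1.28, 0.74, 1.39, 1.23))
    ## missing biomarkers only for patients 6-7
    expect_identical(which(is.na(df$vegf_d15_d1)), c(6L, 7L))
    expect_identical(which(is.na(df$svegfr2_d15_d1)), c(6L, 7L))
    expect_true(all(df$perfusion_change_pct < 0))

    tmp <- tempfile(fileext = ".csv")
    utils::write.csv(df, tmp, row.names = FALSE)
    back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
    expect_equal(back, df)
    unlink(tmp)
})
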