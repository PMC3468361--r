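## Small synthetic volumes for the VOI machinery.
gaussBlob <- function(d = c(24, 24, 24), vox = c(4, 4, 4),
                      centre = c(12, 12, 12), peak = 10, sigmaMm = 10,
                      floor = 0) {
    dx <- (seq_len(d[1]) - centre[1]) * vox[1]
    dy <- (seq_len(d[2]) - centre[2]) * vox[2]
    dz <- (seq_len(d[3]) - centre[3]) * vox[3]
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    volumeImage(floor + peak * exp(-r2 / (2 * sigmaMm^2)), vox,
                modality = "FDG-SUV")
}

test_that("threshold VOI selects everything on a uniform image and fails on empty images", {
    img <- volumeImage(array(2, c(8, 8, 8)), c(4, 4, 4), "FDG-SUV")
    voi <- thresholdVOI(img, 0.75)
    expect_equal(voxelCount(voi), 512)
    expect_error(thresholdVOI(volumeImage(array(0, c(8, 8, 8)),
                                          c(4, 4, 4))), "degenerate")
    expect_error(thresholdVOI(img, 1.2), "between 0 and 1")
})

test_that("threshold VOI volume matches the analytic Gaussian isocontour within 10%", {
    img <- gaussBlob(peak = 10, sigmaMm = 10)
    voi <- thresholdVOI(img, 0.75)
    rIso <- 10 * sqrt(2 * log(1 / 0.75))        # mm
    analytic <- 4 / 3 * pi * rIso^3
    got <- voxelCount(voi) * prod(c(4, 4, 4))
    expect_lt(abs(got - analytic) / analytic, 0.10)
})

test_that("threshold VOI keeps only the component containing the hottest voxel", {
    img <- gaussBlob(centre = c(8, 12, 12), peak = 10)
    img2 <- gaussBlob(centre = c(18, 12, 12), peak = 8.5)
    both <- volumeImage(imageData(img) + imageData(img2), c(4, 4, 4),
                        "FDG-SUV")
    voi <- thresholdVOI(both, 0.75)
    idx <- which(maskArray(voi), arr.ind = TRUE)
    expect_true(all(idx[, 1] < 14))      # second lesion excluded
})

test_that("threshold masks are nested as the fraction increases", {
    img <- gaussBlob()
    hi <- maskArray(thresholdVOI(img, 0.9))
    lo <- maskArray(thresholdVOI(img, 0.5))
    expect_true(all(lo[hi]))
})

test_that("registration recovers a constructed shift and is exact for identical images", {
    spec <- smallPhantomSpec()
    sim <- simulatePatient(spec, seed = 1)
    fixed <- sim$waterAtten
    expect_identical(registerAttenuation(fixed, fixed)$shift, c(0L, 0L, 0L))

    moving <- volumeImage(waterPET:::shiftArray(imageData(fixed),
                                                c(2L, -1L, 0L)),
                          voxelSize(fixed), "attenuation")
    reg <- registerAttenuation(moving, fixed)
    expect_identical(reg$shift, c(-2L, 1L, 0L))   # aligns moving back onto fixed
    expect_gt(reg$correlation, 0.99)
})

test_that("registration on pure noise still reports its correlation for QC", {
    set.seed(4)
    a <- volumeImage(array(rnorm(16^3), c(16, 16, 16)), c(4, 4, 4),
                     "attenuation")
    b <- volumeImage(array(rnorm(16^3), c(16, 16, 16)), c(4, 4, 4),
                     "attenuation")
    reg <- registerAttenuation(a, b, searchWindowMm = 8)
    expect_true(all(abs(reg$shift) <= 2))
    expect_true(is.finite(reg$correlation))
    expect_lt(reg$correlation, 0.5)
})

test_that("registration validates modality and window size", {
    img <- volumeImage(array(1, c(8, 8, 8)), c(4, 4, 4), "FDG-SUV")
    expect_error(registerAttenuation(img, img), "attenuation")
    att <- volumeImage(array(rnorm(8^3), c(8, 8, 8)), c(4, 4, 4),
                       "attenuation")
    expect_error(registerAttenuation(att, att, searchWindowMm = 100),
                 "window larger")
})

test_that("VOI transfer is invertible in the interior and preserves voxel count", {
    m <- array(FALSE, c(16, 16, 16))
    m[7:10, 7:10, 7:10] <- TRUE
    voi <- voiMask(m, c(4, 4, 4))
    expect_identical(maskArray(transferVOI(voi, c(0, 0, 0))),
                     maskArray(voi))
    back <- transferVOI(transferVOI(voi, c(3, -2, 1)), c(-3, 2, -1))
    expect_identical(maskArray(back), maskArray(voi))
    expect_equal(voxelCount(transferVOI(voi, c(3, -2, 1))), 64)
    expect_error(transferVOI(voi, c(20, 0, 0)), "degenerate")
})

test_that("summed images weight frames by duration and add over disjoint ranges", {
    spec <- smallPhantomSpec()
    sim <- simulatePatient(spec, seed = 1)
    dyn <- sim$water
    sch <- schedule(dyn)

    one <- summedImage(dyn, 3)
    expect_equal(imageData(one),
                 imageData(dyn)[, , , 3] * frameDuration(sch)[3])

    all1 <- summedImage(dyn, 1:5)
    a <- summedImage(dyn, 1:2)
    b <- summedImage(dyn, 3:5)
    expect_equal(imageData(all1), imageData(a) + imageData(b),
                 tolerance = 1e-12)
    expect_error(summedImage(dyn, integer(0)), "empty")

    ## full sum matches the fine-grid time integral of the input in the aorta
    fullSum <- summedImage(dyn, seq_len(nFrames(sch)))
    aortaCore <- maskArray(aortaVOI(dyn))
    got <- mean(imageData(fullSum)[aortaCore])
    tg <- seq(0, 160, by = 0.01)
    want <- sum(evalInput(spec@input, tg)) * 0.01
    expect_equal(got, want, tolerance = 0.01)
})

test_that("TAC extraction is a per-frame mean, linear in the image", {
    spec <- smallPhantomSpec()
    sim <- simulatePatient(spec, seed = 1)
    dyn <- sim$water

    ## single-voxel mask returns that voxel's series
    m <- array(FALSE, dim(imageData(dyn))[1:3])
    m[16, 15, 12] <- TRUE
    single <- extractTAC(dyn, voiMask(m, voxelSize(dyn)))
    expect_equal(activity(single), imageData(dyn)[16, 15, 12, ])

    ## scaling the image scales the TAC
    twice <- volumeImage(2 * imageData(dyn), voxelSize(dyn),
                         "water-dynamic", schedule(dyn))
    voi <- thresholdVOI(sim$fdg)
    expect_equal(activity(extractTAC(twice, voi)),
                 2 * activity(extractTAC(dyn, voi)), tolerance = 1e-12)

    expect_error(extractTAC(dyn, voiMask(array(TRUE, c(4, 4, 4)),
                                         c(4, 4, 4))), "grid")
})

test_that("volumes and masks survive a NIfTI round trip", {
    spec <- smallPhantomSpec()
    sim <- simulatePatient(spec, seed = 1)
    tmp <- withr::local_tempdir()
    p <- file.path(tmp, "atten.nii.gz")
    writeVolume(sim$waterAtten, p)
    back <- readVolume(p, modality = "attenuation")
    expect_equal(imageData(back), imageData(sim$waterAtten),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(voxelSize(back), voxelSize(sim$waterAtten))

    voi <- thresholdVOI(sim$fdg)
    pm <- file.path(tmp, "mask.nii.gz")
    writeMask(voi, pm)
    expect_identical(unname(maskArray(readMask(pm))),
                     unname(maskArray(voi)))
})
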