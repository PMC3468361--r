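## Synthetic dynamic-PET data: bolus input functions, 4-D phantoms with a
## tumour lesion and a descending-aorta cylinder, matched FDG and
## attenuation volumes, and simulated cohorts. Everything is reproducible
## from (spec, seed).

INJECTED_DOSE_MBQ <- 370

#' Make a gamma-variate bolus input function
#'
#' The canonical arterial curve for a peripheral venous bolus: zero
#' before the appearance time, a gamma-variate rise peaking `peakTime`
#' seconds after onset at approximately `amplitude`, then washout. With
#' `seed` set, amplitude and peak time receive a small log-normal
#' inter-patient jitter (5 percent coefficient of variation).
#'
#' @param peakTime time from onset to peak (s), positive; default 25.
#' @param amplitude peak concentration (kBq/mL), positive; default 45.
#' @param shape gamma-variate shape, positive; default 3.
#' @param onset appearance time (s); default 10.
#' @param seed optional integer for jittered realisations.
#' @return a [GammaVariateInput-class].
#' @export
makeInputFunction <- function(peakTime = 25, amplitude = 45, shape = 3,
                              onset = 10, seed = NULL) {
    if (peakTime <= 0 || amplitude <= 0 || shape <= 0)
        stop("peakTime, amplitude and shape must be positive")
    if (!is.null(seed)) {
        rs <- localRNG(seed)
        on.exit(restoreRNG(rs))
        amplitude <- amplitude * exp(stats::rnorm(1, 0, 0.05))
        peakTime <- peakTime * exp(stats::rnorm(1, 0, 0.05))
    }
    gammaVariateInput(amplitude, onset = onset, peakTime = peakTime,
                      shape = shape)
}

## Seeded RNG scoped to a generator call: save and restore the global
## state so simulation helpers do not perturb a caller's stream.
localRNG <- function(seed) {
    state <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    state
}

restoreRNG <- function(state) {
    if (is.null(state))
        rm(".Random.seed", envir = globalenv())
    else
        assign(".Random.seed", state, envir = globalenv())
    invisible(NULL)
}

#' Default synthetic patient specification
#'
#' A 48^3 grid of 4-mm voxels holding a 12-mm-radius spherical liver-like
#' lesion (one-tissue kinetics, K1 = 0.9 mL/g/min, k2 = 0.35 /min,
#' V0 = 0.05 -- inside the range of baseline tumour perfusion seen in
#' practice), a 6-mm-radius descending-aorta cylinder carrying the bolus,
#' a quiet soft-tissue background, a 2/-1/1-voxel inter-study shift for
#' the FDG session and frame noise sigma0 = 2.1, calibrated so the
#' signal-to-noise ratio of the brightest dynamic signal (the blood-pool
#' peak frame, about 44 kBq/mL over 10 s) is 10:
#' sqrt(44 x 10) / 2.1 = 10.
#'
#' @param dim grid size (voxels), length 3.
#' @param voxelSize voxel size (mm), length 3.
#' @param tumourCentre tumour centre (voxel indices).
#' @param tumourRadius tumour radius (mm).
#' @param params tumour [OneTissueParams-class].
#' @param aortaCentre aorta axis (x, y) voxel indices.
#' @param aortaRadius aorta radius (mm).
#' @param background body background activity (kBq/mL).
#' @param fdgShift inter-study voxel shift, length 3.
#' @param sigma0 frame-noise scale; frame noise s.d. is
#'   `sigma0 * sqrt(activity / duration)`.
#' @param sched acquisition [FrameSchedule-class].
#' @param input arterial [InputFunction-class].
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(48L, 48L, 48L), voxelSize = c(4, 4, 4),
                        tumourCentre = c(32, 30, 24), tumourRadius = 12,
                        params = oneTissueParams(0.9, 0.35, 0.05),
                        aortaCentre = c(16, 22), aortaRadius = 6,
                        background = 0.4, fdgShift = c(2L, -1L, 1L),
                        sigma0 = 2.1, sched = defaultFrameSchedule(),
                        input = makeInputFunction()) {
    new("PhantomSpec", dim = as.integer(dim),
        voxelSize = as.numeric(voxelSize),
        tumourCentre = as.numeric(tumourCentre),
        tumourRadius = as.numeric(tumourRadius), params = params,
        aortaCentre = as.numeric(aortaCentre),
        aortaRadius = as.numeric(aortaRadius),
        background = as.numeric(background),
        fdgShift = as.integer(fdgShift), sigma0 = as.numeric(sigma0),
        schedule = sched, input = input)
}

## Squared distance (mm^2) of every voxel centre from a point, and the
## body ellipsoid used for the attenuation/emission support.
voxelDist2 <- function(d, vox, centre) {
    dx <- (seq_len(d[1L]) - centre[1L]) * vox[1L]
    dy <- (seq_len(d[2L]) - centre[2L]) * vox[2L]
    dz <- (seq_len(d[3L]) - centre[3L]) * vox[3L]
    outer(outer(dx^2, dy^2, "+"), dz^2, "+")
}

bodyMask <- function(d, vox) {
    cx <- (d + 1) / 2
    ax <- 0.46 * d * vox            # semi-axes in mm, z spans the grid
    dx <- ((seq_len(d[1L]) - cx[1L]) * vox[1L] / ax[1L])^2
    dy <- ((seq_len(d[2L]) - cx[2L]) * vox[2L] / ax[2L])^2
    dz <- ((seq_len(d[3L]) - cx[3L]) * vox[3L] / (d[3L] * vox[3L]))^2
    outer(outer(dx, dy, "+"), dz, "+") <= 1
}

## Attenuation phantom (1/cm): soft-tissue body with a bone rod and an
## air pocket for registration texture.
attenuationArray <- function(spec) {
    d <- spec@dim; vox <- spec@voxelSize
    mu <- array(0, d)
    body <- bodyMask(d, vox)
    mu[body] <- 0.096
    cx <- (d + 1) / 2
    rod <- sweep2D(d, vox, c(cx[1L], cx[2L] + 0.25 * d[2L]), 10)
    mu[rod & body] <- 0.17
    air <- voxelDist2(d, vox, c(cx[1L] - 0.2 * d[1L], cx[2L] - 0.15 * d[2L],
                                cx[3L] + 0.15 * d[3L])) <= 20^2
    mu[air & body] <- 0.02
    mu
}

## Cylinder (axis along z) as a logical array.
sweep2D <- function(d, vox, centreXY, radiusMm) {
    dx <- (seq_len(d[1L]) - centreXY[1L]) * vox[1L]
    dy <- (seq_len(d[2L]) - centreXY[2L]) * vox[2L]
    inXY <- outer(dx^2, dy^2, "+") <= radiusMm^2
    array(rep(inXY, d[3L]), d)
}

## Translate a 3-D array by integer voxels, zero-filling.
shiftArray <- function(a, s) {
    d <- dim(a)
    out <- array(0, d)
    ov <- overlapRanges(d, as.integer(s))
    out[ov$fx, ov$fy, ov$fz] <- a[ov$mx, ov$my, ov$mz]
    out
}

#' Simulate one synthetic patient study
#'
#' Builds the full set of volumes the perfusion pipeline consumes: a 4-D
#' dynamic water study whose tumour voxels follow the one-tissue forward
#' model and whose aorta voxels follow the arterial input function, the
#' water-study attenuation image, a static FDG-SUV volume with a hot
#' lesion co-located with the tumour, and the FDG-study attenuation
#' image -- the FDG session acquired on a grid offset by the spec's
#' inter-study shift, as two sessions of a real patient would be. Frame
#' noise is zero-mean Gaussian with s.d.
#' `sigma0 * sqrt(activity / frameDuration)`, the standard count-rate
#' approximation for reconstructed PET frames; all randomness is driven
#' by `seed`. The water data are generated decay-corrected (as
#' reconstruction pipelines deliver them); `rawDecay = TRUE` produces
#' uncorrected frames instead.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for the noise generator.
#' @param rawDecay logical; generate decay-uncorrected water frames.
#' @return list with `water` (4-D [VolumeImage-class]), `waterAtten`,
#'   `fdg`, `fdgAtten`, and `truth` (the generating parameters: `params`,
#'   `input`, `fdgShift`, `tumourTAC`, `aortaTAC`).
#' @export
simulatePatient <- function(spec, seed = 1L, rawDecay = FALSE) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    rs <- localRNG(seed)
    on.exit(restoreRNG(rs))
    d <- spec@dim; vox <- spec@voxelSize
    sched <- spec@schedule
    nf <- nFrames(sched)
    tumour <- voxelDist2(d, vox, spec@tumourCentre) <= spec@tumourRadius^2
    aorta <- sweep2D(d, vox, spec@aortaCentre, spec@aortaRadius)
    body <- bodyMask(d, vox) | tumour | aorta
    tumourTAC <- forwardModel(spec@params, spec@input, sched)
    aortaVals <- frameAverage(fineGrid(max(frameEnd(sched)), 0.5),
                              evalInput(spec@input,
                                        fineGrid(max(frameEnd(sched)), 0.5)),
                              sched)
    aortaTAC <- timeActivityCurve(sched, aortaVals)
    water <- array(0, c(d, nf))
    dur <- frameDuration(sched)
    for (f in seq_len(nf)) {
        fr <- array(0, d)
        fr[body] <- spec@background
        fr[aorta] <- aortaVals[f]
        fr[tumour] <- activity(tumourTAC)[f]
        if (spec@sigma0 > 0) {
            sd <- spec@sigma0 * sqrt(pmax(fr, 0) / dur[f])
            fr <- fr + array(stats::rnorm(prod(d), 0, 1), d) * sd
        }
        water[, , , f] <- fr
    }
    waterDyn <- volumeImage(water, vox, modality = "water-dynamic",
                            schedule = sched, decayCorrected = TRUE)
    if (rawDecay) {
        lam <- log(2) / O15_HALF_LIFE
        fac <- exp(-lam * frameMid(sched))
        for (f in seq_len(nf))
            waterDyn@data[, , , f] <- waterDyn@data[, , , f] * fac[f]
        waterDyn@decayCorrected <- FALSE
        tumourTAC <- decayUncorrect(tumourTAC)
        aortaTAC <- decayUncorrect(aortaTAC)
    }
    mu <- attenuationArray(spec)
    waterAtten <- volumeImage(mu, vox, modality = "attenuation")
    fdgAtten <- volumeImage(shiftArray(mu, spec@fdgShift), vox,
                            modality = "attenuation")
    fdg <- array(0, d)
    fdg[bodyMask(d, vox)] <- 1
    sig <- spec@tumourRadius / 1.5
    hot <- 8 * exp(-voxelDist2(d, vox, spec@tumourCentre) / (2 * sig^2))
    fdg <- fdg + hot
    fdg <- shiftArray(fdg, spec@fdgShift)
    if (spec@sigma0 > 0)
        fdg <- fdg + array(stats::rnorm(prod(d), 0, 0.03), d) *
            (fdg > 0)
    fdgImg <- volumeImage(fdg, vox, modality = "FDG-SUV")
    list(water = waterDyn, waterAtten = waterAtten, fdg = fdgImg,
         fdgAtten = fdgAtten,
         truth = list(params = spec@params, input = spec@input,
                      fdgShift = spec@fdgShift, tumourTAC = tumourTAC,
                      aortaTAC = aortaTAC, seed = seed))
}

#' Simulate a patient cohort
#'
#' Draws per-patient kinetic parameters and response quantities with the
#' statistical structure the cohort analysis assumes: baseline perfusion
#' uniform over `K1Range`, week-2 perfusion change normal with the given
#' mean and s.d., clinical benefit assigned by the threshold rule
#' "benefit iff the week-2 perfusion decrease is at least
#' `benefitThreshold` percent" -- or, when `groupMeans` is supplied, by a
#' benefit label drawn first (probability `pBenefit`) with the change
#' then drawn from that group's normal distribution. SUV changes, drug
#' troughs and biomarker ratios are drawn per group so that the cohort
#' statistics have a known generating effect. Noise-free baseline and
#' week-2 tumour TACs plus the aorta TAC are generated per patient.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param K1Range baseline perfusion range (mL/g/min).
#' @param k2Range,V0Range kinetic parameter ranges.
#' @param changeMean,changeSd week-2 percent perfusion change
#'   distribution (threshold mode).
#' @param benefitThreshold percent decrease defining clinical benefit in
#'   threshold mode (default 50).
#' @param groupMeans optional list
#'   `list(benefit =, nonBenefit =, sd =, pBenefit =)` switching to
#'   label-first group mode.
#' @param sched acquisition schedule.
#' @return list with `records` (data.frame mirroring the packaged cohort
#'   table's columns) and `tacs` (per patient: `baseline`, `week2`,
#'   `aorta` [TimeActivityCurve-class] objects).
#' @export
simulateCohort <- function(n = 7, seed = 1L, K1Range = c(0.74, 1.52),
                           k2Range = c(0.2, 0.8), V0Range = c(0.03, 0.15),
                           changeMean = -54.6, changeSd = 23.4,
                           benefitThreshold = 50, groupMeans = NULL,
                           sched = defaultFrameSchedule()) {
    if (n < 1) stop("n must be at least 1")
    if (diff(K1Range) < 0 || diff(k2Range) < 0 || diff(V0Range) < 0)
        stop("invalid parameter ranges")
    rs <- localRNG(seed)
    on.exit(restoreRNG(rs))
    K1 <- stats::runif(n, K1Range[1L], K1Range[2L])
    k2 <- stats::runif(n, k2Range[1L], k2Range[2L])
    V0 <- stats::runif(n, V0Range[1L], V0Range[2L])
    clampChange <- function(x) pmin(pmax(x, -95), 95)  # flow stays positive
    if (is.null(groupMeans)) {
        change <- clampChange(stats::rnorm(n, changeMean, changeSd))
        benefit <- change <= -benefitThreshold
    } else {
        benefit <- stats::runif(n) < groupMeans$pBenefit
        change <- clampChange(stats::rnorm(n,
            ifelse(benefit, groupMeans$benefit, groupMeans$nonBenefit),
            groupMeans$sd))
    }
    suv0 <- stats::runif(n, 4, 12.5)
    suvChange2 <- stats::rnorm(n, ifelse(benefit, -45, -35), 10)
    suvChange4 <- suvChange2 + stats::rnorm(n, 0, 10)
    trough <- stats::rnorm(n, ifelse(benefit, 102, 74), 25)
    vegf <- exp(stats::rnorm(n, log(4.5), 0.4))
    svegfr2 <- exp(stats::rnorm(n, log(0.5), 0.3))
    fdgResp <- vapply(suvChange2, function(ch)
        classifyFdgResponse(ch) == "OR", logical(1))
    input <- makeInputFunction()
    tacs <- lapply(seq_len(n), function(i) {
        base <- oneTissueParams(K1[i], k2[i], V0[i])
        wk2 <- oneTissueParams(K1[i] * (1 + change[i] / 100), k2[i], V0[i])
        tEnd <- max(frameEnd(sched))
        tg <- fineGrid(tEnd, 0.5)
        list(baseline = forwardModel(base, input, sched),
             week2 = forwardModel(wk2, input, sched),
             aorta = timeActivityCurve(sched,
                 frameAverage(tg, evalInput(input, tg), sched)))
    })
    records <- data.frame(
        patient = seq_len(n),
        primary_tumour = rep("synthetic", n),
        reference_site = rep("synthetic lesion", n),
        baseline_perfusion_ml_min_g = round(K1, 2),
        perfusion_change_pct = round(change, 0),
        baseline_fdg_suv = round(suv0, 1),
        suv_change_wk2_pct = round(suvChange2, 0),
        suv_change_wk4_pct = round(suvChange4, 0),
        fdg_response = ifelse(fdgResp, "Yes", "No"),
        ref_lesion_recist = ifelse(benefit, "SD", "PD"),
        overall_recist = ifelse(benefit, "SD", "PD"),
        duration_cycles = ifelse(benefit,
                                 sample(4:12, n, replace = TRUE), 2L),
        clinical_benefit = ifelse(benefit, "Yes", "No"),
        trough_ng_ml = round(trough, 1),
        vegf_d15_d1 = round(vegf, 2),
        svegfr2_d15_d1 = round(svegfr2, 2))
    list(records = records, tacs = tacs,
         truth = list(K1 = K1, k2 = k2, V0 = V0, change = change,
                      benefit = benefit, seed = seed))
}

#' Add frame noise to a time-activity curve
#'
#' Zero-mean Gaussian noise with standard deviation
#' `sigma0 * sqrt(activity / frameDuration)` per frame, the standard
#' count-rate approximation for reconstructed PET frames (shorter or
#' hotter frames are relatively noisier). Negative noisy values are kept,
#' as reconstructed data can go negative. The default `sigma0` matches
#' the default phantom calibration (blood-pool peak-frame SNR of 10).
#'
#' @param tac a [TimeActivityCurve-class].
#' @param sigma0 noise scale (default 2.1).
#' @param seed integer seed; NULL (the default) draws from the current
#'   RNG stream, which is what simulation loops generating many
#'   independent curves should use.
#' @return a noisy [TimeActivityCurve-class].
#' @export
addTACNoise <- function(tac, sigma0 = 2.1, seed = NULL) {
    stopifnot(is(tac, "TimeActivityCurve"), sigma0 >= 0)
    if (!is.null(seed)) {
        rs <- localRNG(seed)
        on.exit(restoreRNG(rs))
    }
    av <- activity(tac)
    dur <- frameDuration(schedule(tac))
    timeActivityCurve(schedule(tac),
                      av + stats::rnorm(length(av)) * sigma0 *
                          sqrt(pmax(av, 0) / dur),
                      isDecayCorrected(tac))
}

#' The packaged seven-patient cohort table
#'
#' Transcription of the per-patient study results shipped with the
#' package: primary tumour type, reference lesion site, baseline
#' perfusion (mL/min/g), week-2 percent perfusion change, baseline
#' FDG-SUV, week-2 and week-4 percent SUV changes, overall FDG-PET
#' response, RECIST labels, treatment duration (6-week cycles), clinical
#' benefit, day-15 drug trough (ng/mL) and D15:D1 biomarker ratios
#' (missing for patients 6 and 7).
#'
#' @return data.frame with 7 rows.
#' @export
fixtureTable <- function() {
    path <- system.file("extdata", "cohort_response_table.csv",
                        package = "waterPET", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df
}
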