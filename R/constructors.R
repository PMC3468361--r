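#' Create a frame schedule
#'
#' @param start frame start times (s).
#' @param duration frame durations (s).
#' @return a [FrameSchedule-class].
#' @examples
#' frameSchedule(c(0, 5, 10), c(5, 5, 10))
#' @export
frameSchedule <- function(start, duration)
    new("FrameSchedule", start = as.numeric(start),
        duration = as.numeric(duration))

#' The default 10-frame bolus acquisition schedule
#'
#' Four 5-s frames, two 10-s frames and four 30-s frames, contiguous from
#' injection, spanning 160 s.
#'
#' @return a [FrameSchedule-class].
#' @export
defaultFrameSchedule <- function() {
    dur <- c(rep(5, 4), rep(10, 2), rep(30, 4))
    frameSchedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Create a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity frame values (kBq/mL).
#' @param decayCorrected logical; whether physical decay has been
#'   compensated (default TRUE, the usual state of reconstructed data).
#' @return a [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, activity, decayCorrected = TRUE)
    new("TimeActivityCurve", schedule = schedule,
        activity = as.numeric(activity),
        decayCorrected = isTRUE(decayCorrected))

#' Create a gamma-variate bolus input function
#'
#' C_a(t) = A * x^s * exp(s * (1 - x)) with x = (t - t0)/tp for t > t0 and
#' 0 otherwise, so the curve peaks at t0 + tp with value A.
#'
#' @param amplitude peak concentration A (kBq/mL).
#' @param onset appearance time t0 (s).
#' @param peakTime time-to-peak tp from onset (s).
#' @param shape gamma-variate shape s (dimensionless).
#' @return a [GammaVariateInput-class].
#' @export
gammaVariateInput <- function(amplitude, onset = 0, peakTime = 25, shape = 3)
    new("GammaVariateInput", amplitude = as.numeric(amplitude),
        onset = as.numeric(onset), peakTime = as.numeric(peakTime),
        shape = as.numeric(shape))

#' Create a sampled input function
#'
#' @param times sample times (s), strictly increasing.
#' @param values concentrations (kBq/mL).
#' @return a [SampledInput-class].
#' @export
sampledInput <- function(times, values)
    new("SampledInput", times = as.numeric(times),
        values = as.numeric(values))

#' One-tissue model parameters
#'
#' @param K1 influx rate (mL/g/min).
#' @param k2 washout rate (1/min).
#' @param V0 vascular volume fraction (mL/g).
#' @param delay bolus arrival delay (s) applied to the input function.
#' @return a [OneTissueParams-class].
#' @export
oneTissueParams <- function(K1, k2, V0 = 0, delay = 0)
    new("OneTissueParams", K1 = as.numeric(K1), k2 = as.numeric(k2),
        V0 = as.numeric(V0), delay = as.numeric(delay))

#' Create a spectral basis
#'
#' A grid of `nRates` log-spaced washout rates between `betaMin` and
#' `betaMax` (1/min), preceded by an exact zero rate (the trapping
#' column). The maximum rate bounds the fastest kinetics the spectrum can
#' represent and should exceed the expected vascular washout.
#'
#' @param nRates number of positive rates (default 48).
#' @param betaMax maximum rate (1/min, default 300).
#' @param betaMin smallest positive rate (1/min, default 1e-3).
#' @param fineStep convolution quadrature step (s, default 0.5).
#' @return a [SpectralBasis-class].
#' @export
spectralBasis <- function(nRates = 48, betaMax = 300, betaMin = 1e-3,
                          fineStep = 0.5) {
    stopifnot(nRates >= 1, betaMax >= betaMin, betaMin > 0)
    rates <- if (nRates == 1L) betaMax
             else exp(seq(log(betaMin), log(betaMax), length.out = nRates))
    new("SpectralBasis", rates = c(0, rates), fineStep = fineStep)
}

#' Create a volume image
#'
#' @param data 3-D or 4-D numeric array (frame axis last).
#' @param voxelSize voxel edge lengths (mm), length 3.
#' @param modality modality tag.
#' @param schedule [FrameSchedule-class], required for 4-D data.
#' @param decayCorrected logical flag for dynamic data.
#' @return a [VolumeImage-class].
#' @export
volumeImage <- function(data, voxelSize, modality = "unknown",
                        schedule = NULL, decayCorrected = TRUE) {
    storage.mode(data) <- "double"
    new("VolumeImage", data = data, voxelSize = as.numeric(voxelSize),
        modality = modality, schedule = schedule,
        decayCorrected = isTRUE(decayCorrected))
}

#' Create a VOI mask
#'
#' @param mask logical 3-D array.
#' @param voxelSize voxel edge lengths (mm).
#' @param provenance named list recording how the mask was made.
#' @return a [VOIMask-class].
#' @export
voiMask <- function(mask, voxelSize, provenance = list())
    new("VOIMask", mask = mask, voxelSize = as.numeric(voxelSize),
        provenance = provenance)

## ---- accessors ----

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "FrameSchedule", function(object) length(object@start))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStart", "FrameSchedule", function(object) object@start)

#' @rdname FrameSchedule-class
#' @export
setMethod("frameDuration", "FrameSchedule",
    function(object) object@duration)

#' @rdname FrameSchedule-class
#' @export
setMethod("frameMid", "FrameSchedule",
    function(object) object@start + object@duration / 2)

#' @rdname FrameSchedule-class
#' @export
setMethod("frameEnd", "FrameSchedule",
    function(object) object@start + object@duration)

#' @rdname TimeActivityCurve-class
#' @export
setMethod("activity", "TimeActivityCurve", function(object) object@activity)

#' @rdname TimeActivityCurve-class
#' @export
setMethod("schedule", "TimeActivityCurve", function(object) object@schedule)

#' @rdname TimeActivityCurve-class
#' @export
setMethod("nFrames", "TimeActivityCurve",
    function(object) nFrames(object@schedule))

#' @rdname TimeActivityCurve-class
#' @export
setMethod("isDecayCorrected", "TimeActivityCurve",
    function(object) object@decayCorrected)

#' @rdname SpectralBasis-class
#' @export
setMethod("basisRates", "SpectralBasis", function(object) object@rates)

#' @rdname SpectralResult-class
#' @export
setMethod("alphaWeights", "SpectralResult", function(object) object@alpha)

#' @rdname SpectralResult-class
#' @export
setMethod("fittedCurve", "SpectralResult",
    function(object) object@fittedCurve)

#' @rdname SpectralResult-class
#' @export
setMethod("residualNorm", "SpectralResult",
    function(object) object@residualNorm)

#' @rdname perfusionSum
#' @export
setMethod("perfusionSum", "SpectralResult",
    function(object) sum(object@alpha))

#' @rdname perfusionSum
#' @export
setMethod("perfusionTissue", "SpectralResult",
    function(object)
        sum(object@alpha[object@basis@rates < object@vascularCutoff]))

#' @rdname perfusionSum
#' @export
setMethod("vascularWeight", "SpectralResult",
    function(object)
        sum(object@alpha[object@basis@rates >= object@vascularCutoff]))

#' @rdname VolumeImage-class
#' @export
setMethod("imageData", "VolumeImage", function(object) object@data)

#' @rdname VolumeImage-class
#' @export
setMethod("voxelSize", "VolumeImage", function(object) object@voxelSize)

#' @rdname VolumeImage-class
#' @export
setMethod("modality", "VolumeImage", function(object) object@modality)

#' @rdname VolumeImage-class
#' @export
setMethod("schedule", "VolumeImage", function(object) object@schedule)

#' @rdname VolumeImage-class
#' @export
setMethod("isDecayCorrected", "VolumeImage",
    function(object) object@decayCorrected)

#' @rdname VOIMask-class
#' @export
setMethod("maskArray", "VOIMask", function(object) object@mask)

#' @rdname VOIMask-class
#' @export
setMethod("voxelCount", "VOIMask", function(object) sum(object@mask))

#' @rdname VOIMask-class
#' @export
setMethod("voxelSize", "VOIMask", function(object) object@voxelSize)

## ---- show methods ----

setMethod("show", "FrameSchedule", function(object) {
    cat("FrameSchedule:", nFrames(object), "frames,",
        frameStart(object)[1L], "-", max(frameEnd(object)), "s\n")
})

setMethod("show", "TimeActivityCurve", function(object) {
    cat("TimeActivityCurve:", nFrames(object), "frames, range",
        sprintf("%.3g..%.3g kBq/mL,", min(object@activity),
                max(object@activity)),
        if (object@decayCorrected) "decay-corrected" else "raw", "\n")
})

setMethod("show", "GammaVariateInput", function(object) {
    cat(sprintf(
        "GammaVariateInput: peak %.3g kBq/mL at %g s (onset %g s, shape %g)\n",
        object@amplitude, object@onset + object@peakTime, object@onset,
        object@shape))
})

setMethod("show", "SampledInput", function(object) {
    cat("SampledInput:", length(object@times), "samples on",
        sprintf("[%g, %g] s\n", min(object@times), max(object@times)))
})

setMethod("show", "OneTissueParams", function(object) {
    cat(sprintf(
        "OneTissueParams: K1 = %.4g mL/g/min, k2 = %.4g /min, V0 = %.4g, delay = %g s\n",
        object@K1, object@k2, object@V0, object@delay))
})

setMethod("show", "SpectralBasis", function(object) {
    cat(sprintf(
        "SpectralBasis: %d rates, 0 and %.3g..%.3g /min (fine step %g s)\n",
        length(object@rates), min(object@rates[-1L]), max(object@rates),
        object@fineStep))
})

setMethod("show", "SpectralResult", function(object) {
    cat(sprintf(
        paste0("SpectralResult: %d active components, perfusion %.4g",
               " (tissue %.4g + vascular %.4g) mL/g/min, residual %.3g\n"),
        sum(object@alpha > 0), perfusionSum(object),
        perfusionTissue(object), vascularWeight(object),
        object@residualNorm))
})

setMethod("show", "VolumeImage", function(object) {
    d <- dim(object@data)
    cat("VolumeImage [", object@modality, "]: ",
        paste(d, collapse = " x "), ", voxel ",
        paste(object@voxelSize, collapse = " x "), " mm\n", sep = "")
})

setMethod("show", "VOIMask", function(object) {
    cat("VOIMask:", voxelCount(object), "voxels (",
        sprintf("%.2f mL", voxelCount(object) *
                    prod(object@voxelSize) / 1000), ")\n")
})
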