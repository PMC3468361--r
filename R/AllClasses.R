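#' @import methods
NULL

#' Dynamic acquisition frame schedule
#'
#' Timing of a dynamic PET acquisition: one start time and one duration per
#' frame, both in seconds. The default constructor [frameSchedule()] checks
#' ordering and overlap; [defaultFrameSchedule()] returns the 10-frame
#' bolus protocol used throughout the package (4 x 5 s, 2 x 10 s, 4 x 30 s,
#' spanning 160 s).
#'
#' @slot start numeric, frame start times (s).
#' @slot duration numeric, frame durations (s).
#' @export
setClass("FrameSchedule",
    representation(start = "numeric", duration = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@start) != length(object@duration))
            msg <- c(msg, "start and duration must have equal length")
        if (length(object@start) == 0L)
            msg <- c(msg, "schedule must contain at least one frame")
        if (any(!is.finite(object@start)) || any(!is.finite(object@duration)))
            msg <- c(msg, "frame times must be finite")
        if (any(object@duration <= 0))
            msg <- c(msg, "frame durations must be positive")
        if (is.unsorted(object@start, strictly = TRUE))
            msg <- c(msg, "frames must be ordered by start time")
        n <- length(object@start)
        if (n > 1L) {
            ends <- object@start + object@duration
            if (any(object@start[-1L] < ends[-n] - 1e-9))
                msg <- c(msg, "frames must not overlap")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Time-activity curve
#'
#' Tracer concentration (kBq/mL) in a region, one value per acquisition
#' frame of its [FrameSchedule-class]. The `decayCorrected` flag records
#' whether physical decay of the tracer has been compensated.
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, frame values (kBq/mL). Negative values can arise
#'   from noise and are permitted.
#' @slot decayCorrected logical flag.
#' @export
setClass("TimeActivityCurve",
    representation(schedule = "FrameSchedule", activity = "numeric",
                   decayCorrected = "logical"),
    validity = function(object) {
        msg <- NULL
        if (length(object@activity) != length(object@schedule@start))
            msg <- c(msg, "activity length must equal frame count")
        if (any(!is.finite(object@activity)))
            msg <- c(msg, "activity values must be finite")
        if (length(object@decayCorrected) != 1L || is.na(object@decayCorrected))
            msg <- c(msg, "decayCorrected must be TRUE or FALSE")
        if (is.null(msg)) TRUE else msg
    })

#' Arterial input function
#'
#' Virtual class for the continuous-time arterial tracer concentration
#' C_a(t) (kBq/mL). Two representations are provided: a parametric
#' gamma-variate bolus ([GammaVariateInput-class]) and a sampled curve with
#' a linear-interpolation contract ([SampledInput-class]). Both evaluate
#' to zero before tracer appearance and are non-negative.
#'
#' @export
setClass("InputFunction", representation("VIRTUAL"))

#' @rdname InputFunction-class
#' @slot amplitude peak concentration (kBq/mL).
#' @slot onset appearance time t0 (s); C_a(t) = 0 for t < t0.
#' @slot peakTime time from onset to peak (s).
#' @slot shape dimensionless gamma-variate shape parameter.
#' @export
setClass("GammaVariateInput", contains = "InputFunction",
    representation(amplitude = "numeric", onset = "numeric",
                   peakTime = "numeric", shape = "numeric"),
    validity = function(object) {
        ok <- length(object@amplitude) == 1L && object@amplitude > 0 &&
            length(object@onset) == 1L && object@onset >= 0 &&
            length(object@peakTime) == 1L && object@peakTime > 0 &&
            length(object@shape) == 1L && object@shape > 0
        if (ok) TRUE else "amplitude, peakTime and shape must be positive; onset non-negative"
    })

#' @rdname InputFunction-class
#' @slot times sample times (s), strictly increasing, starting at or after 0.
#' @slot values concentrations (kBq/mL) at `times`; negative samples are
#'   clipped to zero at evaluation.
#' @export
setClass("SampledInput", contains = "InputFunction",
    representation(times = "numeric", values = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@times) < 2L)
            msg <- c(msg, "at least two samples required")
        if (length(object@times) != length(object@values))
            msg <- c(msg, "times and values must have equal length")
        if (is.unsorted(object@times, strictly = TRUE))
            msg <- c(msg, "times must be strictly increasing")
        if (any(object@times < 0))
            msg <- c(msg, "times must be non-negative")
        if (any(!is.finite(object@values)))
            msg <- c(msg, "values must be finite")
        if (is.null(msg)) TRUE else msg
    })

#' One-tissue compartment model parameters
#'
#' Parameters of the single-tissue model with explicit vascular volume:
#' influx rate K1 (mL/g/min, blood to tissue), washout rate k2 (1/min),
#' vascular volume fraction V0 (mL/g, tissue density taken as 1 g/mL) and
#' a bolus arrival delay (s) applied to the input function.
#'
#' @slot K1 numeric, mL/g/min, non-negative.
#' @slot k2 numeric, 1/min, non-negative.
#' @slot V0 numeric in [0, 1].
#' @slot delay numeric, seconds.
#' @export
setClass("OneTissueParams",
    representation(K1 = "numeric", k2 = "numeric", V0 = "numeric",
                   delay = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@K1 < 0) msg <- c(msg, "K1 must be non-negative")
        if (object@k2 < 0) msg <- c(msg, "k2 must be non-negative")
        if (object@V0 < 0 || object@V0 > 1)
            msg <- c(msg, "V0 must lie in [0, 1]")
        if (!is.finite(object@delay))
            msg <- c(msg, "delay must be finite")
        if (is.null(msg)) TRUE else msg
    })

#' Spectral basis of exponential rates
#'
#' The fixed grid of washout rates beta_i (1/min) used by [spectralFit()].
#' The first rate is exactly zero (irreversible trapping column); the
#' remainder are strictly increasing up to a predetermined maximum rate.
#' `fineStep` is the fine-grid sampling step (s) used for convolution
#' quadrature.
#'
#' @slot rates numeric, 1/min; `rates[1] == 0`, strictly increasing.
#' @slot fineStep numeric, seconds.
#' @export
setClass("SpectralBasis",
    representation(rates = "numeric", fineStep = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@rates) < 2L)
            msg <- c(msg, "basis needs at least two rates")
        if (object@rates[1L] != 0)
            msg <- c(msg, "first basis rate must be exactly 0")
        if (is.unsorted(object@rates, strictly = TRUE))
            msg <- c(msg, "rates must be strictly increasing")
        if (max(object@rates) <= 0)
            msg <- c(msg, "maximum rate must be positive")
        if (length(object@fineStep) != 1L || object@fineStep <= 0)
            msg <- c(msg, "fineStep must be a positive scalar")
        if (is.null(msg)) TRUE else msg
    })

#' Spectral deconvolution result
#'
#' Non-negative weights alpha_i (mL/g/min) on the basis rates, the fitted
#' curve on the original frame schedule, and the residual norm. Perfusion
#' summaries are derived by the accessors [perfusionSum()] (sum over all
#' alpha_i, the whole-spectrum convention), [perfusionTissue()] (sum over
#' rates below the vascular cutoff) and [vascularWeight()] (sum at and
#' above the cutoff); the three satisfy
#' `perfusionSum == perfusionTissue + vascularWeight` exactly.
#'
#' @slot alpha numeric, non-negative weights (mL/g/min), one per basis rate.
#' @slot basis the [SpectralBasis-class] used.
#' @slot fittedCurve fitted [TimeActivityCurve-class].
#' @slot residualNorm Euclidean norm of the frame residuals.
#' @slot vascularCutoff rate (1/min) at and above which weight is counted
#'   as vascular.
#' @export
setClass("SpectralResult",
    representation(alpha = "numeric", basis = "SpectralBasis",
                   fittedCurve = "TimeActivityCurve",
                   residualNorm = "numeric", vascularCutoff = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@alpha) != length(object@basis@rates))
            msg <- c(msg, "one weight per basis rate required")
        if (any(object@alpha < 0))
            msg <- c(msg, "weights must be non-negative")
        if (length(object@vascularCutoff) != 1L || object@vascularCutoff <= 0)
            msg <- c(msg, "vascularCutoff must be a positive scalar")
        if (is.null(msg)) TRUE else msg
    })

#' Voxel volume (static or dynamic)
#'
#' A 3-D static or 4-D dynamic voxel array with physical voxel size (mm)
#' and a modality tag. Dynamic volumes carry the [FrameSchedule-class] of
#' their frame axis and a decay-correction flag that propagates to
#' extracted time-activity curves.
#'
#' @slot data numeric array, 3-D or 4-D (frame axis last).
#' @slot voxelSize numeric length 3, mm, positive.
#' @slot modality character tag, e.g. "FDG-SUV", "water-dynamic",
#'   "attenuation", "summed".
#' @slot schedule a [FrameSchedule-class] for 4-D data, else NULL.
#' @slot decayCorrected logical.
#' @export
setClass("VolumeImage",
    representation(data = "array", voxelSize = "numeric",
                   modality = "character", schedule = "ANY",
                   decayCorrected = "logical"),
    validity = function(object) {
        msg <- NULL
        nd <- length(dim(object@data))
        if (!nd %in% c(3L, 4L))
            msg <- c(msg, "data must be a 3-D or 4-D array")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 positive values (mm)")
        if (nd == 4L) {
            if (!is(object@schedule, "FrameSchedule"))
                msg <- c(msg, "4-D volumes require a FrameSchedule")
            else if (dim(object@data)[4L] != length(object@schedule@start))
                msg <- c(msg, "frame axis must match the schedule length")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Volume-of-interest mask
#'
#' Boolean voxel set on the grid of its source [VolumeImage-class],
#' with provenance (threshold fraction, source modality, source maximum).
#'
#' @slot mask logical 3-D array.
#' @slot voxelSize numeric length 3, mm.
#' @slot provenance named list describing how the mask was produced.
#' @export
setClass("VOIMask",
    representation(mask = "array", voxelSize = "numeric",
                   provenance = "list"),
    validity = function(object) {
        msg <- NULL
        if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
            msg <- c(msg, "mask must be a logical 3-D array")
        if (!any(object@mask))
            msg <- c(msg, "mask must contain at least one voxel")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 positive values (mm)")
        if (is.null(msg)) TRUE else msg
    })

#' Synthetic patient phantom specification
#'
#' Geometry, kinetics and noise level of the 4-D digital phantom produced
#' by [simulatePatient()]: a spherical tumour lesion following the
#' one-tissue model, a descending-aorta cylinder following the arterial
#' input function, a uniform body background, a matched static FDG volume
#' and a pair of attenuation images offset by a known inter-study shift.
#'
#' @slot dim integer length 3, grid size (voxels).
#' @slot voxelSize numeric length 3, mm.
#' @slot tumourCentre numeric length 3, voxel indices.
#' @slot tumourRadius numeric, mm.
#' @slot params [OneTissueParams-class] of the tumour.
#' @slot aortaCentre numeric length 2, (x, y) voxel indices of the aorta axis.
#' @slot aortaRadius numeric, mm.
#' @slot background numeric, body background activity (kBq/mL).
#' @slot fdgShift integer length 3, voxel shift of the FDG study grid
#'   relative to the water study grid.
#' @slot sigma0 numeric, frame-noise scale (see [simulatePatient()]).
#' @slot schedule [FrameSchedule-class] of the dynamic acquisition.
#' @slot input [InputFunction-class] driving the phantom.
#' @export
setClass("PhantomSpec",
    representation(dim = "integer", voxelSize = "numeric",
                   tumourCentre = "numeric", tumourRadius = "numeric",
                   params = "OneTissueParams", aortaCentre = "numeric",
                   aortaRadius = "numeric", background = "numeric",
                   fdgShift = "integer", sigma0 = "numeric",
                   schedule = "FrameSchedule", input = "InputFunction"),
    validity = function(object) {
        msg <- NULL
        if (length(object@dim) != 3L || any(object@dim < 8L))
            msg <- c(msg, "dim must be 3 values >= 8")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be positive")
        rTum <- object@tumourRadius / object@voxelSize[1L]
        if (any(object@tumourCentre - rTum < 1) ||
            any(object@tumourCentre + rTum > object@dim))
            msg <- c(msg, "tumour sphere must lie inside the image")
        rAo <- object@aortaRadius / object@voxelSize[1L]
        if (any(object@aortaCentre - rAo < 1) ||
            any(object@aortaCentre + rAo > object@dim[1:2]))
            msg <- c(msg, "aorta cylinder must lie inside the image")
        dxy <- sqrt(sum((object@tumourCentre[1:2] - object@aortaCentre)^2))
        if (dxy * object@voxelSize[1L] <= object@tumourRadius + object@aortaRadius)
            msg <- c(msg, "tumour and aorta must be disjoint")
        if (object@sigma0 < 0) msg <- c(msg, "sigma0 must be non-negative")
        if (object@background < 0) msg <- c(msg, "background must be non-negative")
        if (is.null(msg)) TRUE else msg
    })
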