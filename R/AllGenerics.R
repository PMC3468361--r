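#' @rdname FrameSchedule-class
#' @param object an object.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameStart", function(object) standardGeneric("frameStart"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameMid", function(object) standardGeneric("frameMid"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameEnd", function(object) standardGeneric("frameEnd"))

#' @rdname TimeActivityCurve-class
#' @param object an object.
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("isDecayCorrected",
    function(object) standardGeneric("isDecayCorrected"))

#' Evaluate an input function
#'
#' Evaluates the arterial concentration C_a(t) at arbitrary times (s).
#' Times before tracer appearance give 0. A [SampledInput-class] is
#' linearly interpolated between its samples and held at its last value
#' beyond them (zero before the first sample); negative interpolants are
#' clipped to zero.
#'
#' @param fn an [InputFunction-class].
#' @param t numeric times (s).
#' @return numeric concentrations (kBq/mL).
#' @export
setGeneric("evalInput", function(fn, t) standardGeneric("evalInput"))

#' @rdname evalInput
#' @details [inputSupport()] returns the closed interval of times (s) on
#'   which the input function is defined for convolution purposes.
#' @export
setGeneric("inputSupport", function(fn) standardGeneric("inputSupport"))

#' @rdname SpectralBasis-class
#' @param object an object.
#' @export
setGeneric("basisRates", function(object) standardGeneric("basisRates"))

#' @rdname SpectralResult-class
#' @param object an object.
#' @export
setGeneric("alphaWeights", function(object) standardGeneric("alphaWeights"))

#' @rdname SpectralResult-class
#' @export
setGeneric("fittedCurve", function(object) standardGeneric("fittedCurve"))

#' @rdname SpectralResult-class
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))

#' Perfusion estimates from a spectral fit
#'
#' [perfusionSum()] is the whole-spectrum convention (sum of all alpha_i,
#' tissue perfusion plus vascular-volume contribution); [perfusionTissue()]
#' sums only weights at rates below the vascular cutoff and estimates K1;
#' [vascularWeight()] is the remainder. All in mL/g/min.
#'
#' @param object a [SpectralResult-class].
#' @return numeric scalar (mL/g/min).
#' @export
setGeneric("perfusionSum", function(object) standardGeneric("perfusionSum"))

#' @rdname perfusionSum
#' @export
setGeneric("perfusionTissue",
    function(object) standardGeneric("perfusionTissue"))

#' @rdname perfusionSum
#' @export
setGeneric("vascularWeight",
    function(object) standardGeneric("vascularWeight"))

#' @rdname VolumeImage-class
#' @param object an object.
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname VolumeImage-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname VolumeImage-class
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname VOIMask-class
#' @param object an object.
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname VOIMask-class
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))
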