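#' @rdname evalInput
#' @export
setMethod("evalInput", signature("GammaVariateInput", "numeric"),
    function(fn, t) {
        x <- (t - fn@onset) / fn@peakTime
        out <- numeric(length(t))
        pos <- x > 0
        out[pos] <- fn@amplitude * x[pos]^fn@shape *
            exp(fn@shape * (1 - x[pos]))
        out
    })

#' @rdname evalInput
#' @export
setMethod("evalInput", signature("SampledInput", "numeric"),
    function(fn, t) {
        out <- stats::approx(fn@times, fn@values, xout = t,
                             method = "linear", yleft = 0,
                             yright = fn@values[length(fn@values)])$y
        pmax(out, 0)
    })

#' @rdname evalInput
#' @export
setMethod("inputSupport", "GammaVariateInput",
    function(fn) c(0, Inf))

#' @rdname evalInput
#' @export
setMethod("inputSupport", "SampledInput",
    function(fn) c(0, max(fn@times)))

#' Fit a gamma-variate bolus to an aorta time-activity curve
#'
#' Estimates the continuous arterial input function from a frame-sampled
#' blood-pool curve by least-squares fitting a gamma-variate bolus whose
#' *frame averages* match the measured values -- a short early frame
#' averages over a rapidly rising bolus, so matching frame averages
#' rather than midpoint samples removes the discretisation bias that a
#' simple interpolation contract would leave in the deconvolution.
#' Levenberg-Marquardt over (amplitude, onset, time-to-peak, shape),
#' deterministic.
#'
#' @param tac a blood-pool [TimeActivityCurve-class].
#' @param fineStep quadrature step (s) for the frame averaging.
#' @return a [GammaVariateInput-class]; attributes `residualNorm` and
#'   `converged` carry the fit diagnostics.
#' @seealso [inputFromTAC()] for the non-parametric interpolation
#'   alternative.
#' @export
fitInputFunction <- function(tac, fineStep = 0.5) {
    stopifnot(is(tac, "TimeActivityCurve"))
    sched <- schedule(tac)
    a <- activity(tac)
    if (max(a) <= 0)
        stop("degenerate input: blood curve has no positive frames")
    tg <- fineGrid(max(frameEnd(sched)), fineStep)
    onset0 <- frameStart(sched)[which(a > 0.05 * max(a))[1L]]
    p0 <- c(A = 1.2 * max(a), t0 = max(onset0, 1), tp = 20, s = 3)
    lower <- c(1e-3, 0, 2, 0.5)
    upper <- c(20 * max(a), 90, 90, 12)
    resFun <- function(p) {
        fn <- gammaVariateInput(p[1L], p[2L], p[3L], p[4L])
        frameAverage(tg, evalInput(fn, tg), sched) - a
    }
    fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                              fn = resFun,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 300, ftol = 1e-12,
                                  ptol = 1e-12))
    out <- gammaVariateInput(fit$par[1L], fit$par[2L], fit$par[3L],
                             fit$par[4L])
    attr(out, "residualNorm") <- sqrt(sum(fit$fvec^2))
    attr(out, "converged") <- fit$info %in% 1:4
    if (!attr(out, "converged"))
        warning("input-function fit did not converge: ", fit$message)
    out
}

#' Build an input function from an aorta time-activity curve
#'
#' Converts a VOI-mean TAC (typically from a descending-aorta VOI on the
#' dynamic study) into a [SampledInput-class] sampled at the frame
#' mid-times, with a terminal sample at the end of the last frame so that
#' the input support covers the full acquisition window.
#'
#' @param tac a [TimeActivityCurve-class].
#' @return a [SampledInput-class].
#' @export
inputFromTAC <- function(tac) {
    sch <- schedule(tac)
    tm <- frameMid(sch)
    tEnd <- max(frameEnd(sch))
    v <- activity(tac)
    times <- c(tm, tEnd)
    values <- c(v, v[length(v)])
    if (tm[1L] > 0) {       # anchor at zero activity before the bolus
        times <- c(0, times)
        values <- c(0, values)
    }
    sampledInput(times, values)
}
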