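## Core kinetic machinery. Time is in seconds internally; rate constants
## (K1, k2, beta) cross the interface in per-minute units and are converted
## here, in one place.

PER_MIN <- 1 / 60                    # multiply a 1/min rate to get 1/s
O15_HALF_LIFE <- 122.24              # seconds

fineGrid <- function(tEnd, step = 0.5) seq(0, tEnd + step / 2, by = step)

## Trapezoidal convolution of a sampled curve with exp(-b t) for several
## rates at once: Y[, j] = int_0^t ca(s) exp(-b_j (t - s)) ds on the grid.
## The recursion y(t+h) = y(t) e^{-bh} + h/2 (ca(t+h) + ca(t) e^{-bh}) is
## exact for the trapezoidal rule and runs one vectorised pass over time.
convolveGrid <- function(ca, bsec, h) {
    n <- length(ca)
    nb <- length(bsec)
    E <- exp(-bsec * h)
    Y <- matrix(0, n, nb)
    if (n >= 2L) {
        prev <- numeric(nb)
        for (i in 2:n) {
            prev <- prev * E + (h / 2) * (ca[i] + ca[i - 1L] * E)
            Y[i, ] <- prev
        }
    }
    Y
}

## Time-average of a fine-grid curve over each frame interval
## [start, start + duration], by the trapezoidal rule when the frame
## boundaries fall on the grid (the usual case; O(h^2) accurate), with a
## plain sample mean as the fallback for unaligned schedules.
frameWeights <- function(tGrid, sched) {
    s <- frameStart(sched)
    e <- frameEnd(sched)
    h <- tGrid[2L] - tGrid[1L]
    lapply(seq_along(s), function(f) {
        idx <- which(tGrid >= s[f] - 1e-9 & tGrid <= e[f] + 1e-9)
        if (length(idx) < 2L)
            stop("quadrature grid too coarse for frame ", f)
        aligned <- abs(tGrid[idx[1L]] - s[f]) < 1e-6 &&
            abs(tGrid[idx[length(idx)]] - e[f]) < 1e-6
        w <- rep(1, length(idx))
        if (aligned) {
            w[c(1L, length(idx))] <- 0.5
            w <- w / (length(idx) - 1L)
        } else {
            w <- w / length(idx)
        }
        list(idx = idx, w = w)
    })
}

frameAverage <- function(tGrid, values, sched) {
    fw <- frameWeights(tGrid, sched)
    vapply(fw, function(x) sum(values[x$idx] * x$w), numeric(1))
}

frameAverageMatrix <- function(tGrid, M, sched) {
    fw <- frameWeights(tGrid, sched)
    out <- matrix(0, length(fw), ncol(M))
    for (f in seq_along(fw))
        out[f, ] <- as.numeric(crossprod(M[fw[[f]]$idx, , drop = FALSE],
                                         fw[[f]]$w))
    out
}

#' Convolve an input function with a decaying exponential
#'
#' Computes (C_a %*% exp(-beta t))(t) = int_0^t C_a(s) exp(-beta (t - s)) ds
#' by trapezoidal quadrature on a fine time grid. For `beta = 0` this is
#' the running integral of C_a. The rate is given in 1/min; times in
#' seconds; the result is in kBq s / mL.
#'
#' @param inputFn an [InputFunction-class].
#' @param beta washout rate (1/min), non-negative.
#' @param evalTimes times (s) at which to evaluate; must lie inside the
#'   input support window.
#' @param fineStep quadrature step (s, default 0.5).
#' @return numeric vector, one value per element of `evalTimes`.
#' @examples
#' fn <- gammaVariateInput(40, onset = 10)
#' convolveExponential(fn, 0.4, c(30, 60, 120))
#' @export
convolveExponential <- function(inputFn, beta, evalTimes, fineStep = 0.5) {
    if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
        beta < 0)
        stop("'beta' must be a single non-negative rate (1/min)")
    sup <- inputSupport(inputFn)
    if (any(evalTimes < sup[1L] - 1e-9) || any(evalTimes > sup[2L] + 1e-9))
        stop("'evalTimes' outside the input function support window [",
             sup[1L], ", ", sup[2L], "] s")
    if (length(evalTimes) == 0L) return(numeric(0))
    tg <- fineGrid(max(evalTimes), fineStep)
    ca <- evalInput(inputFn, tg)
    y <- convolveGrid(ca, beta * PER_MIN, fineStep)[, 1L]
    stats::approx(tg, y, xout = evalTimes, rule = 2)$y
}

#' Forward one-tissue compartment model with vascular term
#'
#' Evaluates the detected activity
#' M(t) = V0 C_a(t - delay) + K1 conv(C_a(. - delay), exp(-k2 t))(t)
#' (K1 and k2 in per-minute units, converted internally) and averages it
#' over each acquisition frame, yielding the noise-free frame values a
#' scanner would report for a region obeying the model.
#'
#' @param params a [OneTissueParams-class].
#' @param inputFn an [InputFunction-class].
#' @param sched a [FrameSchedule-class]; must lie inside the input
#'   support window.
#' @param fineStep quadrature step (s).
#' @return a decay-corrected [TimeActivityCurve-class].
#' @examples
#' fn <- gammaVariateInput(40, onset = 10)
#' forwardModel(oneTissueParams(0.8, 0.4, 0.05), fn, defaultFrameSchedule())
#' @export
forwardModel <- function(params, inputFn, sched, fineStep = 0.5) {
    stopifnot(is(params, "OneTissueParams"), is(inputFn, "InputFunction"),
              is(sched, "FrameSchedule"))
    validObject(params)
    tEnd <- max(frameEnd(sched))
    sup <- inputSupport(inputFn)
    if (tEnd > sup[2L] + 1e-9)
        stop("schedule extends beyond the input function support window")
    tg <- fineGrid(tEnd, fineStep)
    ca <- evalInput(inputFn, tg - params@delay)
    ca[tg < params@delay] <- 0
    conv <- convolveGrid(ca, params@k2 * PER_MIN, fineStep)[, 1L]
    m <- params@V0 * ca + params@K1 * PER_MIN * conv
    timeActivityCurve(sched, frameAverage(tg, m, sched),
                      decayCorrected = TRUE)
}

#' Relative change in percent
#'
#' 100 * (followup - baseline) / baseline. The baseline must be positive.
#'
#' @param baseline,followup numeric scalars or vectors (recycled).
#' @return percent change.
#' @export
percentChange <- function(baseline, followup) {
    if (any(!is.finite(baseline)) || any(baseline <= 0))
        stop("'baseline' must be positive")
    100 * (followup - baseline) / baseline
}

#' Decay-correct a time-activity curve
#'
#' Multiplies each frame value by exp(lambda t_mid) with
#' lambda = ln(2) / halfLife, referencing activity to injection time.
#' Refuses to correct twice. [decayUncorrect()] is the exact inverse.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param halfLife radionuclide half-life (s); default the 15-O value
#'   122.24 s.
#' @return a [TimeActivityCurve-class] with the flag updated.
#' @export
decayCorrect <- function(tac, halfLife = O15_HALF_LIFE) {
    stopifnot(is(tac, "TimeActivityCurve"), halfLife > 0)
    if (isDecayCorrected(tac))
        stop("curve is already decay-corrected")
    lam <- log(2) / halfLife
    timeActivityCurve(schedule(tac),
                      activity(tac) * exp(lam * frameMid(schedule(tac))),
                      decayCorrected = TRUE)
}

#' @rdname decayCorrect
#' @export
decayUncorrect <- function(tac, halfLife = O15_HALF_LIFE) {
    stopifnot(is(tac, "TimeActivityCurve"), halfLife > 0)
    if (!isDecayCorrected(tac))
        stop("curve is not decay-corrected")
    lam <- log(2) / halfLife
    timeActivityCurve(schedule(tac),
                      activity(tac) * exp(-lam * frameMid(schedule(tac))),
                      decayCorrected = FALSE)
}
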