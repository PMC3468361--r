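## Independent oracles used across the suite. These deliberately avoid the
## package's own convolution/NNLS/test-statistic code paths.

## Adaptive-quadrature convolution oracle:
## int_0^t Ca(s) exp(-beta/60 (t - s)) ds via stats::integrate.
convOracle <- function(fn, beta, t) {
    vapply(t, function(tt) {
        if (tt <= 0) return(0)
        stats::integrate(function(s)
            evalInput(fn, s) * exp(-beta / 60 * (tt - s)),
            lower = 0, upper = tt, rel.tol = 1e-10,
            subdivisions = 2000L)$value
    }, numeric(1))
}

## Exhaustive refined grid search over the non-negative quadrant for a
## two-column non-negative least-squares problem.
gridNNLS2 <- function(A, b, upper = NULL, rounds = 8, nGrid = 61) {
    if (is.null(upper))
        upper <- rep(2 * max(abs(b)) / max(abs(A)), 2)
    lo <- c(0, 0)
    hi <- upper
    best <- c(0, 0)
    for (r in seq_len(rounds)) {
        g1 <- seq(lo[1], hi[1], length.out = nGrid)
        g2 <- seq(lo[2], hi[2], length.out = nGrid)
        rss <- outer(g1, g2, Vectorize(function(x1, x2)
            sum((b - A %*% c(x1, x2))^2)))
        ij <- arrayInd(which.min(rss), dim(rss))
        best <- c(g1[ij[1]], g2[ij[2]])
        span <- (hi - lo) / (nGrid - 1)
        lo <- pmax(0, best - 2 * span)
        hi <- best + 2 * span
    }
    best
}

## One-sided Welch p-value through explicit numerical integration of the
## t density (no pt()).
welchOracle <- function(a, b) {
    na <- length(a); nb <- length(b)
    va <- var(a); vb <- var(b)
    se2 <- va / na + vb / nb
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    dens <- function(x)
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
            (1 + x^2 / df)^(-(df + 1) / 2)
    stats::integrate(dens, lower = -Inf, upper = tstat,
                     rel.tol = 1e-12)$value
}
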