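#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||_2 subject to x >= 0 by the classic active-set
#' algorithm. The inner unconstrained solves use the singular value
#' decomposition with a relative tolerance, so near-duplicate columns
#' (which arise when very fast exponential basis functions become
#' numerically proportional to the input curve) are handled gracefully
#' instead of aborting. Deterministic: no randomness, fixed tie-breaking
#' (largest-gradient column enters first).
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param maxIter iteration cap (default 10 * n).
#' @return list with `x` (the solution), `residualNorm` and `iterations`.
#' @export
nnlsSolve <- function(A, b, maxIter = 10 * ncol(A)) {
    stopifnot(is.matrix(A), length(b) == nrow(A))
    n <- ncol(A)
    x <- numeric(n)
    passive <- logical(n)
    tol <- 10 * .Machine$double.eps * max(abs(A)) * max(nrow(A), n)
    w <- as.numeric(crossprod(A, b))
    iter <- 0L
    lsSolve <- function(Ap, b) {
        sv <- svd(Ap)
        keep <- sv$d > max(sv$d[1L], 0) * 1e-10
        if (!any(keep)) return(numeric(ncol(Ap)))
        sv$v[, keep, drop = FALSE] %*%
            ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
    }
    while (iter < maxIter) {
        wFree <- w
        wFree[passive] <- -Inf
        if (max(wFree) <= tol) break
        passive[which.max(wFree)] <- TRUE
        repeat {
            iter <- iter + 1L
            s <- numeric(n)
            s[passive] <- lsSolve(A[, passive, drop = FALSE], b)
            if (min(s[passive]) > 0) {
                x <- s
                break
            }
            neg <- passive & s <= 0
            step <- min(x[neg] / (x[neg] - s[neg]))
            x <- x + step * (s - x)
            passive[passive & x <= tol] <- FALSE
            x[!passive] <- 0
            if (iter >= maxIter) break
        }
        w <- as.numeric(crossprod(A, b - A %*% x))
    }
    x[x < 0] <- 0
    list(x = x, residualNorm = sqrt(sum((b - A %*% x)^2)),
         iterations = iter)
}
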