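## Metabolic response classification and cohort statistics.

#' Lean-body-mass corrected standardised uptake value (SUL)
#'
#' SUL = concentration x lean body mass / injected dose, with
#' concentration in kBq/mL, mass in kg and dose in MBq; the kBq/MBq and
#' kg/g factors cancel, giving SUL in g/mL. A 370 MBq dose, 50 kg lean
#' mass and 7.4 kBq/mL tissue concentration give SUL = 1.
#'
#' @param concentration tissue concentration (kBq/mL), positive.
#' @param injectedDose injected activity (MBq), positive.
#' @param leanBodyMass lean body mass (kg), positive.
#' @return SUL (g/mL).
#' @export
suvLean <- function(concentration, injectedDose, leanBodyMass) {
    if (any(concentration <= 0) || any(injectedDose <= 0) ||
        any(leanBodyMass <= 0))
        stop("all inputs must be positive")
    concentration * leanBodyMass / injectedDose
}

#' Classify FDG-PET metabolic response
#'
#' Applies the lesion-level change rules: progressive disease (PD) if any
#' lesion's lean-corrected SUV rose by 15 percent or more, or if new
#' lesions appeared (new lesions take precedence over everything);
#' overall response (OR) if every baseline lesion fell by 20 percent or
#' more with no new lesions; MIXED if OR-level and PD-level lesions
#' coexist; stable disease (SD) otherwise. Both thresholds are inclusive.
#'
#' @param changes numeric vector of percent changes in lean-corrected SUV
#'   versus baseline, one per lesion present at baseline.
#' @param newLesions logical; any new lesion on follow-up.
#' @return one of "OR", "PD", "MIXED", "SD".
#' @examples
#' classifyFdgResponse(-39)                 # OR
#' classifyFdgResponse(c(-10, 20))          # PD
#' classifyFdgResponse(c(-25, -30, 16))     # MIXED
#' @export
classifyFdgResponse <- function(changes, newLesions = FALSE) {
    if (length(changes) == 0L)
        stop("at least one lesion change is required")
    if (any(!is.finite(changes)))
        stop("lesion changes must be finite")
    if (isTRUE(newLesions)) return("PD")
    pdLevel <- any(changes >= 15)
    orLevel <- any(changes <= -20)
    if (pdLevel && orLevel) return("MIXED")
    if (pdLevel) return("PD")
    if (all(changes <= -20)) return("OR")
    "SD"
}

#' One-sided Welch t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' the one-sided p-value for the alternative mean(a) < mean(b). When both
#' groups are constant the test is degenerate: equal means give p = 0.5
#' by convention and unequal means a limiting 0/1, both flagged.
#'
#' @param a,b numeric vectors, at least two values each.
#' @return list with `t`, `df`, `p` and `degenerate`.
#' @export
welchTOneSided <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least two values")
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
        warning("degenerate test: zero variance in both groups")
        if (mean(a) == mean(b))
            return(list(t = 0, df = NA_real_, p = 0.5, degenerate = TRUE))
        return(list(t = ifelse(mean(a) < mean(b), -Inf, Inf),
                    df = NA_real_,
                    p = as.numeric(mean(a) > mean(b)), degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, alternative = "less", var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the 95 percent confidence interval
#' from the Fisher z-transform (the standard normal-theory interval).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `ci` (length 2), `p` (two-sided) and `n`.
#' @export
pearsonWithCI <- function(x, y, conf = 0.95) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("at least three complete pairs required")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in an argument")
    ct <- stats::cor.test(x, y, conf.level = conf)
    list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
         p = ct$p.value, n = length(x))
}

#' One-sample z-test against a reference value
#'
#' z = (mean - reference) / (s / sqrt(n)) with the sample standard
#' deviation (n - 1 divisor) and the one-sided p-value for mean >
#' reference, as used for drug trough levels against a clinical
#' reference concentration.
#'
#' @param values numeric vector, n >= 2, non-constant.
#' @param reference reference value (same units as `values`).
#' @return list with `z`, `p`, `n` and `mean`.
#' @export
ztestVsReference <- function(values, reference) {
    if (length(values) < 2L) stop("at least two values required")
    s <- stats::sd(values)
    if (s == 0) stop("zero variance")
    z <- (mean(values) - reference) / (s / sqrt(length(values)))
    list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
         n = length(values), mean = mean(values))
}
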