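## Internal numeric helpers shared across modules.

## Evaluate a polynomial with coefficients c0 + c1 x + c2 x^2 + ...
.polyEval <- function(coef, x) {
    y <- rep(coef[length(coef)], length(x))
    for (j in rev(seq_len(length(coef) - 1L)))
        y <- y * x + coef[j]
    y
}

## Derivative coefficients of a polynomial (intercept-first convention).
.polyDeriv <- function(coef) {
    if (length(coef) == 1L) return(0)
    coef[-1L] * seq_len(length(coef) - 1L)
}

## Gaussian smoothing with reflective padding; sd in samples.
.gaussSmooth <- function(x, sd) {
    if (sd <= 0) return(x)
    k <- max(1L, ceiling(4 * sd))
    w <- stats::dnorm(seq(-k, k), 0, sd)
    w <- w / sum(w)
    n <- length(x)
    k <- min(k, n - 1L)
    w <- w[(length(w) %/% 2 + 1 - k):(length(w) %/% 2 + 1 + k)]
    w <- w / sum(w)
    xp <- c(rev(x[seq_len(k)]), x, rev(x[(n - k + 1L):n]))
    as.numeric(stats::filter(xp, w, sides = 2))[(k + 1L):(k + n)]
}

## Rolling extrema with edge truncation (windows shrink at the ends).
.rollFun <- function(x, window, fun) {
    n <- length(x)
    h <- max(1L, window %/% 2L)
    vapply(seq_len(n), function(i)
        fun(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

.rollMin <- function(x, window) .rollFun(x, window, min)
.rollMax <- function(x, window) .rollFun(x, window, max)

## Trapezoidal integral of y over unit-spaced samples idx[1]..idx[2].
.trapz <- function(y, from, to) {
    if (to <= from) return(0)
    seg <- y[from:to]
    sum((seg[-1L] + seg[-length(seg)]) / 2)
}

## Odd window for runmed, clipped to the series length.
.oddWindow <- function(window, n) {
    w <- min(window, n - (1 - n %% 2))
    if (w %% 2 == 0) w <- w - 1L
    max(3L, w)
}

#' Format p-values with mixed display precision
#'
#' Clinical contingency tables commonly print p-values to one decimal when
#' p >= 0.2 and to three decimals below that; reports produced by
#' [summarizeCohort()] follow the same convention.
#'
#' @param p numeric vector of p-values.
#' @return character vector of formatted p-values.
#' @examples
#' formatPValue(c(0.0037, 0.33129, 0.90046))
#' @export
formatPValue <- function(p) {
    vapply(p, function(pi) {
        if (is.na(pi)) return(NA_character_)
        if (pi >= 0.2) sprintf("%.1f", pi) else sprintf("%.3f", pi)
    }, character(1))
}
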