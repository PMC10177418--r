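#' Fit a concentration-response curve
#'
#' Fits the saturating hyperbolic response `signal = smax c / (kHalf +
#' c)` (linear at low concentration with slope `smax / kHalf`) to
#' calibration points by nonlinear least squares. When the points are
#' effectively linear (the hyperbola is unidentifiable), the fit falls
#' back to a straight line through the origin, which the inversion and
#' LOD machinery treat as the low-concentration limit.
#'
#' @param conc concentrations, mg/L; at least 3 distinct positive values.
#' @param signal integrated band signals, signal-position units.
#' @return a [ConcentrationCurve-class]. A point set that decreases with
#'   concentration beyond noise triggers a warning carrying the residual
#'   spread.
#' @examples
#' m <- gelModel()
#' conc <- 200 / 2^(0:7)
#' fitConcentrationCurve(conc, stainResponse(m, conc))
#' @export
fitConcentrationCurve <- function(conc, signal) {
    stopifnot(length(conc) == length(signal))
    if (length(conc) < 3L) stop("need at least 3 calibration points")
    if (any(conc <= 0)) stop("concentrations must be positive")
    if (anyDuplicated(conc)) stop("concentrations must be distinct")
    ord <- order(conc)
    conc <- conc[ord]; signal <- signal[ord]
    if (any(diff(signal) < -2 * stats::sd(signal) / sqrt(length(signal))))
        warning("signal is not monotone in concentration beyond noise; ",
                "residual spread ", signif(stats::sd(diff(signal)), 3))
    fit <- tryCatch(
        minpack.lm::nlsLM(signal ~ smax * conc / (kHalf + conc),
                          start = list(smax = max(signal) * 2,
                                       kHalf = stats::median(conc)),
                          control = minpack.lm::nls.lm.control(
                              maxiter = 200L)),
        error = function(e) NULL)
    if (!is.null(fit)) {
        cf <- stats::coef(fit)
        ## a half-saturation far beyond the calibrated range means the
        ## saturation is unidentifiable: use the linear limit instead
        if (cf[["smax"]] > 0 && cf[["kHalf"]] > 0 &&
            cf[["kHalf"]] < 100 * max(conc))
            return(new("ConcentrationCurve", kind = "hyperbolic",
                       coef = c(smax = cf[["smax"]],
                                kHalf = cf[["kHalf"]]),
                       residuals = unname(stats::residuals(fit)),
                       concRange = range(conc)))
    }
    ## degenerate / linear regime: least squares through the origin
    slope <- sum(conc * signal) / sum(conc^2)
    if (slope <= 0) stop("response is not increasing; cannot calibrate")
    new("ConcentrationCurve", kind = "linear", coef = c(slope = slope),
        residuals = signal - slope * conc, concRange = range(conc))
}

#' Predicted signal under a concentration curve
#' @param curve a [ConcentrationCurve-class].
#' @param conc concentrations, mg/L.
#' @return predicted integrated signals.
#' @export
predictSignal <- function(curve, conc) {
    stopifnot(is(curve, "ConcentrationCurve"), all(conc >= 0))
    if (curve@kind == "hyperbolic")
        curve@coef[["smax"]] * conc / (curve@coef[["kHalf"]] + conc)
    else curve@coef[["slope"]] * conc
}

#' Estimate a protein concentration from band signal
#'
#' Inverts the fitted response. Unless a per-protein curve is supplied,
#' results are albumin-equivalent concentrations: Coomassie staining is
#' not uniform across proteins, so a protein staining half as strongly
#' reads at half its true concentration against the albumin curve.
#'
#' @param curve a [ConcentrationCurve-class].
#' @param signal integrated band signals (non-negative).
#' @param lod limit of detection in mg/L used for the `below_LOD`
#'   qualifier (see [estimateLod()]); `NA` disables that qualifier
#'   except at zero signal.
#' @return data.frame with columns `conc_mg_per_l` and `qualifier`
#'   (`quantified`, `below_LOD`, or `above_range`).
#' @export
estimateConcentration <- function(curve, signal, lod = NA_real_) {
    stopifnot(is(curve, "ConcentrationCurve"))
    if (any(signal < 0)) stop("signal must be non-negative")
    conc <- if (curve@kind == "hyperbolic") {
        smax <- curve@coef[["smax"]]; k <- curve@coef[["kHalf"]]
        ifelse(signal >= smax, Inf, k * signal / (smax - signal))
    } else signal / curve@coef[["slope"]]
    maxSig <- predictSignal(curve, curve@concRange[2])
    qualifier <- rep("quantified", length(signal))
    qualifier[signal > maxSig] <- "above_range"
    lodCut <- if (is.na(lod)) 0 else predictSignal(curve, lod)
    qualifier[signal <= lodCut] <- "below_LOD"
    data.frame(conc_mg_per_l = ifelse(is.finite(conc), conc, NA_real_),
               qualifier = qualifier)
}

#' Estimate the limit of detection
#'
#' The LOD is the smallest concentration whose predicted integrated
#' signal reaches `k` times the noise floor (the conventional
#' 3-sigma detection criterion by default). The noise must be expressed
#' in integrated-signal units; [detectionNoiseArea()] converts the
#' per-sample trace noise of a gel model into that unit. For a linear
#' response with slope m the closed form is `k * noise / m`; for the
#' hyperbolic response the monotone inversion is exact as well.
#'
#' @param curve a [ConcentrationCurve-class].
#' @param noiseSd noise floor in integrated-signal units (> 0).
#' @param k detection multiplier (default 3).
#' @return LOD in mg/L. If the response saturates below the detection
#'   threshold, no concentration is detectable and the function signals
#'   an error of class `urinePAGE_no_lod`.
#' @examples
#' m <- gelModel()
#' conc <- 200 / 2^(0:7)
#' curve <- fitConcentrationCurve(conc, stainResponse(m, conc))
#' estimateLod(curve, detectionNoiseArea(m@noiseSd, m@bandWidth))
#' @export
estimateLod <- function(curve, noiseSd, k = 3) {
    stopifnot(is(curve, "ConcentrationCurve"), k > 0)
    if (noiseSd <= 0) stop("noiseSd must be positive")
    thr <- k * noiseSd
    if (curve@kind == "linear")
        return(thr / curve@coef[["slope"]])
    smax <- curve@coef[["smax"]]; kh <- curve@coef[["kHalf"]]
    if (thr >= smax)
        stop(structure(class = c("urinePAGE_no_lod", "error",
                                 "condition"),
                       list(message = paste0(
                           "response saturates at ", signif(smax, 4),
                           " below the detection threshold ",
                           signif(thr, 4), "; no LOD exists"),
                           call = sys.call())))
    kh * thr / (smax - thr)
}

setMethod("show", "ConcentrationCurve", function(object) {
    cat("ConcentrationCurve (", object@kind, "): ", sep = "")
    if (object@kind == "hyperbolic")
        cat("smax", signif(object@coef[["smax"]], 4), ", half-saturation",
            signif(object@coef[["kHalf"]], 4), "mg/L\n")
    else cat("slope", signif(object@coef[["slope"]], 4),
             "signal per mg/L\n")
    cat("  calibrated over [", object@concRange[1], ", ",
        object@concRange[2], "] mg/L, residual RMS ",
        signif(sqrt(mean(object@residuals^2)), 3), "\n", sep = "")
})
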