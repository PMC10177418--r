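#' Construct a gel forward model
#'
#' Builds a [GelModel-class] describing how a gradient-gel lane of known
#' composition turns into a densitometric trace. The defaults emulate a
#' Coomassie-stained 4-20% gradient gel: a mildly curved, strictly
#' decreasing migration map in log10(MW) covering 10-250 kDa, a saturating
#' hyperbolic stain response with a linear low-concentration limit,
#' Gaussian bands of constant width, a shallow linear background, and
#' additive Gaussian noise calibrated so that an albumin dilution series
#' from 200 mg/L in 2-fold steps loses detectability between 3.12 and
#' 1.56 mg/L.
#'
#' @param migrationCoef polynomial coefficients (intercept first) mapping
#'   log10(MW in kDa) to relative mobility Rf; must be strictly decreasing
#'   in MW over `mwRange`.
#' @param mwRange numeric(2) molecular-weight validity range, kDa.
#' @param smax saturating maximum of the stain response, signal-position
#'   units.
#' @param kHalf half-saturation concentration, mg/L.
#' @param bandWidth Gaussian band standard deviation, profile samples.
#' @param background numeric(2) linear background (intercept, slope over
#'   the profile span), signal units.
#' @param noiseSd additive noise standard deviation, signal units.
#' @param profileLength samples per lane profile.
#' @param responseScale named numeric of per-protein stain-response scale
#'   factors (default: all 1); Coomassie staining is not uniform across
#'   proteins, and this is where that non-uniformity can be injected.
#'
#' @return A validated [GelModel-class] object.
#' @examples
#' m <- gelModel()
#' migrationRf(m, c(69.23, 23))
#' @export
gelModel <- function(migrationCoef = c(1.55, -0.75, 0.05),
                     mwRange = c(10, 250),
                     smax = 1000,
                     kHalf = 100,
                     bandWidth = 3,
                     background = c(5, 3),
                     noiseSd = 0.7,
                     profileLength = 512L,
                     responseScale = numeric()) {
    new("GelModel",
        migrationCoef = as.numeric(migrationCoef),
        mwRange = as.numeric(mwRange),
        smax = as.numeric(smax),
        kHalf = as.numeric(kHalf),
        bandWidth = as.numeric(bandWidth),
        background = as.numeric(background),
        noiseSd = as.numeric(noiseSd),
        profileLength = as.integer(profileLength),
        responseScale = responseScale)
}

#' Relative mobility of a molecular weight under a gel model
#'
#' @param model a [GelModel-class].
#' @param mw molecular weights, kDa; must lie within the model's range.
#' @return Rf values between 0 and 1, strictly decreasing in `mw`.
#' @export
migrationRf <- function(model, mw) {
    stopifnot(is(model, "GelModel"))
    out <- mw < model@mwRange[1] | mw > model@mwRange[2]
    if (any(out))
        stop("molecular weight(s) ", paste(mw[out], collapse = ", "),
             " kDa outside the model range [", model@mwRange[1], ", ",
             model@mwRange[2], "] kDa")
    .polyEval(model@migrationCoef, log10(mw))
}

#' Stain response of a gel model
#'
#' Integrated band signal produced by a protein concentration under the
#' saturating hyperbolic response `smax * c / (kHalf + c)`; zero at zero
#' and strictly increasing.
#'
#' @param model a [GelModel-class].
#' @param conc concentrations, mg/L.
#' @param scale per-protein stain-response scale factor(s), recycled.
#' @return integrated signals, signal-position units.
#' @export
stainResponse <- function(model, conc, scale = 1) {
    stopifnot(is(model, "GelModel"), all(conc >= 0))
    scale * model@smax * conc / (model@kHalf + conc)
}

#' @describeIn gelModel profile length accessor
#' @param model a [GelModel-class].
#' @export
profileLength <- function(model) model@profileLength

#' Noise floor of band detection in integrated-signal units
#'
#' Under matched-filter band detection, a Gaussian band of width
#' `bandWidth` smoothed with a kernel of width `smoothSd` reaches the
#' detection amplitude `k * noiseSd` when its integrated signal equals
#' `k` times this quantity. It converts the per-sample noise standard
#' deviation into the equivalent noise floor on integrated band signal,
#' which is the unit in which concentration-response curves are fitted --
#' the bridge between [detectBands()] and [estimateLod()].
#'
#' @param noiseSd per-sample noise standard deviation, signal units.
#' @param bandWidth Gaussian band standard deviation, samples.
#' @param smoothSd detection smoothing kernel standard deviation, samples
#'   (defaults to `bandWidth`, the matched filter).
#' @return noise floor in signal-position units.
#' @export
detectionNoiseArea <- function(noiseSd, bandWidth, smoothSd = bandWidth) {
    stopifnot(noiseSd >= 0, bandWidth > 0, smoothSd >= 0)
    noiseSd * sqrt(bandWidth^2 + smoothSd^2) * sqrt(2 * pi)
}

setMethod("show", "GelModel", function(object) {
    cat("GelModel:", object@profileLength, "samples/lane, MW range",
        object@mwRange[1], "-", object@mwRange[2], "kDa\n")
    cat("  stain response: smax", object@smax, ", half-saturation",
        object@kHalf, "mg/L\n")
    cat("  band sd", object@bandWidth, "samples; noise sd",
        object@noiseSd, "; background", object@background[1], "+",
        object@background[2], "x\n")
    if (length(object@responseScale))
        cat("  per-protein response scales:",
            paste(names(object@responseScale), signif(object@responseScale, 3),
                  sep = "=", collapse = ", "), "\n")
})
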