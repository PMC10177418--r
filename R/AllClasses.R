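#' @import methods
NULL

#' Forward model of a Coomassie-stained gradient-gel lane
#'
#' A `GelModel` holds everything needed to turn a lane composition into a
#' densitometric trace: the monotone migration map from log10 molecular
#' weight to relative mobility (Rf), the saturating stain-response curve
#' relating protein concentration to integrated band signal, the band
#' shape, the smooth background, and the additive noise level.
#'
#' @slot migrationCoef numeric polynomial coefficients (intercept first) of
#'   Rf as a function of log10(MW in kDa); strictly decreasing in MW over
#'   `mwRange`.
#' @slot mwRange numeric(2), molecular-weight validity range in kDa.
#' @slot smax numeric, saturating maximum of the stain response
#'   (signal-position units).
#' @slot kHalf numeric, concentration (mg/L) at half-saturation; the
#'   low-concentration response slope is `smax / kHalf`.
#' @slot bandWidth numeric, Gaussian band standard deviation in profile
#'   samples.
#' @slot background numeric(2), intercept and slope of the linear
#'   background (signal units over the profile span).
#' @slot noiseSd numeric, standard deviation of additive Gaussian noise.
#' @slot profileLength integer, number of samples per lane profile.
#' @slot responseScale named numeric, optional per-protein stain-response
#'   scale factors (Coomassie staining is not uniform across proteins);
#'   proteins not named have scale 1.
#'
#' @seealso [gelModel()], [simulateLane()]
#' @export
setClass("GelModel",
    representation(
        migrationCoef = "numeric",
        mwRange = "numeric",
        smax = "numeric",
        kHalf = "numeric",
        bandWidth = "numeric",
        background = "numeric",
        noiseSd = "numeric",
        profileLength = "integer",
        responseScale = "numeric"
    )
)

setValidity("GelModel", function(object) {
    msg <- character()
    if (length(object@mwRange) != 2L || object@mwRange[1] <= 0 ||
        diff(object@mwRange) <= 0)
        msg <- c(msg, "mwRange must be increasing and positive")
    if (object@smax <= 0 || object@kHalf <= 0)
        msg <- c(msg, "stain response parameters must be positive")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (object@bandWidth <= 0)
        msg <- c(msg, "bandWidth must be > 0")
    if (object@profileLength < 16L)
        msg <- c(msg, "profileLength must be >= 16")
    if (length(object@background) != 2L)
        msg <- c(msg, "background must be (intercept, slope)")
    ## migration map must be strictly decreasing in MW across the range
    if (length(msg) == 0L) {
        mw <- seq(object@mwRange[1], object@mwRange[2], length.out = 200L)
        rf <- .polyEval(object@migrationCoef, log10(mw))
        if (any(diff(rf) >= 0))
            msg <- c(msg, "migration map must be strictly decreasing in MW")
        if (any(rf < 0) || any(rf > 1))
            msg <- c(msg, "migration map must stay within Rf [0, 1] over mwRange")
    }
    if (length(msg)) msg else TRUE
})

#' A densitometric lane trace
#'
#' One-dimensional intensity profile of a single gel lane, indexed from the
#' top of the gel (wells) towards the dye front. Larger signal means more
#' protein.
#'
#' @slot signal numeric vector of intensities.
#' @slot laneId character scalar identifier.
#' @slot backgroundSubtracted logical, whether a baseline has been removed
#'   (the signal is then clipped at zero).
#' @slot noiseSd numeric, robust per-sample noise estimate made on the
#'   unclipped baseline residual at subtraction time (`NA` before
#'   subtraction). Kept here because the zero clip halves any noise
#'   estimate made afterwards.
#'
#' @seealso [gelLane()], [subtractBackground()], [detectBands()]
#' @export
setClass("GelLane",
    representation(
        signal = "numeric",
        laneId = "character",
        backgroundSubtracted = "logical",
        noiseSd = "numeric"
    )
)

setValidity("GelLane", function(object) {
    msg <- character()
    if (length(object@signal) < 2L)
        msg <- c(msg, "signal must have length >= 2")
    if (any(!is.finite(object@signal)))
        msg <- c(msg, "signal must be finite")
    if (isTRUE(object@backgroundSubtracted) && any(object@signal < 0))
        msg <- c(msg, "background-subtracted signal must be non-negative")
    if (length(object@noiseSd) != 1L ||
        (!is.na(object@noiseSd) && object@noiseSd < 0))
        msg <- c(msg, "noiseSd must be a single non-negative value or NA")
    if (length(msg)) msg else TRUE
})

#' A grayscale gel scan
#'
#' Pixel intensities oriented so that larger values mean more protein
#' (scans of Coomassie gels are inverted on load). Rows run from the top of
#' the gel to the dye front, columns across lanes.
#'
#' @slot pixels numeric matrix of signal-oriented intensities.
#' @slot laneBoundaries list of integer(2) column ranges, one per lane
#'   (may be empty, in which case lanes are auto-detected).
#' @slot source character, originating file path ("" if in-memory).
#'
#' @seealso [readGelImage()], [extractLaneProfiles()]
#' @export
setClass("GelImage",
    representation(
        pixels = "matrix",
        laneBoundaries = "list",
        source = "character"
    )
)

setValidity("GelImage", function(object) {
    msg <- character()
    if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
        msg <- c(msg, "pixels must be a finite numeric matrix")
    for (b in object@laneBoundaries)
        if (length(b) != 2L || b[1] < 1L || b[2] > ncol(object@pixels) ||
            b[1] > b[2])
            msg <- c(msg, "invalid lane boundary")
    if (length(msg)) msg else TRUE
})

#' Molecular-weight calibration curve
#'
#' A polynomial fit of log10(MW) against relative mobility, strictly
#' decreasing in Rf over its valid range.
#'
#' @slot degree integer polynomial degree actually used (may be lower than
#'   requested if a higher degree was non-monotone).
#' @slot coef numeric coefficients of log10(MW) as a polynomial in Rf,
#'   intercept first.
#' @slot residuals numeric fit residuals in log10(MW).
#' @slot rfRange numeric(2), Rf range covered by the calibration points.
#' @slot mwRange numeric(2), corresponding MW range in kDa.
#' @slot anchored logical, whether an internal-standard correction has been
#'   applied.
#'
#' @seealso [fitMwCurve()], [estimateMw()], [calibrateInternal()]
#' @export
setClass("MwCalibration",
    representation(
        degree = "integer",
        coef = "numeric",
        residuals = "numeric",
        rfRange = "numeric",
        mwRange = "numeric",
        anchored = "logical"
    )
)

setValidity("MwCalibration", function(object) {
    msg <- character()
    if (length(object@coef) != object@degree + 1L)
        msg <- c(msg, "coef length must be degree + 1")
    if (length(object@rfRange) != 2L || diff(object@rfRange) <= 0)
        msg <- c(msg, "rfRange must be increasing")
    rf <- seq(object@rfRange[1], object@rfRange[2], length.out = 200L)
    if (any(diff(.polyEval(object@coef, rf)) >= 0))
        msg <- c(msg, "calibration must be strictly decreasing over rfRange")
    if (length(msg)) msg else TRUE
})

#' Concentration-response calibration for semiquantification
#'
#' Saturating (hyperbolic) or linear map from protein concentration (mg/L)
#' to integrated densitometric band signal, strictly increasing over its
#' calibration range.
#'
#' @slot kind character, `"hyperbolic"` (signal = smax c / (kHalf + c)) or
#'   `"linear"` (signal = slope c, the low-concentration limit).
#' @slot coef named numeric: `smax` and `kHalf`, or `slope`.
#' @slot residuals numeric fit residuals in signal units.
#' @slot concRange numeric(2), concentration range of the calibration
#'   points in mg/L.
#'
#' @seealso [fitConcentrationCurve()], [estimateConcentration()],
#'   [estimateLod()]
#' @export
setClass("ConcentrationCurve",
    representation(
        kind = "character",
        coef = "numeric",
        residuals = "numeric",
        concRange = "numeric"
    )
)

setValidity("ConcentrationCurve", function(object) {
    msg <- character()
    if (!object@kind %in% c("hyperbolic", "linear"))
        msg <- c(msg, "kind must be 'hyperbolic' or 'linear'")
    if (object@kind == "hyperbolic" &&
        (is.na(object@coef["smax"]) || is.na(object@coef["kHalf"]) ||
         object@coef["smax"] <= 0 || object@coef["kHalf"] <= 0))
        msg <- c(msg, "hyperbolic curve needs positive smax and kHalf")
    if (object@kind == "linear" &&
        (is.na(object@coef["slope"]) || object@coef["slope"] <= 0))
        msg <- c(msg, "linear curve needs a positive slope")
    if (length(object@concRange) != 2L || object@concRange[1] < 0 ||
        diff(object@concRange) <= 0)
        msg <- c(msg, "concRange must be increasing and non-negative")
    if (length(msg)) msg else TRUE
})

#' Tunable thresholds of the proteinuria pattern classifier
#'
#' @slot albuminWindow numeric(2), kDa window in which a band is taken to
#'   be albumin (the 69 kDa reference); bands below the window are the
#'   low-molecular-weight (LMW) evidence, bands above it the glomerular
#'   high-MW evidence.
#' @slot transferrinWindow numeric(2), kDa window for transferrin
#'   (77 kDa); bands above it count as "higher molecular mass" for
#'   glomerular grade 3.
#' @slot lmwThreshold numeric, kDa boundary splitting tubular patterns into
#'   "upper" (all LMW bands at or above it) and "lower" (any LMW band
#'   below it); 20 kDa.
#' @slot traceFraction numeric, a band is above trace when its integrated
#'   signal exceeds this fraction of the lane total.
#' @slot intenseFraction numeric, a band is intense (or dominant, for
#'   overload signatures) at or above this fraction of the lane total.
#' @slot minLaneSignal numeric, lanes with total integrated signal below
#'   this are treated as carrying only trace bands (a lone faint albumin
#'   band then reads as a normal pattern).
#' @slot overloadRelTol numeric, relative MW tolerance when matching
#'   overload signatures (free light chains, hemoglobin, myoglobin,
#'   lysozyme, ovalbumin).
#'
#' @seealso [classifierConfig()], [classifyLane()]
#' @export
setClass("ClassifierConfig",
    representation(
        albuminWindow = "numeric",
        transferrinWindow = "numeric",
        lmwThreshold = "numeric",
        traceFraction = "numeric",
        intenseFraction = "numeric",
        minLaneSignal = "numeric",
        overloadRelTol = "numeric"
    )
)

setValidity("ClassifierConfig", function(object) {
    msg <- character()
    if (!(object@traceFraction > 0 &&
          object@traceFraction < object@intenseFraction &&
          object@intenseFraction < 1))
        msg <- c(msg, "need 0 < traceFraction < intenseFraction < 1")
    if (object@lmwThreshold <= 0)
        msg <- c(msg, "lmwThreshold must be > 0")
    if (length(object@albuminWindow) != 2L ||
        diff(object@albuminWindow) <= 0)
        msg <- c(msg, "albuminWindow must be increasing")
    if (length(object@transferrinWindow) != 2L ||
        diff(object@transferrinWindow) <= 0 ||
        object@transferrinWindow[1] < object@albuminWindow[2])
        msg <- c(msg, "transferrinWindow must be increasing and above albuminWindow")
    if (object@overloadRelTol <= 0 || object@overloadRelTol > 0.5)
        msg <- c(msg, "overloadRelTol must be in (0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' A classified proteinuria pattern
#'
#' @slot primary character, one of `"normal"`, `"glomerular"`,
#'   `"tubular_upper"`, `"tubular_lower"`,
#'   `"mixed_glomerular_tubular"`.
#' @slot grade integer glomerular grade: 0 when no glomerular component,
#'   otherwise 1 (intense albumin, trace transferrin), 2 (intense albumin
#'   and transferrin) or 3 (grade 2 plus higher-MW bands).
#' @slot sublabel character tubular sublabel: `"upper"`, `"lower"`, or
#'   `"none"` when no tubular component.
#' @slot overload character vector of overload signature flags, a subset of
#'   flc, hemoglobin, myoglobin, lysozyme, ovalbumin.
#' @slot evidence data.frame of the bands supporting the call (MW,
#'   integrated signal, intensity class, role).
#' @slot notes character vector of warnings (zero evidence, co-migrating
#'   overload signatures, ...).
#'
#' @seealso [classifyLane()]
#' @export
setClass("PatternCall",
    representation(
        primary = "character",
        grade = "integer",
        sublabel = "character",
        overload = "character",
        evidence = "data.frame",
        notes = "character"
    )
)

.patternLevels <- c("normal", "glomerular", "tubular_upper",
    "tubular_lower", "mixed_glomerular_tubular")
.overloadLevels <- c("flc", "hemoglobin", "myoglobin", "lysozyme",
    "ovalbumin")

setValidity("PatternCall", function(object) {
    msg <- character()
    if (length(object@primary) != 1L ||
        !object@primary %in% .patternLevels)
        msg <- c(msg, "primary must be exactly one known pattern label")
    glom <- object@primary %in% c("glomerular", "mixed_glomerular_tubular")
    if (glom != (object@grade > 0L))
        msg <- c(msg, "grade must be positive iff a glomerular component is present")
    tub <- object@primary %in%
        c("tubular_upper", "tubular_lower", "mixed_glomerular_tubular")
    if (tub != (object@sublabel %in% c("upper", "lower")))
        msg <- c(msg, "sublabel must be upper/lower iff a tubular component is present")
    if (!all(object@overload %in% .overloadLevels))
        msg <- c(msg, "unknown overload flag")
    if (length(msg)) msg else TRUE
})

#' Result of a 2x2 contingency-table test
#'
#' Records the observed counts, the routing decision between the Pearson
#' chi-square test and the Fisher exact test (used when any expected count
#' is below 5), the statistic and the p-value.
#'
#' @slot counts 2x2 integer matrix.
#' @slot test character, `"pearson_chi2"` or `"fisher_exact"`.
#' @slot statistic numeric chi-square statistic (`NA` for Fisher).
#' @slot p numeric p-value.
#' @slot minExpected numeric, smallest expected count under independence.
#'
#' @seealso [contingencyTest()]
#' @export
setClass("ContingencyResult",
    representation(
        counts = "matrix",
        test = "character",
        statistic = "numeric",
        p = "numeric",
        minExpected = "numeric"
    )
)

setValidity("ContingencyResult", function(object) {
    msg <- character()
    if (!identical(dim(object@counts), c(2L, 2L)) ||
        any(object@counts < 0) ||
        any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be a 2x2 non-negative integer matrix")
    if (!object@test %in% c("pearson_chi2", "fisher_exact"))
        msg <- c(msg, "unknown test")
    if (is.na(object@p) || object@p < 0 || object@p > 1)
        msg <- c(msg, "p must be in [0, 1]")
    if ((object@test == "fisher_exact") != (object@minExpected < 5))
        msg <- c(msg, "fisher_exact must be used iff min expected count < 5")
    if (length(msg)) msg else TRUE
})
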