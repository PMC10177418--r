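#' Fit a molecular-weight calibration curve
#'
#' Least-squares polynomial fit of log10(MW) on relative mobility from a
#' ladder of markers of known molecular weight. Gradient gels are
#' nonlinear in log-MW, so the default degree is 3; if the fitted
#' polynomial is not strictly decreasing over the calibration range
#' (checked on a dense grid), the degree is lowered until it is, with a
#' warning.
#'
#' @param mw marker molecular weights, kDa.
#' @param rf matching relative mobilities between 0 and 1; MW and Rf must be
#'   strictly anti-monotone (heavier proteins migrate less).
#' @param degree requested polynomial degree (needs at least degree + 1
#'   markers).
#' @return a [MwCalibration-class].
#' @examples
#' ladder <- c(250, 130, 70, 35, 15)
#' rf <- migrationRf(gelModel(), ladder)
#' fitMwCurve(ladder, rf)
#' @export
fitMwCurve <- function(mw, rf, degree = 3L) {
    stopifnot(length(mw) == length(rf), all(mw > 0),
              all(rf >= 0), all(rf <= 1))
    if (length(mw) < 2L) stop("need at least 2 (MW, Rf) pairs")
    ord <- order(rf)
    mw <- mw[ord]; rf <- rf[ord]
    bad <- which(diff(mw) >= 0)
    if (length(bad))
        stop("input pairs are not monotone: MW ", mw[bad[1]],
             " kDa at Rf ", signif(rf[bad[1]], 4), " is followed by MW ",
             mw[bad[1] + 1], " kDa at Rf ", signif(rf[bad[1] + 1], 4))
    degree <- min(as.integer(degree), length(mw) - 1L)
    if (degree < 1L) stop("need at least degree + 1 pairs")
    y <- log10(mw)
    grid <- seq(min(rf), max(rf), length.out = 256L)
    for (d in seq(degree, 1L)) {
        fit <- stats::lm(y ~ stats::poly(rf, d, raw = TRUE))
        coef <- unname(stats::coef(fit))
        if (all(.polyEval(.polyDeriv(coef), grid) < 0)) {
            if (d < degree)
                warning("degree ", degree, " fit was not monotone; ",
                        "refitted at degree ", d)
            return(new("MwCalibration", degree = d, coef = coef,
                       residuals = unname(stats::residuals(fit)),
                       rfRange = range(rf), mwRange = range(mw),
                       anchored = FALSE))
        }
    }
    stop("no monotone polynomial fit found (degenerate input?)")
}

#' Estimate molecular weight from relative mobility
#'
#' Evaluates `10^P(rf)` under a fitted calibration; monotone decreasing in
#' Rf. Mobilities outside the calibrated range are extrapolated with a
#' warning, never silently.
#'
#' @param curve a [MwCalibration-class].
#' @param rf relative mobilities between 0 and 1.
#' @return molecular weights, kDa.
#' @export
estimateMw <- function(curve, rf) {
    stopifnot(is(curve, "MwCalibration"))
    if (any(rf < 0 | rf > 1)) stop("Rf must lie in [0, 1]")
    outside <- rf < curve@rfRange[1] - 1e-9 | rf > curve@rfRange[2] + 1e-9
    if (any(outside))
        warning(sum(outside), " mobilit",
                if (sum(outside) == 1) "y" else "ies",
                " outside the calibrated Rf range [",
                signif(curve@rfRange[1], 3), ", ",
                signif(curve@rfRange[2], 3), "]; extrapolating")
    10^.polyEval(curve@coef, rf)
}

#' Residual RMS of a calibration fit
#' @param curve a [MwCalibration-class].
#' @return root-mean-square residual in log10(MW).
#' @export
calibrationRms <- function(curve) {
    stopifnot(is(curve, "MwCalibration"))
    sqrt(mean(curve@residuals^2))
}

## Invert the calibration on a dense grid: Rf at which the curve predicts
## the given MW (NA outside the calibrated MW range).
.rfOfMw <- function(curve, mw) {
    grid <- seq(curve@rfRange[1], curve@rfRange[2], length.out = 2048L)
    pred <- .polyEval(curve@coef, grid)  # log10 MW, decreasing
    stats::approx(pred, grid, xout = log10(mw), rule = 1)$y
}

#' Correct a calibration curve with internal standards
#'
#' Commercial prestained ladders and urinary proteins do not migrate
#' identically, which biases MW estimates (albumin in particular reads
#' low against a commercial curve). Proteins of known identity within the
#' sample -- albumin, the immunoglobulin free-light-chain dimer and
#' monomer -- serve as internal anchors: each anchor is matched to the
#' nearest detected band (in Rf, within `rfTol`), and the curve is
#' corrected affinely in log10(MW) so the anchors fit (one anchor: offset
#' only; two or more: offset and scale by least squares, exact for two).
#' The correction never degrades the fit at the anchors.
#'
#' @param curve a [MwCalibration-class].
#' @param bands band table from [detectBands()] (needs an `rf` column).
#' @param anchors data.frame with columns `mw_kda` and `label`.
#' @param rfTol maximum |Rf| distance for an anchor-band match.
#' @return a corrected [MwCalibration-class] (flagged `anchored`); if no
#'   anchor matches any band, the input curve is returned unchanged with
#'   a warning.
#' @export
calibrateInternal <- function(curve, bands, anchors, rfTol = 0.05) {
    stopifnot(is(curve, "MwCalibration"), is.data.frame(anchors),
              all(c("mw_kda") %in% names(anchors)))
    if (!nrow(anchors)) {
        warning("no anchors supplied; curve unchanged")
        return(curve)
    }
    if (!nrow(bands)) {
        warning("no bands to match anchors against; curve unchanged")
        return(curve)
    }
    expRf <- .rfOfMw(curve, anchors$mw_kda)
    matched <- data.frame(y = numeric(), x = numeric())
    for (i in seq_len(nrow(anchors))) {
        if (is.na(expRf[i])) next
        d <- abs(bands$rf - expRf[i])
        j <- which.min(d)
        if (d[j] <= rfTol)
            matched <- rbind(matched, data.frame(
                y = log10(anchors$mw_kda[i]),
                x = .polyEval(curve@coef, bands$rf[j])))
    }
    if (!nrow(matched)) {
        warning("no anchor matched a band within rfTol = ", rfTol,
                "; curve unchanged")
        return(curve)
    }
    if (nrow(matched) == 1L) {
        alpha <- matched$y - matched$x
        beta <- 1
    } else {
        fit <- stats::lm(y ~ x, data = matched)
        alpha <- unname(stats::coef(fit)[1])
        beta <- unname(stats::coef(fit)[2])
        if (!is.finite(beta) || beta <= 0) {
            ## degenerate anchor geometry: fall back to a pure offset
            alpha <- mean(matched$y - matched$x)
            beta <- 1
        }
    }
    coef <- curve@coef * beta
    coef[1] <- coef[1] + alpha
    new("MwCalibration", degree = curve@degree, coef = coef,
        residuals = curve@residuals, rfRange = curve@rfRange,
        mwRange = sort(10^.polyEval(coef, curve@rfRange)),
        anchored = TRUE)
}

#' Read a ladder specification from CSV
#'
#' @param path CSV with a `marker_kda` column (at least two markers,
#'   each in (1, 1000) kDa).
#' @return numeric vector of marker MWs, sorted decreasing.
#' @export
readLadderCsv <- function(path) {
    if (!file.exists(path)) stop("ladder file not found: ", path)
    d <- utils::read.csv(path)
    if (!"marker_kda" %in% names(d))
        stop("ladder CSV needs a 'marker_kda' column: ", path)
    mw <- sort(as.numeric(d$marker_kda), decreasing = TRUE)
    if (length(mw) < 2L) stop("ladder needs at least 2 markers")
    if (any(mw <= 1 | mw >= 1000))
        stop("marker MWs must lie in (1, 1000) kDa")
    if (any(duplicated(mw))) stop("duplicate ladder markers")
    mw
}

#' Serialise a calibration curve to JSON
#'
#' @param curve a [MwCalibration-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeCalibrationJson <- function(curve, path) {
    stopifnot(is(curve, "MwCalibration"))
    jsonlite::write_json(list(
        schema = "urinePAGE-mw-calibration/1",
        degree = curve@degree, coef = curve@coef,
        residuals = curve@residuals, rf_range = curve@rfRange,
        mw_range = curve@mwRange, anchored = curve@anchored),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(path) {
    if (!file.exists(path)) stop("calibration file not found: ", path)
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("MwCalibration", degree = as.integer(d$degree), coef = d$coef,
        residuals = d$residuals, rfRange = d$rf_range,
        mwRange = d$mw_range, anchored = isTRUE(d$anchored))
}

setMethod("show", "MwCalibration", function(object) {
    cat("MwCalibration: degree", object@degree,
        if (object@anchored) "(internally anchored)", "\n")
    cat("  Rf range [", signif(object@rfRange[1], 3), ", ",
        signif(object@rfRange[2], 3), "], MW range [",
        signif(object@mwRange[1], 4), ", ", signif(object@mwRange[2], 4),
        "] kDa\n", sep = "")
    cat("  residual RMS", signif(calibrationRms(object), 3),
        "log10(kDa)\n")
})
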