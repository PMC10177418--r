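test_that("two points fit exactly and bad inputs are rejected", {
    curve <- fitMwCurve(c(100, 20), c(0.2, 0.7), degree = 1)
    expect_equal(estimateMw(curve, c(0.2, 0.7)), c(100, 20),
                 tolerance = 1e-9)
    expect_error(fitMwCurve(100, 0.5), "at least 2")
    ## non-monotone pairs are rejected naming the offenders
    expect_error(fitMwCurve(c(100, 110, 20), c(0.2, 0.3, 0.7)),
                 "not monotone")
    expect_error(estimateMw(curve, 1.4), "0, 1")
})

test_that("a known nonlinear migration law is recovered within 5%", {
    ## derived oracle: pairs generated from a known decreasing cubic
    ## law in log10(MW), plus Rf noise
    law <- function(m) 1.85 - 1.1 * m + 0.25 * m^2 - 0.035 * m^3
    mw <- sort(ladderMarkers, decreasing = TRUE)
    rfTrue <- law(log10(mw))
    for (s in 1:5) {
        rf <- rfTrue + withr::with_seed(s, rnorm(length(mw), 0, 0.005))
        curve <- fitMwCurve(mw, rf, degree = 3)
        est <- estimateMw(curve, rf)
        expect_true(all(abs(est - mw) / mw < 0.05))
    }
})

test_that("round trip holds for noise-free pairs at any degree up to 3", {
    mw <- sort(ladderMarkers, decreasing = TRUE)
    ## pairs generated from laws the fit can represent: log-linear for
    ## degree 1, the curved default model for degrees 2 and 3
    rfLin <- 1.25 - 0.5 * log10(mw)
    curve1 <- fitMwCurve(mw, rfLin, degree = 1)
    expect_true(all(abs(estimateMw(curve1, rfLin) - mw) / mw < 0.05))
    rf <- migrationRf(defaultModel, mw)
    for (d in 2:3) {
        curve <- fitMwCurve(mw, rf, degree = d)
        expect_true(all(abs(estimateMw(curve, rf) - mw) / mw < 0.05))
    }
    ## the synthetic ladder spans the full 10-250 kDa range
    curve <- fitMwCurve(mw, rf)
    expect_equal(curve@mwRange, c(10, 250))
})

test_that("non-monotone high-degree fits fall back to a lower degree", {
    ## four points with a steep middle drop: the exact cubic overshoots
    mw <- c(100, 79, 13, 10)
    rf <- c(0.05, 0.47, 0.53, 0.95)
    expect_warning(curve <- fitMwCurve(mw, rf, degree = 3),
                   "not monotone")
    expect_lt(curve@degree, 3L)
    grid <- seq(0.05, 0.95, length.out = 100)
    expect_true(all(diff(estimateMw(curve, grid)) < 0))
})

test_that("MW estimates decrease strictly down the lane", {
    curve <- makeCalibration()
    ## a 15-fraction-style lane: strictly increasing mobilities
    rf <- seq(0.08, 0.8, length.out = 15)
    est <- estimateMw(curve, rf)
    expect_true(all(diff(est) < 0))
    ## extrapolation is flagged, not silent
    expect_warning(estimateMw(curve, 0.999), "extrapolat")
})

test_that("internal anchors correct an affinely biased curve", {
    curve <- makeCalibration()
    ## inject an affine bias in log10(MW): scale + offset
    biased <- curve
    biased@coef <- curve@coef * 1.06
    biased@coef[1] <- biased@coef[1] - 0.08
    anchors <- data.frame(mw_kda = c(69.23, 46, 23),
                          label = c("albumin", "flc_dimer", "flc_monomer"))
    sim <- simulateLane(laneComposition(
        data.frame(protein = anchors$label, mw_kda = anchors$mw_kda),
        c(300, 120, 120)), defaultModel, seed = 21)
    bands <- detectBands(subtractBackground(sim$lane))
    ## the biased curve misses the anchors; correction restores them
    bandsRf <- bands$rf
    corrected <- calibrateInternal(biased, bands, anchors)
    expect_true(corrected@anchored)
    errBefore <- abs(estimateMw(biased, bandsRf) - anchors$mw_kda) /
        anchors$mw_kda
    errAfter <- abs(estimateMw(corrected, bandsRf) - anchors$mw_kda) /
        anchors$mw_kda
    expect_true(all(errAfter < 0.01))
    ## anchor residuals never degrade
    expect_true(all(errAfter <= errBefore + 1e-12))
})

test_that("a single albumin anchor pins the dominant band exactly", {
    curve <- makeCalibration()
    biased <- curve
    biased@coef[1] <- biased@coef[1] + 0.04   # +10% MW everywhere
    sim <- simulateLane(laneComposition("Albumin", 400), defaultModel,
                        seed = 3)
    bands <- detectBands(subtractBackground(sim$lane))
    corrected <- calibrateInternal(biased, bands,
                                   data.frame(mw_kda = 69.23,
                                              label = "albumin"))
    expect_equal(estimateMw(corrected, bands$rf[1]), 69.23,
                 tolerance = 1e-9)
})

test_that("unmatched anchors leave the curve unchanged with a warning", {
    curve <- makeCalibration()
    bands <- data.frame(rf = 0.35, center = 180, mw_kda = 70)
    expect_warning(
        same <- calibrateInternal(curve, bands,
                                  data.frame(mw_kda = 15, label = "x"),
                                  rfTol = 0.01),
        "curve unchanged")
    expect_identical(same@coef, curve@coef)
    expect_warning(calibrateInternal(curve, bands[0, ],
                                     data.frame(mw_kda = 69.23,
                                                label = "albumin")),
                   "no bands")
})

test_that("calibration serialises to JSON and back", {
    curve <- makeCalibration()
    path <- file.path(withr::local_tempdir(), "curve.json")
    writeCalibrationJson(curve, path)
    back <- readCalibrationJson(path)
    expect_equal(back@coef, curve@coef)
    expect_equal(back@degree, curve@degree)
    expect_equal(estimateMw(back, 0.4), estimateMw(curve, 0.4))
})
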