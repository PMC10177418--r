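test_that("glomerular patterns are graded by albumin/transferrin intensity", {
    ## intense albumin + trace transferrin -> grade 1
    g1 <- classifyLane(bandTable(c(77, 69.2), c(35, 700)))
    expect_equal(patternLabel(g1), "glomerular")
    expect_equal(patternGrade(g1), 1L)
    expect_equal(patternSublabel(g1), "none")
    ## intense albumin + intense transferrin -> grade 2
    g2 <- classifyLane(bandTable(c(77, 69.2), c(600, 700)))
    expect_equal(patternGrade(g2), 2L)
    ## grade 2 plus a ceruloplasmin-range band -> grade 3
    g3 <- classifyLane(bandTable(c(122, 77, 69.2), c(300, 600, 700)))
    expect_equal(patternGrade(g3), 3L)
    ## grading without a glomerular component is an error
    expect_error(gradeGlomerular(bandTable(c(38.97, 22.99), c(100, 100))),
                 "no glomerular component")
})

test_that("tubular patterns split at 20 kDa into upper and lower", {
    up <- classifyLane(bandTable(c(69.2, 38.97, 22.99), c(30, 300, 250)))
    expect_equal(patternLabel(up), "tubular_upper")
    expect_equal(patternSublabel(up), "upper")
    expect_equal(patternGrade(up), 0L)
    lo <- classifyLane(bandTable(c(69.2, 38.97, 22.99, 13.71),
                                 c(30, 250, 200, 300)))
    expect_equal(patternLabel(lo), "tubular_lower")
    expect_equal(patternSublabel(lo), "lower")
})

test_that("trace albumin alone is a normal pattern", {
    ## total signal below the lane floor: everything reads as trace
    n1 <- classifyLane(bandTable(69.2, 120))
    expect_equal(patternLabel(n1), "normal")
    expect_equal(patternGrade(n1), 0L)
    ## no bands at all: normal with a zero-evidence warning
    expect_warning(n0 <- classifyLane(bandTable(numeric(), numeric())),
                   "zero evidence")
    expect_equal(patternLabel(n0), "normal")
})

test_that("glomerular plus LMW evidence gives a mixed call with sublabel", {
    mx <- classifyLane(bandTable(c(77, 69.2, 38.97, 15.79, 13.71),
                                 c(500, 700, 250, 200, 250)))
    expect_equal(patternLabel(mx), "mixed_glomerular_tubular")
    expect_equal(patternSublabel(mx), "lower")
    expect_gt(patternGrade(mx), 0L)
    mxu <- classifyLane(bandTable(c(77, 69.2, 38.97, 34.24),
                                  c(500, 700, 250, 200)))
    expect_equal(patternSublabel(mxu), "upper")
})

test_that("overload signatures are flagged by their MW fingerprints", {
    ## co-dominant 46 + 23 kDa pair: free light chains
    flc <- detectOverload(bandTable(c(46, 23), c(400, 380)))
    expect_true("flc" %in% flc)
    ## dominant 17.2 kDa band: myoglobin
    myo <- detectOverload(bandTable(c(69.2, 17.2), c(100, 700)))
    expect_equal(as.character(myo), "myoglobin")
    ## hemoglobin/lysozyme/myoglobin co-migrate; all compatible flags
    ## are reported with a note
    hb <- detectOverload(bandTable(c(69.2, 16.4), c(100, 700)))
    expect_true(all(c("hemoglobin", "lysozyme") %in% hb))
    expect_match(attr(hb, "notes"), "co-migrating")
    ## nothing above trace below albumin: no flags
    none <- detectOverload(bandTable(c(69.2, 20), c(700, 20)))
    expect_length(none, 0)
})

test_that("a pure light-chain lane is overload, not tubular", {
    bj <- classifyLane(bandTable(c(69.2, 46, 23), c(90, 500, 450)))
    expect_true("flc" %in% overloadFlags(bj))
    expect_false(patternLabel(bj) %in% c("tubular_upper", "tubular_lower"))
    ## with further LMW proteins present the tubular call stands
    tub <- classifyLane(bandTable(c(46, 23, 15.79, 13.71),
                                  c(400, 380, 200, 220)))
    expect_true("flc" %in% overloadFlags(tub))
    expect_equal(patternLabel(tub), "tubular_lower")
})

test_that("every lane receives exactly one label from the closed set", {
    labels <- c("normal", "glomerular", "tubular_upper", "tubular_lower",
                "mixed_glomerular_tubular")
    for (s in 1:40) {
        k <- withr::with_seed(s, sample(1:6, 1))
        bands <- withr::with_seed(s + 500, bandTable(
            round(exp(runif(k, log(11), log(200))), 2),
            round(runif(k, 10, 800))))
        bands <- bands[!duplicated(round(bands$mw_kda)), , drop = FALSE]
        call <- suppressWarnings(classifyLane(bands))
        expect_length(patternLabel(call), 1)
        expect_true(patternLabel(call) %in% labels)
    }
})

test_that("moving a lone LMW band across 20 kDa flips upper to lower only", {
    for (s in 1:100) {
        ## keep both draws clear of the overload signature windows
        ## (15.3-17.9 kDa and ~44-46 kDa), whose flags are set
        ## independently of the tubular sublabel
        mwHigh <- withr::with_seed(s, runif(1, 20.5, 35))
        mwLow <- withr::with_seed(s + 300, runif(1, 10, 15))
        ctx <- bandTable(c(69.2, 38.97), c(40, 300))
        up <- classifyLane(rbind(ctx, bandTable(mwHigh, 250)))
        lo <- classifyLane(rbind(ctx, bandTable(mwLow, 250)))
        expect_equal(patternLabel(up), "tubular_upper")
        expect_equal(patternLabel(lo), "tubular_lower")
        expect_equal(patternGrade(up), patternGrade(lo))
        expect_identical(overloadFlags(up), overloadFlags(lo))
    }
})

test_that("adding bands above transferrin never lowers the grade", {
    base <- bandTable(c(77, 69.2), c(30, 700))
    for (extraMw in c(95, 122, 150, 180, 240)) {
        g0 <- patternGrade(classifyLane(base))
        g1 <- patternGrade(classifyLane(rbind(base,
            bandTable(extraMw, 150))))
        expect_gte(g1, g0)
        base2 <- bandTable(c(77, 69.2), c(600, 700))
        expect_gte(patternGrade(classifyLane(rbind(base2,
            bandTable(extraMw, 150)))),
            patternGrade(classifyLane(base2)))
    }
})

test_that("classification reports serialise with the intensity definition", {
    call <- classifyLane(bandTable(c(77, 69.2), c(35, 700)))
    path <- file.path(withr::local_tempdir(), "call.json")
    patternReport(call, path, laneId = "L1")
    rep <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(rep$primary, "glomerular")
    expect_match(rep$intensity_definition, "fraction")
})
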