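test_that("background subtraction zeroes flat profiles and is idempotent", {
    flat <- gelLane(rep(7.5, 256))
    out <- subtractBackground(flat)
    expect_true(all(laneSignal(out) == 0))
    ## noisy lane: subtracting twice changes little beyond the noise
    sim <- simulateLane(laneComposition("Albumin", 150), defaultModel,
                        seed = 4)
    once <- subtractBackground(sim$lane)
    twice <- subtractBackground(once)
    expect_lt(mean(abs(laneSignal(twice) - laneSignal(once))), 0.5)
    expect_warning(subtractBackground(flat, window = 9, bandWidth = 3),
                   "band width")
    expect_error(subtractBackground(flat, window = 2), "window")
})

test_that("a band on a ramp background keeps its area within 5%", {
    quiet <- gelModel(noiseSd = 0, background = c(10, 30))
    comp <- laneComposition("Albumin", 120)
    sim <- simulateLane(comp, quiet, seed = 1)
    b <- detectBands(subtractBackground(sim$lane))
    expect_equal(nrow(b), 1L)
    expect_lt(abs(b$integrated_signal - sim$truth$area) / sim$truth$area,
              0.05)
})

test_that("band detection finds well-separated bands and nothing in silence", {
    expect_equal(nrow(detectBands(gelLane(rep(0, 128),
        backgroundSubtracted = TRUE))), 0L)
    comp <- laneComposition(
        c("Ceruloplasmin", "Albumin", "Cystatin C"), c(100, 100, 100))
    sim <- simulateLane(comp, defaultModel, seed = 12)
    b <- detectBands(subtractBackground(sim$lane))
    expect_equal(nrow(b), 3L)
    expect_true(all(abs(b$center - sim$truth$center) <= 1))
    expect_true(all(b$snr >= 3))
    expect_true(all(diff(b$center) > 0))
    expect_true(all(b$rf >= 0 & b$rf <= 1))
})

test_that("detected band count is non-increasing in the prominence gate", {
    sim <- simulateLane(laneComposition(
        c("Albumin", "Serotransferrin", "Protein AMBP", "Cystatin C"),
        c(400, 150, 60, 25)), defaultModel, seed = 8)
    sub <- subtractBackground(sim$lane)
    proms <- c(0, 0.5, 2, 5, 20, 100)
    counts <- vapply(proms, function(p)
        nrow(detectBands(sub, minProminence = p)), integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("band integration matches the analytic Gaussian area", {
    ## unit-area Gaussian, no noise, no background
    x <- seq_len(256)
    g <- dnorm(x, 128, 3)
    lane <- gelLane(g, backgroundSubtracted = TRUE, noiseSd = 0)
    expect_lt(abs(integrateBand(lane, 110, 146) - 1), 0.02)
    ## linearity: doubling the amplitude doubles the area
    lane2 <- gelLane(2 * g, backgroundSubtracted = TRUE, noiseSd = 0)
    expect_equal(integrateBand(lane2, 110, 146),
                 2 * integrateBand(lane, 110, 146))
    ## additivity over adjoining spans
    expect_equal(integrateBand(lane, 110, 128) +
                 integrateBand(lane, 128, 146),
                 integrateBand(lane, 110, 146))
    ## zero-amplitude region integrates to zero
    expect_equal(integrateBand(lane, 1, 50), 0, tolerance = 1e-6)
    expect_error(integrateBand(lane, 200, 300), "outside")
})

test_that("detection has high recall and precision at SNR >= 5", {
    nLanes <- 120
    tp <- fp <- fn <- 0
    for (s in seq_len(nLanes)) {
        mw <- withr::with_seed(1000 + s, {
            ## well-separated random band positions, ample signal
            m <- sort(exp(runif(4, log(12), log(230))), decreasing = TRUE)
            while (any(-diff(log10(m)) < 0.09))
                m <- sort(exp(runif(4, log(12), log(230))),
                          decreasing = TRUE)
            m
        })
        conc <- withr::with_seed(2000 + s, runif(4, 15, 300))
        comp <- laneComposition(
            data.frame(protein = sprintf("p%d", 1:4), mw_kda = mw), conc)
        sim <- simulateLane(comp, defaultModel, seed = 3000 + s)
        b <- detectBands(subtractBackground(sim$lane))
        hit <- vapply(sim$truth$center, function(ct)
            any(abs(b$center - ct) <= 3), logical(1))
        tp <- tp + sum(hit)
        fn <- fn + sum(!hit)
        fp <- fp + sum(vapply(b$center, function(ct)
            all(abs(sim$truth$center - ct) > 3), logical(1)))
    }
    recall <- tp / (tp + fn)
    precision <- tp / (tp + fp)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
})

test_that("lane extraction from a synthetic image matches the profiles", {
    sims <- lapply(1:3, function(s) simulateLane(
        laneComposition(c("Albumin", "Cystatin C"), c(150, 80),
                        sampleId = paste0("s", s)),
        defaultModel, seed = s))
    img <- gelImage(lapply(sims, `[[`, "lane"))
    lanes <- extractLaneProfiles(img, nLanes = 3)
    expect_length(lanes, 3)
    for (i in 1:3) {
        b <- detectBands(subtractBackground(lanes[[i]]))
        expect_true(all(abs(b$center - sims[[i]]$truth$center) <= 1))
    }
    ## lane averaging over replicated columns is the identity
    one <- gelImage(list(sims[[1]]$lane))
    lane1 <- extractLaneProfiles(one)[[1]]
    expect_equal(laneSignal(lane1), laneSignal(sims[[1]]$lane))
    ## a featureless image carries no bands
    blank <- gelImage(matrix(0.5, 64, 40))
    lanesB <- extractLaneProfiles(blank)
    expect_equal(nrow(detectBands(subtractBackground(lanesB[[1]]))), 0L)
    expect_error(extractLaneProfiles(img, nLanes = 5), "3 detectable")
})

test_that("image files round-trip through 16-bit TIFF with the sidecar scale", {
    sim <- simulateLane(laneComposition("Albumin", 150), defaultModel,
                        seed = 2)
    img <- gelImage(list(sim$lane))
    path <- file.path(withr::local_tempdir(), "gel.tiff")
    writeGelImage(img, path)
    back <- readGelImage(path)
    expect_equal(dim(back@pixels), dim(img@pixels))
    lane <- extractLaneProfiles(back)[[1]]
    ## 16-bit quantisation keeps the trace faithful
    expect_lt(max(abs(laneSignal(lane) - laneSignal(sim$lane))),
              max(laneSignal(sim$lane)) / 2^12)
})

test_that("replicate lanes of one sample give the same pattern call", {
    curve <- makeCalibration()
    agree <- 0
    nTrials <- 100
    for (s in seq_len(nTrials)) {
        comp <- laneComposition(
            c("Albumin", "Protein AMBP", "Retinol-binding protein 4",
              "Cystatin C", "Beta-2-microglobulin"),
            c(8, 60, 40, 80, 100))
        calls <- vapply(c(s, s + 50000L), function(sd) {
            b <- analyzeLane(simulateLane(comp, defaultModel,
                                          seed = sd)$lane, curve)
            patternLabel(classifyLane(b))
        }, character(1))
        agree <- agree + (calls[1] == calls[2])
    }
    expect_gte(agree / nTrials, 0.95)
})
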