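#' Assemble a pipeline configuration
#'
#' Validated bag of parameters tying the stages together; every module
#' precondition is checked at build time, and the configuration
#' round-trips through JSON unchanged.
#'
#' @param minSnr band-detection signal-to-noise gate.
#' @param minProminence band-detection prominence gate, signal units.
#' @param bandWidth expected band standard deviation, samples.
#' @param backgroundWindow baseline opening window, samples.
#' @param calibrationDegree polynomial degree of the MW fit.
#' @param ladderLane index of the lane carrying the MW ladder.
#' @param anchors data.frame (`mw_kda`, `label`) of internal standards
#'   applied after the ladder fit; NULL for none.
#' @param anchorRfTol maximum |Rf| distance for an anchor to claim a
#'   band; kept tight so anchors never latch onto neighbouring
#'   proteins.
#' @param classifier a [ClassifierConfig-class].
#' @param seed master seed for any stochastic stage.
#' @return a list of class `urinePAGE_config`.
#' @export
pipelineConfig <- function(minSnr = 3, minProminence = 0.5,
                           bandWidth = 3, backgroundWindow = 51L,
                           calibrationDegree = 3L, ladderLane = 1L,
                           anchors = data.frame(
                               mw_kda = c(69.23, 46, 23),
                               label = c("albumin", "flc_dimer",
                                         "flc_monomer")),
                           anchorRfTol = 0.02,
                           classifier = classifierConfig(),
                           seed = 1L) {
    stopifnot(minSnr > 0, minProminence >= 0, bandWidth > 0,
              backgroundWindow >= 3, calibrationDegree >= 1,
              ladderLane >= 1, is(classifier, "ClassifierConfig"))
    validObject(classifier)
    if (!is.null(anchors))
        stopifnot(is.data.frame(anchors), "mw_kda" %in% names(anchors),
                  all(anchors$mw_kda > 0))
    structure(list(minSnr = minSnr, minProminence = minProminence,
                   bandWidth = bandWidth,
                   backgroundWindow = as.integer(backgroundWindow),
                   calibrationDegree = as.integer(calibrationDegree),
                   ladderLane = as.integer(ladderLane),
                   anchors = anchors, anchorRfTol = anchorRfTol,
                   classifier = classifier,
                   seed = as.integer(seed)),
              class = "urinePAGE_config")
}

#' Run the full lane-to-report workflow
#'
#' Reads (or accepts) a gel image or a set of lane profiles, extracts
#' and background-subtracts each lane, detects bands, fits the MW
#' calibration on the ladder lane, optionally corrects it with internal
#' anchors per sample lane, annotates bands against the reference
#' table, classifies every sample lane's proteinuria pattern, and
#' writes each stage's artifact (profile CSVs, band table CSV,
#' calibration JSON, per-lane classification JSONs, cohort CSV) under
#' `outDir`. Deterministic given identical inputs and configuration;
#' failures in one lane are isolated, reported, and do not abort the
#' others.
#'
#' @param input a [GelImage-class], an image file path, or a list of
#'   [GelLane-class] profiles.
#' @param ladder numeric marker MWs (kDa) or a ladder CSV path.
#' @param reference reference protein table or CSV path.
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created); NULL to skip writing.
#' @return list with `bands` (all-lane band table), `calibration`
#'   (the [MwCalibration-class]), `calls` (data.frame: lane_id,
#'   pattern, grade, sublabel, overload), `failures` (named character
#'   of per-lane errors), and `files` (paths written).
#' @export
runPipeline <- function(input, ladder, reference = referenceProteins(),
                        config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "urinePAGE_config"))
    if (is.character(ladder)) ladder <- readLadderCsv(ladder)
    if (is.character(reference)) reference <- referenceProteins(reference)
    lanes <- if (is.character(input)) {
        extractLaneProfiles(readGelImage(input))
    } else if (is(input, "GelImage")) {
        extractLaneProfiles(input)
    } else if (is.list(input) &&
               all(vapply(input, is, logical(1), "GelLane"))) {
        input
    } else stop("input must be a GelImage, an image path, or a list of GelLane")
    if (config$ladderLane > length(lanes))
        stop("ladder lane ", config$ladderLane, " but only ",
             length(lanes), " lane(s) present")
    files <- character()
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (l in lanes) {
            p <- file.path(outDir, paste0("profile_", laneId(l), ".csv"))
            writeProfileCsv(l, p)
            files <- c(files, p)
        }
    }
    sub <- lapply(lanes, subtractBackground,
                  window = config$backgroundWindow,
                  bandWidth = config$bandWidth)
    bandTables <- lapply(sub, detectBands, minSnr = config$minSnr,
                         minProminence = config$minProminence,
                         bandWidth = config$bandWidth)
    ## MW calibration from the ladder lane
    lb <- bandTables[[config$ladderLane]]
    ladder <- sort(ladder, decreasing = TRUE)
    if (nrow(lb) != length(ladder))
        stop("ladder lane shows ", nrow(lb), " band(s) but the ladder ",
             "specifies ", length(ladder), " marker(s)")
    curve <- fitMwCurve(ladder, lb$rf, degree = config$calibrationDegree)
    sampleIdx <- setdiff(seq_along(lanes), config$ladderLane)
    failures <- character()
    callRows <- list()
    allBands <- list()
    for (i in sampleIdx) {
        id <- laneId(lanes[[i]])
        res <- tryCatch({
            b <- bandTables[[i]]
            laneCurve <- curve
            if (!is.null(config$anchors) && nrow(b)) {
                laneCurve <- suppressWarnings(
                    calibrateInternal(curve, b, config$anchors,
                                      rfTol = config$anchorRfTol))
            }
            if (nrow(b)) b$mw_kda <- estimateMw(laneCurve, b$rf)
            else b$mw_kda <- numeric()
            call <- suppressWarnings(
                classifyLane(b, config$classifier))
            list(bands = b, call = call)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            failures[id] <- conditionMessage(res)
            next
        }
        allBands[[id]] <- res$bands
        callRows[[id]] <- data.frame(
            lane_id = id, pattern = patternLabel(res$call),
            grade = patternGrade(res$call),
            sublabel = patternSublabel(res$call),
            overload = paste(overloadFlags(res$call), collapse = ";"))
        if (!is.null(outDir)) {
            p <- file.path(outDir, paste0("classification_", id, ".json"))
            patternReport(res$call, p, laneId = id)
            files <- c(files, p)
        }
    }
    bands <- do.call(rbind, c(allBands, list(make.row.names = FALSE)))
    calls <- do.call(rbind, c(callRows, list(make.row.names = FALSE)))
    if (!is.null(outDir)) {
        bp <- file.path(outDir, "bands.csv")
        utils::write.csv(bands, bp, row.names = FALSE)
        cp <- file.path(outDir, "calibration.json")
        writeCalibrationJson(curve, cp)
        kp <- file.path(outDir, "calls.csv")
        utils::write.csv(calls, kp, row.names = FALSE)
        files <- c(files, bp, cp, kp)
    }
    if (length(failures))
        warning(length(failures), " lane(s) failed: ",
                paste(names(failures), collapse = ", "))
    list(bands = bands, calibration = curve, calls = calls,
         failures = failures, files = files)
}
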