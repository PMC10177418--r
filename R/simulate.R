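#' Describe the protein composition of one lane
#'
#' A lane composition lists the proteins loaded in a lane together with
#' their concentrations. Proteins can be given by name (resolved against
#' the packaged indicator-protein reference, see [referenceProteins()]) or
#' as explicit (name, MW) pairs.
#'
#' @param proteins character vector of protein names, or a data.frame with
#'   columns `protein` and `mw_kda`.
#' @param conc concentrations in mg/L, one per protein; all positive.
#' @param sampleId sample identifier.
#' @param reference reference table used to resolve names to molecular
#'   weights.
#' @return data.frame with columns `protein`, `mw_kda`, `conc_mg_per_l`
#'   and attribute `sample_id`.
#' @examples
#' laneComposition(c("Albumin", "Beta-2-microglobulin"), c(200, 50))
#' @export
laneComposition <- function(proteins, conc, sampleId = "lane1",
                            reference = referenceProteins()) {
    if (is.data.frame(proteins)) {
        stopifnot(all(c("protein", "mw_kda") %in% names(proteins)))
        out <- data.frame(protein = as.character(proteins$protein),
                          mw_kda = as.numeric(proteins$mw_kda))
    } else {
        idx <- match(proteins, reference$protein)
        if (anyNA(idx))
            stop("unknown protein(s): ",
                 paste(proteins[is.na(idx)], collapse = ", "),
                 "; give explicit (protein, mw_kda) pairs instead")
        out <- data.frame(protein = proteins,
                          mw_kda = reference$mw_kda[idx])
    }
    conc <- as.numeric(conc)
    if (length(conc) != nrow(out))
        stop("need one concentration per protein")
    if (nrow(out) && any(conc <= 0))
        stop("concentrations must be positive")
    if (nrow(out) && any(out$mw_kda <= 0))
        stop("molecular weights must be positive")
    out$conc_mg_per_l <- conc
    attr(out, "sample_id") <- sampleId
    out
}

#' Simulate a densitometric lane trace with known ground truth
#'
#' Forward-simulates one gel lane: each composition entry becomes a
#' Gaussian band centred at the migration position of its molecular
#' weight, with integrated signal given by the saturating stain response
#' at its concentration (times any per-protein response scale); a linear
#' background and additive Gaussian noise complete the trace. The call is
#' deterministic given (composition, model, seed).
#'
#' @param composition a [laneComposition()] data.frame (may have 0 rows).
#' @param model a [GelModel-class].
#' @param seed integer seed controlling the noise draw.
#' @return list with elements `lane` (a [GelLane-class]) and `truth`
#'   (data.frame with one row per band: `protein`, `mw_kda`,
#'   `conc_mg_per_l`, `rf`, `center` in profile samples, `area` in
#'   signal-position units; the generation seed is kept as an attribute).
#' @examples
#' sim <- simulateLane(laneComposition("Albumin", 200), gelModel(), seed = 1)
#' sim$truth
#' @export
simulateLane <- function(composition, model = gelModel(), seed = 1L) {
    stopifnot(is(model, "GelModel"), is.data.frame(composition))
    L <- model@profileLength
    x <- seq_len(L)
    n <- nrow(composition)
    if (n) {
        rf <- migrationRf(model, composition$mw_kda)  # errors if out of range
        center <- rf * (L - 1) + 1
        scale <- rep(1, n)
        if (length(model@responseScale)) {
            hit <- match(composition$protein, names(model@responseScale))
            scale[!is.na(hit)] <- model@responseScale[hit[!is.na(hit)]]
        }
        area <- stainResponse(model, composition$conc_mg_per_l, scale)
    } else {
        rf <- center <- area <- numeric()
    }
    signal <- model@background[1] + model@background[2] * (x - 1) / (L - 1)
    for (i in seq_len(n))
        signal <- signal + area[i] * stats::dnorm(x, center[i],
                                                  model@bandWidth)
    if (model@noiseSd > 0)
        signal <- signal + withr::with_seed(as.integer(seed),
            stats::rnorm(L, 0, model@noiseSd))
    truth <- data.frame(protein = if (n) composition$protein else character(),
                        mw_kda = if (n) composition$mw_kda else numeric(),
                        conc_mg_per_l = if (n) composition$conc_mg_per_l
                                        else numeric(),
                        rf = rf, center = center, area = area)
    truth <- truth[order(truth$center), , drop = FALSE]
    rownames(truth) <- NULL
    attr(truth, "seed") <- as.integer(seed)
    lane <- gelLane(signal, laneId = attr(composition, "sample_id") %||%
                    "lane1")
    list(lane = lane, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a 2-fold (or other) dilution series of a single protein
#'
#' Emulates the limit-of-detection experiment: a urine sample containing a
#' known albumin concentration is serially diluted and each dilution run
#' in its own lane. Concentrations form the geometric series
#' `baseConc / fold^k`, k = 0 .. nSteps-1.
#'
#' @param baseConc starting concentration, mg/L (default 200, the
#'   undiluted sample).
#' @param fold dilution factor per step (> 1).
#' @param nSteps number of lanes.
#' @param model a [GelModel-class].
#' @param seed integer; lane k uses seed + k - 1.
#' @param protein protein name for the truth records.
#' @param mw molecular weight of the diluted protein, kDa.
#' @return list of `nSteps` elements, each a `simulateLane()` result.
#' @examples
#' ser <- simulateDilutionSeries(nSteps = 3, seed = 1)
#' vapply(ser, function(s) s$truth$conc_mg_per_l, numeric(1))
#' @export
simulateDilutionSeries <- function(baseConc = 200, fold = 2, nSteps = 8,
                                   model = gelModel(), seed = 1L,
                                   protein = "Albumin", mw = 69.23) {
    stopifnot(baseConc > 0, fold > 1, nSteps >= 1)
    lapply(seq_len(nSteps), function(k) {
        conc <- baseConc / fold^(k - 1)
        comp <- laneComposition(
            data.frame(protein = protein, mw_kda = mw), conc,
            sampleId = sprintf("dilution_%02d", k))
        simulateLane(comp, model, seed = as.integer(seed) + k - 1L)
    })
}

## Composition templates for the clinically distinguished patterns.
## Concentrations are mg/L; the per-pattern band sets follow the
## molecular-weight rules that define each pattern (glomerular: albumin
## plus higher-MW proteins; "upper" tubular: LMW bands all >= 20 kDa;
## "lower" tubular: LMW bands below 20 kDa present).
.patternTemplate <- function(pattern, grade = 1L, sublabel = "lower") {
    alb <- c("Albumin" = 69.23)
    tf <- c("Serotransferrin" = 77.01)
    cerulo <- c("Ceruloplasmin" = 122.13)
    ambp <- c("Protein AMBP" = 38.97)
    zag <- c("Zinc-alpha-2-glycoprotein" = 34.24)
    rbp <- c("Retinol-binding protein 4" = 22.99)
    cysc <- c("Cystatin C" = 15.79)
    b2m <- c("Beta-2-microglobulin" = 13.71)
    build <- function(mws, conc)
        data.frame(protein = names(mws), mw_kda = unname(mws),
                   conc_mg_per_l = conc)
    switch(pattern,
        normal = build(alb, 15),
        glomerular = switch(grade,
            build(c(alb, tf), c(500, 4)),
            build(c(alb, tf), c(500, 300)),
            build(c(alb, tf, cerulo), c(500, 300, 120))),
        tubular_upper = build(c(alb, ambp, zag, rbp), c(8, 120, 60, 80)),
        tubular_lower = build(c(alb, ambp, rbp, cysc, b2m),
                              c(8, 60, 40, 80, 100)),
        mixed_glomerular_tubular = if (sublabel == "upper")
            build(c(alb, tf, ambp, zag, rbp), c(500, 300, 60, 50, 70))
        else
            build(c(alb, tf, ambp, cysc, b2m), c(500, 300, 60, 70, 80)),
        stop("unknown pattern: ", pattern))
}

.egfrDefaults <- list(
    normal = c(meanlog = log(95), sdlog = 0.25),
    glomerular = c(meanlog = log(66), sdlog = 0.50),
    tubular_upper = c(meanlog = log(71), sdlog = 0.37),
    tubular_lower = c(meanlog = log(31), sdlog = 0.70))

.icdDefaults <- list(
    tubular = c("C90.0" = 0.43, "D47.2" = 0.02, "N18.3" = 0.18,
                "Z94.0" = 0.06, "N03.9" = 0.10, "C34.9" = 0.01,
                "R80.9" = 0.20),
    glomerular = c("C90.0" = 0.26, "D47.2" = 0.01, "N18.3" = 0.23,
                   "Z94.0" = 0.06, "N03.9" = 0.17, "C34.9" = 0.07,
                   "R80.9" = 0.20))

#' Simulate a cohort of lanes with known proteinuria patterns
#'
#' Draws a pattern for each sample from `patternWeights`, builds the
#' pattern's composition template with mild lognormal jitter on the
#' concentrations, simulates the lane, and attaches synthetic metadata
#' (eGFR drawn per pattern, an ICD-10 code, age, sex). Ground-truth
#' pattern labels make the cohort a fixture for classifier-recovery
#' experiments.
#'
#' @param n number of samples (> 0).
#' @param patternWeights named probabilities over the pattern labels
#'   (normal, glomerular, tubular_upper, tubular_lower,
#'   mixed_glomerular_tubular); normalised to 1.
#' @param model a [GelModel-class].
#' @param seed integer master seed; all per-sample draws derive from it.
#' @param concJitterSd standard deviation of the lognormal concentration
#'   jitter applied to template concentrations.
#' @param egfrParams named list of `c(meanlog, sdlog)` per pattern for the
#'   lognormal eGFR draw (mixed patterns use their tubular sublabel's
#'   parameters).
#' @param icdProbs named list with elements `tubular` and `glomerular`,
#'   each a named probability vector over ICD-10 codes.
#' @return list with elements `lanes` (list of [GelLane-class]), `bands`
#'   (list of per-lane truth tables), `truth` (data.frame: `sample_id`,
#'   `pattern`, `grade`, `sublabel`) and `meta` (data.frame: `sample_id`,
#'   `egfr`, `icd10`, `age`, `sex`).
#' @examples
#' coh <- simulateCohort(4, c(glomerular = 1), seed = 1)
#' coh$truth
#' @export
simulateCohort <- function(n,
                           patternWeights = c(normal = 0.1,
                               glomerular = 0.3, tubular_upper = 0.2,
                               tubular_lower = 0.25,
                               mixed_glomerular_tubular = 0.15),
                           model = gelModel(), seed = 1L,
                           concJitterSd = 0.2,
                           egfrParams = .egfrDefaults,
                           icdProbs = .icdDefaults) {
    if (n <= 0) stop("n must be positive")
    if (is.null(names(patternWeights)) ||
        !all(names(patternWeights) %in% .patternLevels))
        stop("patternWeights must be named with known pattern labels")
    w <- patternWeights / sum(patternWeights)
    draws <- withr::with_seed(as.integer(seed), {
        pattern <- sample(names(w), n, replace = TRUE, prob = w)
        grade <- sample(1:3, n, replace = TRUE)
        sub <- sample(c("upper", "lower"), n, replace = TRUE)
        list(pattern = pattern, grade = grade, sub = sub,
             seeds = sample.int(2^30, n))
    })
    lanes <- vector("list", n)
    bands <- vector("list", n)
    truth <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        pattern = draws$pattern,
                        grade = ifelse(draws$pattern %in%
                            c("glomerular", "mixed_glomerular_tubular"),
                            draws$grade, 0L),
                        sublabel = ifelse(draws$pattern ==
                                "mixed_glomerular_tubular", draws$sub,
                            ifelse(draws$pattern == "tubular_upper", "upper",
                            ifelse(draws$pattern == "tubular_lower", "lower",
                                   "none"))))
    ## mixed patterns are graded like glomerular; grade 3 needs its
    ## higher-MW band, which the mixed template does not carry
    truth$grade[truth$pattern == "mixed_glomerular_tubular" &
                truth$grade == 3L] <- 2L
    meta <- data.frame(sample_id = truth$sample_id,
                       egfr = NA_real_, icd10 = NA_character_,
                       age = NA_integer_, sex = NA_character_)
    for (i in seq_len(n)) {
        si <- draws$seeds[i]
        tmpl <- .patternTemplate(truth$pattern[i],
                                 grade = max(truth$grade[i], 1L),
                                 sublabel = if (truth$sublabel[i] == "none")
                                     "lower" else truth$sublabel[i])
        mi <- withr::with_seed(si, {
            conc <- tmpl$conc_mg_per_l *
                exp(stats::rnorm(nrow(tmpl), 0, concJitterSd))
            epat <- switch(truth$pattern[i],
                mixed_glomerular_tubular =
                    paste0("tubular_", truth$sublabel[i]),
                truth$pattern[i])
            ep <- egfrParams[[epat]]
            tubularLike <- truth$pattern[i] %in%
                c("tubular_upper", "tubular_lower",
                  "mixed_glomerular_tubular")
            ip <- if (tubularLike) icdProbs$tubular else icdProbs$glomerular
            list(conc = conc,
                 egfr = round(stats::rlnorm(1, ep["meanlog"], ep["sdlog"]), 1),
                 icd = sample(names(ip), 1, prob = ip),
                 age = sample(18:91, 1),
                 sex = sample(c("F", "M"), 1))
        })
        comp <- laneComposition(tmpl[, c("protein", "mw_kda")], mi$conc,
                                sampleId = truth$sample_id[i])
        sim <- simulateLane(comp, model, seed = si %% 2147483647L)
        lanes[[i]] <- sim$lane
        bands[[i]] <- sim$truth
        meta$egfr[i] <- min(mi$egfr, 130)
        meta$icd10[i] <- mi$icd
        meta$age[i] <- mi$age
        meta$sex[i] <- mi$sex
    }
    list(lanes = lanes, bands = bands, truth = truth, meta = meta)
}
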