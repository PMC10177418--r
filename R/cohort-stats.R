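.check2x2 <- function(table) {
    table <- as.matrix(table)
    if (!identical(dim(table), c(2L, 2L)))
        stop("need a 2x2 table")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    storage.mode(table) <- "integer"
    table
}

#' Pearson chi-square test for a 2x2 table
#'
#' Classic sum of (O - E)^2 / E with 1 degree of freedom, without
#' continuity correction: the printed p-values of clinical contingency
#' tables in this workflow match the uncorrected statistic. Intended for
#' tables whose expected counts are all at least 5; route smaller tables
#' to [fisherExact()] (or use [contingencyTest()], which applies the
#' rule).
#'
#' @param table 2x2 matrix of counts; both margins must be positive.
#' @return list with `statistic` (chi-square) and `p`.
#' @examples
#' pearsonChi2(matrix(c(91, 113, 26, 70), 2, byrow = TRUE))
#' @export
pearsonChi2 <- function(table) {
    table <- .check2x2(table)
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("a zero margin leaves the chi-square test undefined")
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, of tables no more probable than the observed one. Used when
#' any expected count falls below 5.
#'
#' @param table 2x2 matrix of non-negative integer counts with a
#'   positive total.
#' @return the two-sided p-value.
#' @examples
#' fisherExact(matrix(c(2, 202, 7, 89), 2, byrow = TRUE))
#' @export
fisherExact <- function(table) {
    table <- .check2x2(table)
    if (sum(table) == 0) stop("empty table")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(1)  # degenerate margin: only one table is possible
    stats::fisher.test(table)$p.value
}

#' Contingency test with expected-count routing
#'
#' Computes the expected counts under independence and applies the
#' Fisher exact test when the smallest expected count is below 5, the
#' Pearson chi-square test otherwise (a minimum of exactly 5 stays with
#' Pearson).
#'
#' @param table 2x2 matrix of counts.
#' @return a [ContingencyResult-class].
#' @examples
#' contingencyTest(matrix(c(2, 202, 7, 89), 2, byrow = TRUE))
#' @export
contingencyTest <- function(table) {
    table <- .check2x2(table)
    if (sum(table) == 0) stop("empty table")
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    minE <- min(expected)
    if (minE < 5) {
        new("ContingencyResult", counts = table, test = "fisher_exact",
            statistic = NA_real_, p = fisherExact(table),
            minExpected = minE)
    } else {
        r <- pearsonChi2(table)
        new("ContingencyResult", counts = table, test = "pearson_chi2",
            statistic = r$statistic, p = r$p, minExpected = minE)
    }
}

#' @describeIn contingencyTest p-value accessor
#' @param result a [ContingencyResult-class].
#' @export
testPValue <- function(result) result@p

#' @describeIn contingencyTest test-name accessor
#' @export
testUsed <- function(result) result@test

setMethod("show", "ContingencyResult", function(object) {
    cat("ContingencyResult:", object@test, "\n")
    print(object@counts)
    cat("  min expected count", signif(object@minExpected, 4), "\n")
    if (!is.na(object@statistic))
        cat("  chi-square", signif(object@statistic, 4), "\n")
    cat("  p =", formatPValue(object@p), "(", signif(object@p, 4), ")\n")
})

#' Rank tests for group differences in a quantitative variable
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis for three or more,
#' both with the normal / chi-square approximation and tie correction
#' (the Mann-Whitney approximation uses a continuity correction). Used
#' for non-normally distributed quantities such as eGFR.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return the p-value.
#' @examples
#' rankTests(list(rnorm(20), rnorm(20, 1)))
#' @export
rankTests <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (any(!vapply(groups, length, integer(1))))
        stop("every group must be non-empty")
    if (length(groups) == 2L)
        return(suppressWarnings(stats::wilcox.test(
            groups[[1]], groups[[2]], exact = FALSE,
            correct = TRUE)$p.value))
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups),
                    vapply(groups, length, integer(1))))
    stats::kruskal.test(x, g)$p.value
}

#' Summarise a classified cohort against diagnoses and kidney function
#'
#' Produces the two cohort-level reports of the workflow: (1) per
#' diagnosis group, the split of samples between tubular-or-mixed and
#' pure glomerular patterns, with percentages recomputed from the counts
#' and a p-value from [contingencyTest()] of group membership against
#' pattern class; (2) per tubular subtype ("upper" vs "lower", mixed
#' patterns counted by their sublabel), the number of samples, the count
#' and percentage with eGFR below 60 mL/min/1.73 m2, the median (Q1; Q3)
#' eGFR, and the Mann-Whitney p-value comparing the two subtypes.
#'
#' @param calls data.frame with columns `sample_id`, `pattern`,
#'   `sublabel` (e.g. built from [classifyLane()] results).
#' @param meta data.frame with columns `sample_id`, `egfr`, `icd10`.
#' @param codeGroups named list of regular expressions matched against
#'   ICD-10 codes; each defines one diagnosis-group row.
#' @return list with data.frames `diagnoses` (group, counts, percents,
#'   test, p, p_display) and `tubular` (subtype summary incl.
#'   rank-test p), plus `unmatched` (sample ids present on only one
#'   side; reported, never silently dropped).
#' @export
summarizeCohort <- function(calls, meta,
                            codeGroups = list(
                                "Hematologic lymphoid disorders" =
                                    "^(C90\\.0|D47\\.2|C82\\.9)",
                                "Multiple myeloma" = "^C90\\.0",
                                "Renal disorders" = "^(N0[3-6]|N1[7-9]|N18|N28|Z94\\.0|E10\\.2|E11\\.2)",
                                "Chronic kidney disease" = "^N18",
                                "Kidney transplant status" = "^Z94\\.0")) {
    stopifnot(all(c("sample_id", "pattern") %in% names(calls)),
              all(c("sample_id", "egfr", "icd10") %in% names(meta)))
    if (!nrow(calls))
        return(list(diagnoses = data.frame(), tubular = data.frame(),
                    unmatched = character()))
    unmatched <- c(setdiff(calls$sample_id, meta$sample_id),
                   setdiff(meta$sample_id, calls$sample_id))
    if (length(unmatched))
        warning(length(unmatched), " sample id(s) without a metadata/",
                "call counterpart: ",
                paste(utils::head(unmatched, 5), collapse = ", "))
    d <- merge(calls, meta, by = "sample_id")
    tubularClass <- d$pattern %in% c("tubular_upper", "tubular_lower",
                                     "mixed_glomerular_tubular")
    glomClass <- d$pattern == "glomerular"
    dd <- d[tubularClass | glomClass, , drop = FALSE]
    inTub <- dd$pattern != "glomerular"
    diagRows <- lapply(names(codeGroups), function(g) {
        inGroup <- grepl(codeGroups[[g]], dd$icd10)
        tab <- matrix(c(sum(inGroup & inTub), sum(inGroup & !inTub),
                        sum(!inGroup & inTub), sum(!inGroup & !inTub)),
                      2, 2, byrow = TRUE)
        res <- contingencyTest(tab)
        data.frame(group = g,
                   n_all = sum(inGroup),
                   pct_all = 100 * sum(inGroup) / nrow(dd),
                   n_tubular_mixed = sum(inGroup & inTub),
                   pct_tubular_mixed = 100 * sum(inGroup & inTub) /
                       max(sum(inTub), 1),
                   n_pure_glomerular = sum(inGroup & !inTub),
                   pct_pure_glomerular = 100 * sum(inGroup & !inTub) /
                       max(sum(!inTub), 1),
                   test = testUsed(res), p = testPValue(res),
                   p_display = formatPValue(testPValue(res)))
    })
    diagnoses <- do.call(rbind, diagRows)
    ## tubular subtype table (mixed lanes counted by sublabel)
    sub <- if ("sublabel" %in% names(d)) d$sublabel else
        ifelse(d$pattern == "tubular_upper", "upper",
        ifelse(d$pattern == "tubular_lower", "lower", "none"))
    tubRows <- lapply(c("upper", "lower"), function(s) {
        e <- d$egfr[sub == s & !is.na(d$egfr)]
        q <- if (length(e)) stats::quantile(e, c(0.25, 0.5, 0.75),
                                            names = FALSE, type = 2)
             else rep(NA_real_, 3)
        data.frame(subtype = s, n = length(e),
                   n_egfr_lt60 = sum(e < 60),
                   pct_egfr_lt60 = 100 * sum(e < 60) /
                       max(length(e), 1),
                   egfr_q1 = q[1], egfr_median = q[2], egfr_q3 = q[3])
    })
    tubular <- do.call(rbind, tubRows)
    tubular$p_rank <- if (all(tubular$n > 0))
        rankTests(list(d$egfr[sub == "upper" & !is.na(d$egfr)],
                       d$egfr[sub == "lower" & !is.na(d$egfr)]))
    else NA_real_
    list(diagnoses = diagnoses, tubular = tubular, unmatched = unmatched)
}

#' Packaged diagnosis counts of the proteinuria cohort
#'
#' The printed per-diagnosis sample counts of a 300-sample proteinuria
#' cohort split into tubular-or-mixed (204) and pure glomerular (96)
#' patterns, as transcribed into `inst/extdata/cohort_diagnoses.csv`;
#' these counts are the input for reproducing the cohort's contingency
#' statistics.
#'
#' @return data.frame with columns `group`, `icd10`, `n_all`,
#'   `n_tubular_mixed`, `n_pure_glomerular` (first row: the totals).
#' @examples
#' head(cohortDiagnosisCounts())
#' @export
cohortDiagnosisCounts <- function() {
    path <- system.file("extdata", "cohort_diagnoses.csv",
                        package = "urinePAGE", mustWork = TRUE)
    utils::read.csv(path)
}

#' Contingency table of one diagnosis group against pattern class
#'
#' Builds the 2x2 table (rows: in group / not in group; columns:
#' tubular-or-mixed / pure glomerular) from a group's counts and the
#' cohort totals.
#'
#' @param nTubular samples in the group with tubular or mixed pattern.
#' @param nGlomerular samples in the group with pure glomerular pattern.
#' @param totTubular,totGlomerular cohort totals per pattern class.
#' @return 2x2 integer matrix.
#' @examples
#' contingencyTest(diagnosisTable(91, 26))
#' @export
diagnosisTable <- function(nTubular, nGlomerular, totTubular = 204L,
                           totGlomerular = 96L) {
    stopifnot(nTubular <= totTubular, nGlomerular <= totGlomerular)
    matrix(c(nTubular, nGlomerular,
             totTubular - nTubular, totGlomerular - nGlomerular),
           2, 2, byrow = TRUE,
           dimnames = list(c("in_group", "not_in_group"),
                           c("tubular_mixed", "pure_glomerular")))
}
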