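test_that("the chi-square statistic equals the direct formula", {
    for (s in 1:300) {
        tab <- withr::with_seed(s, matrix(sample(1:60, 4, replace = TRUE),
                                          2, 2))
        r <- pearsonChi2(tab)
        e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        expect_equal(r$statistic, sum((tab - e)^2 / e), tolerance = 1e-10)
        expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE),
                     tolerance = 1e-10)
    }
    expect_equal(pearsonChi2(matrix(10, 2, 2))$statistic, 0)
    expect_equal(pearsonChi2(matrix(10, 2, 2))$p, 1)
    expect_error(pearsonChi2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
                 "margin")
})

test_that("the Fisher p matches full hypergeometric enumeration", {
    ## every 2x2 table with total at most 16 (acceptance covers 30)
    for (a in 0:16) for (b in 0:(16 - a))
        for (cc in 0:(16 - a - b)) for (d in 0:(16 - a - b - cc)) {
            if (a + b + cc + d == 0) next
            tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
            expect_equal(fisherExact(tab), fisherEnumOracle(tab),
                         tolerance = 1e-10)
        }
    ## degenerate margins admit a single table
    expect_equal(fisherExact(matrix(c(0, 5, 0, 7), 2, 2, byrow = TRUE)),
                 1)
    expect_error(fisherExact(matrix(0L, 2, 2)), "empty")
})

test_that("routing between tests is a pure function of expected counts", {
    ## a large-margin table: min expected 26*204/300 = 17.68 >= 5
    r1 <- contingencyTest(diagnosisTable(91, 26))
    expect_equal(testUsed(r1), "pearson_chi2")
    expect_equal(r1@minExpected, 96 * 117 / 300, tolerance = 1e-12)
    ## a sparse table routes to Fisher: min expected 9*96/300 = 2.88
    r2 <- contingencyTest(diagnosisTable(2, 7))
    expect_equal(testUsed(r2), "fisher_exact")
    expect_true(is.na(r2@statistic))
    ## the boundary at exactly 5 stays with Pearson
    r3 <- contingencyTest(matrix(5L, 2, 2))
    expect_equal(testUsed(r3), "pearson_chi2")
    expect_equal(testPValue(r3), 1)
})

test_that("rank tests agree with the exact permutation distribution", {
    ## two identical groups cannot differ
    expect_gte(rankTests(list(1:8, 1:8)), 0.99)
    ## n = 6 vs 6 under a shift alternative, against the enumeration
    ## oracle over all 924 group assignments
    x <- withr::with_seed(11, rnorm(6))
    y <- withr::with_seed(12, rnorm(6) + 1.2)
    expect_lt(abs(rankTests(list(x, y)) - mannWhitneyExactOracle(x, y)),
              0.01)
    expect_error(rankTests(list(1:3, numeric())), "non-empty")
    expect_error(rankTests(list(1:3)), "length")
})

test_that("the Kruskal-Wallis route holds its type-I error rate", {
    reps <- 400
    rej <- 0
    for (s in seq_len(reps)) {
        g <- withr::with_seed(7000 + s,
            list(rnorm(8), rnorm(8), rnorm(8)))
        rej <- rej + (rankTests(g) < 0.05)
    }
    rate <- rej / reps
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("cohort summaries recompute everything from the sample data", {
    coh <- simulateCohort(120, c(glomerular = 0.4, tubular_upper = 0.3,
                                 tubular_lower = 0.3), seed = 31)
    calls <- cbind(coh$truth[, c("sample_id", "pattern", "sublabel")])
    rep <- summarizeCohort(calls, coh$meta)
    ## counts match the generated truth exactly
    nTub <- sum(coh$truth$pattern != "glomerular")
    expect_equal(sum(rep$tubular$n), nTub)
    expect_equal(rep$tubular$n[rep$tubular$subtype == "upper"],
                 sum(coh$truth$sublabel == "upper"))
    ## percentages are recomputed from counts, never stored
    expect_equal(rep$tubular$pct_egfr_lt60,
                 100 * rep$tubular$n_egfr_lt60 / rep$tubular$n)
    expect_equal(rep$diagnoses$pct_tubular_mixed,
                 100 * rep$diagnoses$n_tubular_mixed / nTub)
    ## medians come from the raw eGFR values
    upperIds <- coh$truth$sample_id[coh$truth$sublabel == "upper"]
    expect_equal(rep$tubular$egfr_median[rep$tubular$subtype == "upper"],
                 median(coh$meta$egfr[coh$meta$sample_id %in% upperIds]))
    expect_true(all(rep$diagnoses$test %in%
                    c("pearson_chi2", "fisher_exact")))
})

test_that("empty cohorts and unmatched ids are handled explicitly", {
    rep <- summarizeCohort(data.frame(sample_id = character(),
                                      pattern = character(),
                                      sublabel = character()),
                           data.frame(sample_id = character(),
                                      egfr = numeric(),
                                      icd10 = character()))
    expect_equal(nrow(rep$diagnoses), 0L)
    calls <- data.frame(sample_id = c("a", "b"),
                        pattern = c("glomerular", "tubular_lower"),
                        sublabel = c("none", "lower"))
    meta <- data.frame(sample_id = c("a", "zz"), egfr = c(50, 70),
                       icd10 = c("N18.3", "C90.0"))
    expect_warning(rep2 <- summarizeCohort(calls, meta), "counterpart")
    expect_setequal(rep2$unmatched, c("b", "zz"))
})

test_that("p-values print with the mixed display precision", {
    expect_equal(formatPValue(c(0.0037, 0.0641, 0.33129, 0.90046)),
                 c("0.004", "0.064", "0.3", "0.9"))
})
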