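## Shared fixtures: everything is generated in code at test time.

defaultModel <- gelModel()

## The packaged synthetic 11-marker ladder (10-250 kDa).
ladderMarkers <- readLadderCsv(system.file("extdata",
    "ladder_synthetic.csv", package = "urinePAGE"))

## Simulate a ladder lane under a model.
makeLadderLane <- function(model = defaultModel, seed = 5L,
                           conc = 150) {
    comp <- laneComposition(
        data.frame(protein = sprintf("marker_%03d", ladderMarkers),
                   mw_kda = ladderMarkers),
        rep(conc, length(ladderMarkers)), sampleId = "ladder")
    simulateLane(comp, model, seed = seed)
}

## Ladder-based MW calibration reused across classifier tests.
makeCalibration <- function(model = defaultModel, seed = 5L) {
    sim <- makeLadderLane(model, seed)
    b <- detectBands(subtractBackground(sim$lane))
    stopifnot(nrow(b) == length(ladderMarkers))
    fitMwCurve(sort(ladderMarkers, decreasing = TRUE), b$rf)
}

## Detect bands and attach MW estimates in one step.
analyzeLane <- function(lane, curve) {
    b <- detectBands(subtractBackground(lane))
    if (nrow(b)) b$mw_kda <- estimateMw(curve, b$rf)
    else b$mw_kda <- numeric()
    b
}

## A band table straight from (mw, signal) pairs, for classifier rules.
bandTable <- function(mw, signal) {
    data.frame(mw_kda = mw, integrated_signal = signal)
}

## Independent Fisher oracle: full hypergeometric enumeration over all
## tables with the observed margins, probability-mass criterion.
fisherEnumOracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
    k <- max(0, c1 - r2):min(r1, c1)
    pr <- stats::dhyper(k, r1, r2, c1)
    pobs <- stats::dhyper(tab[1, 1], r1, r2, c1)
    sum(pr[pr <= pobs * (1 + 1e-7)])
}

## Independent Mann-Whitney oracle: exact permutation distribution of
## the rank-sum statistic over all group assignments.
mannWhitneyExactOracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    obs <- sum(r[seq_len(nx)])
    combs <- utils::combn(nx + ny, nx)
    stat <- apply(combs, 2, function(idx) sum(r[idx]))
    mu <- nx * (nx + ny + 1) / 2
    mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}
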