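---
title: "Reading proteinuria patterns from SDS-PAGE densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading proteinuria patterns from SDS-PAGE densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.2)
library(urinePAGE)
```

## The assay and its model

SDS-PAGE on a 4–20% gradient gel separates urinary proteins by molecular
weight over the clinically relevant 10–250 kDa span. After Coomassie
staining, a scanned lane is a one-dimensional densitometric trace: band
position encodes MW through a monotone migration law, band intensity
encodes amount through the stain response. Everything this package does —
band calling, calibration, pattern classification, semiquantification —
operates on that trace.

The forward model (`gelModel()`) states the assumptions explicitly:

* **Migration.** Relative mobility is a polynomial in log10(MW),
  strictly decreasing in MW over the valid range (default
  `rf = 1.55 - 0.75 m + 0.05 m^2` with `m = log10(MW/kDa)`, spanning
  Rf 0.04–0.85 over 250–10 kDa). Rf is band centre over dye-front
  position, with index 0 at the wells and the profile end standing in
  for the dye front when none is marked.
* **Stain response.** Integrated band signal is saturating-hyperbolic
  in concentration, `S(c) = smax·c/(kHalf + c)` (defaults smax = 1000
  signal·sample units, kHalf = 100 mg/L), linear at low concentration
  with slope `smax/kHalf` and visibly saturating at high load — the
  shape a dilution series of albumin traces out. The response scale can
  differ per protein (Coomassie staining is not uniform), which is why
  quantities estimated against an albumin curve are reported as
  *albumin-equivalent* concentrations.
* **Band shape.** Gaussian in the migration coordinate with constant
  width per lane (default sd 3 samples of a 512-sample profile).
* **Background and noise.** A shallow linear background plus additive
  Gaussian noise (default sd 0.7 signal units).

The noise default is a calibration, not a free dial: it is set so that a
2-fold albumin dilution series starting at 200 mg/L loses detectability
between 3.12 and 1.56 mg/L under the default detection gates, anchoring
the synthetic regime to the empirical sensitivity of the stained-gel
assay (limit of detection ≈ 2–3 mg/L albumin).

```{r dilution}
model <- gelModel()
ser <- simulateDilutionSeries(baseConc = 200, fold = 2, nSteps = 8,
                              model = model, seed = 1)
sapply(ser, function(s) {
    b <- detectBands(subtractBackground(s$lane))
    c(conc = s$truth$conc_mg_per_l,
      detected = nrow(b) > 0 && any(abs(b$center - s$truth$center) <= 3))
})
```

## Densitometry choices

The band caller is a conventional 1-D peak pipeline, with three numerical
choices that matter:

1. **Baseline.** Morphological opening (rolling minimum then maximum,
   window 51 samples, wider than any band) of a *lightly smoothed* copy
   of the trace. Opening the raw noisy trace tracks the minima of the
   noise and sits ~2 noise-sd too low; smoothing first removes that
   bias. The residual is clipped at zero for integration, but the noise
   estimate — MAD of the first-differenced residual, divided by √2 — is
   taken *before* clipping, because clipping halves it.
2. **Detection.** The residual is smoothed with a Gaussian kernel
   matched to the band width; local maxima are measured against a wide
   running-median floor and kept when amplitude ≥ `minSnr` (default 3,
   the conventional detection-limit criterion) times the per-sample
   noise and prominence ≥ `minProminence` (default 0.5). Overlapping
   bands split at the local minimum between maxima, which keeps the
   detected count monotone in the prominence gate. Centres are refined
   by parabolic interpolation.
3. **Integration.** Trapezoidal area of the clipped residual between
   the flanking minima, but never further than 6 band widths from the
   peak — integrating clipped noise across an otherwise empty lane
   would otherwise inflate an isolated band's area by hundreds of
   signal units.

`detectionNoiseArea()` converts the per-sample noise into the equivalent
noise floor on *integrated* signal
(`noiseSd · sqrt(bandWidth² + smoothSd²) · sqrt(2π)`), which is what the
limit-of-detection machinery compares against: `estimateLod()` returns
the smallest concentration whose predicted signal reaches k (default 3)
times that floor, by exact monotone inversion of the fitted response.

```{r lod}
conc <- 200 / 2^(0:7)
curve <- fitConcentrationCurve(conc, stainResponse(model, conc))
estimateLod(curve, detectionNoiseArea(model@noiseSd, model@bandWidth))
```

## Molecular-weight calibration

`fitMwCurve()` fits log10(MW) on Rf by least squares, degree 3 by
default: gradient gels are distinctly nonlinear in log-MW, and a cubic is
the lowest degree that tracks the curvature of an 11-marker 10–250 kDa
ladder to a fraction of a percent. Monotonicity is verified on a dense
grid; a non-monotone fit falls back one degree at a time with a warning,
so every accepted curve inverts uniquely.

Commercial prestained markers and urinary proteins do not migrate
identically — against a commercial curve the albumin band reads visibly
low. `calibrateInternal()` answers this with proteins of known identity
inside the sample (albumin 69.23 kDa, the immunoglobulin
free-light-chain dimer 46 and monomer 23 kDa): each anchor claims the
nearest detected band within a tight Rf tolerance (0.02 in the pipeline,
deliberately strict so an anchor never latches onto a neighbouring
protein), and the curve is corrected affinely in log10(MW) — offset for
one anchor, offset plus scale for two or more. An affine correction
fixes an affine bias exactly and can never worsen the least-squares fit
at the anchors.

A practical note on tolerances: with Rf noise of sd 0.005 on ladder
points, one marker's MW estimate carries ~2.3% error at one standard
deviation (the curve's slope is ≈ 2.2 log10-kDa per Rf unit), so a 5%
recovery bound is a ~2σ statement per marker — true for the large
majority of markers, not a worst-case guarantee. The test suite checks
it accordingly (batch-wise over seeded ladders), and exactly (< 0.5%)
in the noise-free limit.

## From bands to a pattern call

The classifier (`classifyLane()`) is the rule set a trained eye applies,
made operational:

* a **low-molecular-weight component** is present when any band sits
  below the albumin window (62–74 kDa);
* a **glomerular component** is present when the albumin band is above
  trace *and* at least one band migrates above the albumin window;
* both ⇒ mixed; one ⇒ tubular or glomerular; neither ⇒ normal.
  Tubular calls are sublabelled **lower** when any LMW band falls below
  20 kDa, **upper** otherwise. Glomerular grades: 1 — intense albumin
  with at most trace transferrin; 2 — intense transferrin too; 3 —
  additional bands above transferrin.

"Trace" and "intense" are visual categories in practice; here they are
fractions of the lane's total integrated signal (defaults < 5% and
≥ 20%), the largest interpretive choice in the package and therefore
configurable and recorded in every report. Two edge rules close gaps the
fraction definition leaves open, both declared package decisions:

* a lane whose *total* signal is below `minLaneSignal` (default 200
  signal units, about the response of 25 mg/L albumin — the upper end
  of a normal urine) carries only trace bands, so a lone faint albumin
  band is a normal pattern even though it is 100% of its lane;
* an above-trace albumin band with no other evidence (no higher-MW
  band, no LMW band) is read as isolated albuminuria: glomerular,
  grade 1.

Overload signatures are flagged independently of the primary label:
free light chains as a co-dominant 46 + 23 kDa pair, hemoglobin (15.99),
myoglobin (17.17), lysozyme (16.53) and ovalbumin (≈ 44 kDa) as dominant
single bands, each within a ±4% MW window. Hemoglobin, myoglobin and
lysozyme lie within mutual tolerance; all compatible flags are reported
with a co-migration note, because they are distinguished clinically, not
by mobility. Free-light-chain bands are discounted from the tubular
evidence only when the lane shows the pure dimer+monomer pattern and
nothing else below albumin — observed tubular patterns involve several
LMW proteins, not only light chains. The 20 kDa rule is applied to
post-anchor-correction MW estimates, since the commercial-ladder bias
acts exactly in this range. Where a weak mixed pattern falls is decided
by the same precedence (any LMW band plus any glomerular component ⇒
mixed); the rules are declared, not inferred from data.

```{r classify}
bands <- data.frame(mw_kda = c(77, 69.2, 38.97, 15.79, 13.71),
                    integrated_signal = c(500, 700, 250, 200, 250))
classifyLane(bands)
```

## Cohort statistics

Contingency tables of diagnosis group against pattern class are tested
with the Pearson χ² statistic (no continuity correction — the printed
p-values of the reference cohort match the uncorrected statistic) or the
Fisher exact test whenever any expected count falls below 5, with a
minimum of exactly 5 staying with Pearson. The two-sided Fisher p is the
probability-mass convention: the sum over tables with the observed
margins that are no more probable than the observed one. eGFR
comparisons use Mann–Whitney / Kruskal–Wallis with tie correction. No
multiple-testing correction is applied, matching the reporting
convention of the source tables. Displayed p-values follow the mixed
precision of clinical tables: one decimal at p ≥ 0.2, three decimals
below. One known discrepancy is documented rather than hidden: the
glomerular-diseases row of the packaged diagnosis counts yields an
uncorrected Pearson p of 0.088 where 0.087 was printed, and that row is
excluded from reproduction checks.

```{r table2}
counts <- cohortDiagnosisCounts()
mm <- counts[counts$group == "Multiple myeloma", ]
contingencyTest(diagnosisTable(mm$n_tubular_mixed, mm$n_pure_glomerular))
```

## What the simulations do and do not show

`simulateCohort()` draws pattern labels, builds per-pattern composition
templates (concentrations in the tens to hundreds of mg/L with mild
lognormal jitter, sd 0.2), and attaches synthetic metadata: lognormal
eGFR centred per pattern (medians 95 / 66 / 71 / 31 mL/min/1.73 m² for
normal / glomerular / "upper" / "lower" tubular) and ICD-10 codes drawn
from per-class frequency tables. Problem sizes used by the test suite
and the acceptance script — 500-lane recovery cohorts, 100-replicate
dilution series, 10-ladder calibration batches — are the package's
standard experiment sizes; each runs in seconds.

The generator reproduces what the analysis depends on: monotone
migration, saturating stain response, Gaussian bands, smooth background,
additive noise. It deliberately omits gel artifacts — smiling, streaking,
lane warping, dye-front irregularities, proteolytic degradation smears —
and per-gel migration drift. Passing recovery tests therefore
demonstrates that the *algorithms* are correct under the stated model,
not that the thresholds are transferable to any scanner and staining
protocol without local re-calibration; `classifierConfig()` and
`gelModel()` expose exactly the knobs a laboratory would need to re-fit.

Known limitations, in one place: MW estimates inherit the commercial
ladder's mobility bias unless internal anchors are present; bands closer
than about two band-widths merge and split at the saddle, so co-migrating
proteins are reported as one band with multiple annotations;
concentrations are albumin-equivalent unless a per-protein response
curve is supplied; and the cohort-level clinical associations (eGFR
medians, diagnosis proportions) can only be recomputed from per-sample
data — the package recomputes them from whatever cohort it is given and
never stores them.
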