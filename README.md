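# urinePAGE

Densitometric evaluation of urinary protein SDS-PAGE patterns.

## The problem

Proteinuria — more than ~150 mg of protein excreted in urine per day — is a
cardinal sign of kidney disease, and *which* proteins leak tells you *where*
the damage is. A leaky glomerular filtration barrier passes albumin
(69 kDa) and larger plasma proteins (transferrin, immunoglobulins):
**glomerular** proteinuria. Failed reabsorption in the proximal tubule
spills many proteins smaller than albumin (α1-microglobulin,
retinol-binding protein, cystatin C, β2-microglobulin): **tubular**
proteinuria, which further splits at 20 kDa into an "upper" type (all
low-molecular-weight bands ≥ 20 kDa, kidney function usually preserved) and
a "lower" type (bands below 20 kDa present, usually with reduced eGFR).
Massive overflow of one plasma protein — immunoglobulin free light chains
(a 46 kDa dimer plus 23 kDa monomer, the Bence-Jones pattern), hemoglobin,
myoglobin, lysozyme — marks **overload** proteinuria.

One SDS-PAGE separation of a urine sample on a 4–20% gradient gel displays
all of this at once: each protein becomes a Coomassie-stained band whose
position encodes molecular weight and whose intensity encodes
concentration. `urinePAGE` implements the complete computational side of
that assay for laboratory scientists and method developers:

- **simulation** of gel lanes/images with known ground truth
  (`simulateLane`, `simulateDilutionSeries`, `simulateCohort`);
- **densitometry**: lane extraction, morphological baseline removal,
  matched-filter band detection with prominence and SNR gates
  (`extractLaneProfiles`, `subtractBackground`, `detectBands`);
- **molecular-weight calibration**: monotone polynomial fit of
  log10(MW) vs relative mobility Rf, with internal-standard correction
  for the mobility mismatch between commercial ladders and urinary
  proteins (`fitMwCurve`, `estimateMw`, `calibrateInternal`);
- **annotation** against a packaged indicator-protein reference and the
  LC-MS/MS shortlist rule for gel fractions (`matchBands`,
  `shortlistFractionProteins`);
- **classification** of the proteinuria pattern with glomerular grading
  and overload signatures (`classifyLane`, `gradeGlomerular`,
  `detectOverload`);
- **semiquantification** with a saturating stain-response curve and a
  limit of detection (`fitConcentrationCurve`, `estimateConcentration`,
  `estimateLod`);
- **cohort statistics**: Pearson χ² / Fisher exact with the
  expected-count < 5 routing rule, rank tests, and cohort summary tables
  (`contingencyTest`, `rankTests`, `summarizeCohort`).

## The core rules

With band intensities expressed as fractions of the lane's total
integrated signal (trace < 5%, intense ≥ 20%):

| evidence | call |
|---|---|
| albumin ≤ trace, nothing else | normal |
| albumin above trace + band above albumin MW, no LMW band | glomerular (grade 1: trace transferrin; 2: intense transferrin; 3: + higher-MW bands) |
| LMW bands (below albumin), no glomerular component | tubular — "lower" if any band < 20 kDa, else "upper" |
| both | mixed glomerular–tubular (with sublabel) |

Overload flags (free light chains ≈ 46 + 23 kDa pair, hemoglobin 15.99,
myoglobin 17.17, lysozyme 16.53, ovalbumin ≈ 44 kDa) are set independently
by molecular-weight signature. MW comes from
`log10(MW) = P(Rf)` with `P` a monotone-decreasing polynomial (default
degree 3) fitted to a 10–250 kDa ladder; the detection limit is the
smallest concentration whose predicted band signal reaches 3× the noise
floor.

## Worked example

```r
library(urinePAGE)
model <- gelModel()

# a ladder lane plus one mixed-proteinuria sample
ladder <- readLadderCsv(system.file("extdata", "ladder_synthetic.csv",
                                    package = "urinePAGE"))
lad <- simulateLane(laneComposition(
    data.frame(protein = paste0("M", ladder), mw_kda = ladder),
    rep(150, length(ladder)), sampleId = "ladder"), model, seed = 5)
smp <- simulateLane(laneComposition(
    c("Albumin", "Serotransferrin", "Protein AMBP",
      "Cystatin C", "Beta-2-microglobulin"),
    c(500, 300, 60, 70, 80), sampleId = "patient"), model, seed = 9)

res <- runPipeline(list(lad$lane, smp$lane), ladder = ladder)
res$calls
#>   lane_id                  pattern grade sublabel overload
#> 1 patient mixed_glomerular_tubular     2    lower
```

The sample lane carries intense albumin and transferrin (a grade-2
glomerular component) together with low-molecular-weight bands down to
13.7 kDa (β2-microglobulin), so the call is mixed glomerular–"lower"
tubular. `res$bands` lists each detected band with its Rf, estimated MW,
SNR and integrated signal; `res$calibration` is the fitted MW curve.

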