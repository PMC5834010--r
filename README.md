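# TILDensity

Automated quantification of tumour-infiltrating lymphocyte (TIL) density
in H&E-like slide images, and its association with pathological complete
response (pCR) after neoadjuvant chemotherapy in breast cancer.

Manual TIL scoring on histology slides reproduces poorly between
pathologists. This package implements a computational alternative for
pathologists, biostatisticians and methods researchers: nuclei are
segmented from slide images, classified into cancer / stromal /
lymphocyte with a support-vector machine, and summarized by a spatial
density statistic that then enters the clinical association models.

## The statistic

For every detected lymphocyte in a section, the mean Euclidean distance
*R* to its *N* = 50 nearest lymphocytes is computed with an exact
K-nearest-neighbour search, giving a per-lymphocyte density

&nbsp;&nbsp;&nbsp;&nbsp;ρ̂ = *N* / (π *R*²),

and the **median** of ρ̂ over all lymphocytes is the slide summary
(arbitrary units). Sparse slides truncate *N* to *n* − 1; fewer than 2
lymphocytes give a missing summary. The summary is rigid-motion
invariant, scales as 1/*c*² under coordinate scaling, and is
proportional to the intensity of a homogeneous Poisson pattern — all
verified against independent oracles in the test suite.

Downstream analyses mirror a neoadjuvant-trial secondary analysis:
univariable and multivariable logistic regression of pCR on density
(odds ratios with Wald 95% CIs, complete-case per model), Kruskal–Wallis
tests against categorical covariates, ER-stratified Cox models for
overall and disease-free survival (Efron ties), and cohort-flow
accounting with rounded inclusion/pCR percentages.

Because no public imaging or outcome data accompany the method, the
package ships a first-class synthetic generator: slides as marked point
patterns (Poisson or Thomas-clustered lymphocytes) rendered via
Beer–Lambert stain mixing, and trial cohorts whose pCR follows a
configurable logistic model in density plus clinical covariates.

## Worked example

```r
library(TILDensity)

## a synthetic slide and its density summary
slide <- simulatePointPattern(syntheticConfig(seed = 7))
lymphocyteDensity(asCellMap(slide, "demo"))
#> SlideDensitySummary 'demo': n_lymphocytes = 400, k = 50,
#>   median density = 0.0007756 a.u.

## end-to-end: simulate a 400-patient cohort with one slide per patient
## (plus a post-treatment slide for the matched subset), measure density,
## fit the association models, account the cohort flow
res <- runPipeline(pipelineConfig(n_patients = 400, seed = 1), "til-out")
res$percentages
#>     baseline_pct      matched_pct pcr_baseline_pct  pcr_matched_pct
#>              100               60               25               28

formatFitTable(res$fits$multi_pre)
#>               variable estimate     ci_95        p   n
#>   measured_pre_density     1.43 0.99–2.07    0.058 400
#>                    age     0.97 0.94–0.99    0.016 400
#>                  grade     3.40 2.17–5.34 <0.00001 400
#>      er_statusPositive     0.27 0.16–0.45 <0.00001 400
#>    node_statusPositive     0.56 0.33–0.95    0.031 400
#>  tumour_size_cat>50 mm     0.55 0.25–1.20     0.13 400
#>               armD FEC     0.83 0.50–1.38     0.47 400
```

The density summary (0.00078 cells/µm² here) is proportional to the
simulated lymphocyte intensity of 400/mm². In the model table, each row
is an odds ratio for pCR: measured pre-treatment density trends positive
(1.43 per a.u. at this modest sample size), higher grade strongly favours
pCR, ER-positivity strongly disfavours it — the directions built into the
cohort generator's defaults. `res$flow` holds the stage counts behind the
percentages; every run also writes per-stage CSVs, a log and a JSON
manifest (config echo, seed, checksums) into the output directory.

A command-line wrapper with verbs `run-all`, `simulate`, `segment`,
`classify`, `density` and `accounting` is installed at
`inst/scripts/til-pipeline.R`.

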