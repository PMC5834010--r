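---
title: "Quantifying tumour-infiltrating lymphocyte density and its association with pCR"
author: "TILDensity package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour-infiltrating lymphocyte density and its association with pCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the statistic

Tumour-infiltrating lymphocytes (TILs) predict response to neoadjuvant
chemotherapy in breast cancer, but manual TIL scoring reproduces poorly.
TILDensity implements a fully automated alternative: nuclei are segmented
in H&E-stained slide images, classified into cancer / stromal / lymphocyte,
and summarized by a spatial density statistic. For every detected
lymphocyte the mean Euclidean distance $R$ to its $N = 50$ nearest
lymphocytes is computed and converted into a local density

$$\hat\rho = \frac{N}{\pi R^2},$$

the density of the disc that just contains those $N$ neighbours. The
per-slide summary is the **median** of $\hat\rho$ over all detected
lymphocytes, reported in arbitrary units (a.u.; internally cells/µm²).
The median is robust to the long upper tail produced by tight lymphoid
aggregates. Downstream, the slide summaries enter logistic models for
pathological complete response (pCR), Kruskal–Wallis tests against
categorical covariates, and ER-stratified Cox models for survival.

Properties that the test suite verifies exactly: the statistic is
invariant under rigid motions of the coordinates, covariant under scaling
($x \mapsto cx$ multiplies densities by $1/c^2$), and for a homogeneous
Poisson pattern of intensity $\lambda$ it is proportional to $\lambda$.
The proportionality constant is not 1 — the *mean* of the 50
nearest-neighbour distances enters, not the distance to the 50th — and we
pin it by simulation at $\approx 2.07\,\lambda$ for a 1.5 mm field
(slightly below the unbounded-plane value $\approx 2.21$ because no edge
correction is applied; densities near the field border are biased low).

### Sparse-slide conventions

The neighbour count is truncated to $k = \min(50, n-1)$ so the statistic
stays defined on sparse slides (the truncation is recorded in the
output as `k_used`); with fewer than 2 lymphocytes the summary is
missing. Lymphocytes at exactly duplicated coordinates would give
$R = 0$; their density is set to missing and excluded from the median,
with a warning, rather than emitting infinity. The even-count median is
the mean of the two central order statistics. Both the arithmetic change
`post − pre` and the log-ratio are emitted for paired slides, since the
parameterization of "change in density" is a free choice; the arithmetic
difference is the default.

## The synthetic-data generator

No public imaging or outcome data accompany the method, so the package
ships a generator that is itself first-class, tested code. It emulates
two layers:

**Slides.** Each cell class is a homogeneous Poisson process on the
field (default 1 × 1 mm) with intensities in cells/mm²; lymphocytes can
instead follow a Thomas cluster process (Poisson parents, Gaussian
offspring) because real TIL infiltrates are clustered — Poisson is the
default for calibration. Nuclei are rendered as filled ellipses whose
colours are defined in stain-concentration space: a nucleus with
haematoxylin level $c_H$ and eosin level $c_E$ is drawn with
Beer–Lambert transmittance $10^{-(c_H \mathbf{h} + c_E \mathbf{e})}$ for
the fixed Ruifrok–Johnston stain vectors $\mathbf{h}, \mathbf{e}$. This
makes colour deconvolution exactly invertible up to pixel noise, which
is the minimal image model that makes segmentation *and* three-class
classification non-trivially learnable. Class morphology: lymphocytes
small, dark, round (radius 2.8 ± 0.3 µm, $c_H = 1.0$); cancer nuclei
large, mildly irregular (6 ± 0.8 µm, axis ratio 1.2–1.7, $c_H = 0.45$);
stromal nuclei elongated and paler (4 ± 0.5 µm, axis ratio 2.5–4,
$c_H = 0.35$). Additive Gaussian pixel noise (sd 0.02) and per-nucleus
staining jitter complete the render at 0.5 µm/pixel. Coordinates are
continuous microns, origin top-left, y downward, matching the raster.

What the generator does **not** emulate: H&E texture (chromatin,
nucleoli), stain variation between labs, tissue architecture (glands,
tumour beds), out-of-focus regions, folds and pen marks, or
whole-slide-image scale. Passing tests therefore demonstrate that the
pipeline's machinery is correct and calibrated on idealized tissue, not
that it reaches any particular accuracy on scanner output.

**Cohorts.** Patients receive covariates from configurable
distributions (age truncated-normal 50 ± 10; grade 1/2/3 with weights
0.10/0.45/0.45; ER+ 60%; node+ 45%; tumour >50 mm 15%; two equal trial
arms; pre-treatment density log-normal with median ≈ 0.5 a.u.). pCR is
Bernoulli with logit equal to an intercept plus a density slope (default
log 2.13 per a.u.) and covariate effects; the defaults give ≈ 20%
prevalence, matching the trial setting. Survival is exponential from
surgery with independent exponential censoring capped at 6.3 years; DFS
is the minimum of relapse and death times. Post-treatment density change
follows a two-component scheme: residual-disease patients draw a
positive shift with probability 0.40 versus 0.05 under pCR, encoding
only the *direction* of the published association, which is all that is
stated. Every generator is a deterministic function of its config,
including the seed.

## Segmentation and classification

The paper-level description ("the algorithm segments cell nuclei", an
SVM over three classes) fixes neither operators nor features, so the
package commits to a standard, fully parameterized chain:

1. colour deconvolution with the fixed H&E matrix (channels clamped at
   zero; optical density is finite even for black pixels);
2. Gaussian smoothing (default 1 µm) of the haematoxylin channel;
3. global Otsu threshold on the min–max-normalized channel — guarded by
   a minimum dynamic range of 0.1 OD, below which an image is declared
   foreground-free instead of letting Otsu split pure noise;
4. hole filling, then a distance-transform watershed (tolerance 2 px)
   to split touching nuclei;
5. an area filter, default 8–250 µm², generous bounds around the
   generator's radii.

`microns_per_pixel` has deliberately no default: calibration must be
explicit. The chain is deterministic, objects are sorted row-major by
centroid, and only centroids and approximate masks matter downstream.

Each nucleus yields seven features: area, moment-based eccentricity,
solidity (area over pixel-corner convex-hull area), equivalent diameter,
mean and sd of haematoxylin OD under the mask, and a moment-based
roundness $A/(\pi a^2)$ with $a$ the semi-major axis (1 for a disc,
$b/a$ for an ellipse). Second moments include the $1/12$ px² pixel-area
term so single-pixel-wide shapes stay well-defined. The classifier is an
RBF-kernel SVM (one-vs-one, cost 1, $\gamma = 1/7$) on standardized
features, trained with equal per-class counts (≈1000 per class in the
reference configuration), so no class reweighting is needed. Training
tiles are segmented with the *production* chain before feature
extraction, so training and deployment features share one measurement
process — training on ground-truth masks instead was observed to shift
the area and OD distributions enough to break generalization. Whether a
QC filter should exclude some segmented objects before classification is
unspecified in the source description; we classify every segmented
object.

## Association models

Logistic regression uses maximum likelihood (IRLS, deviance tolerance
1e-8) on complete cases per model, with the per-model n reported.
Categorical covariates are coded with fixed reference levels — Negative
for ER and nodes, `BEV+D FEC` for arm, `<=50 mm` for size ("<51 mm"
read as ≤50 mm, making the integer classes exhaustive) — so effect
directions match the published table layout. CIs and p-values are Wald
($e^{\beta \pm 1.96\,\mathrm{se}}$); a constant outcome or
quasi-separation (|coefficient| > 15 or se > 100) flags the fit as
non-converged and no odds ratios are reported. Kruskal–Wallis uses the
tie-corrected H (fully tied data degenerate to H = 0). Cox models use
Efron tie handling — the less biased default where the convention is
unstated — fitted separately within ER strata; report tables round
ratios and CI bounds to two decimals. No multiplicity adjustment is
applied anywhere. Whether raw or rescaled density should enter the
regressions is unstated in the source; both are supported and the raw
a.u. scale is the default (the min–max rescaling to [0, 1] is provided
for plotting, with the all-equal input mapping to zeros by convention).

## Verification strategy and problem sizes

Every numerical component is tested against an independent oracle: the
grid-bucketed exact KNN search against an all-pairs brute force (100
random instances, ≤ 500 points, 1e-9); shape features against raw
per-pixel loops; SVM predictions against a hand-written one-vs-one
decision function over the fitted support vectors; the 2×2-table
logistic fit against the cross-product odds ratio; Kruskal–Wallis
against a hand-ranked example (H = 7.2) and the squared standardized
rank-sum statistic; segmentation and classification against the
generator's ground truth (recall/precision ≥ 0.95 on non-overlapping
nuclei; per-class recall ≥ 0.9 on isolated nuclei, since an overlapping
nucleus has no unambiguous object-level label). Estimator calibration
uses coverage simulations — 200 replicates each: cohorts of n = 20000
for the logistic density effect (truth OR 2.13) and n = 5000 with ~30%
censoring for a Cox hazard ratio of 2 — requiring the true effect inside
the fitted 95% CI in ≥ 93% of replicates and the pooled estimate to
recover the truth. Monte-Carlo checks (Poisson count moments, the
λ-linearity of the median summary with Spearman ρ = 1 across a
4-point λ grid, marginal pCR prevalence against a 200000-draw numeric
integration) use 3-standard-error bands. These sizes keep the full suite
in the low minutes on one CPU while leaving each check's Monte-Carlo
error well inside its tolerance.

## Known limitations

- No edge correction in the density statistic: border lymphocytes are
  biased low. Acceptable here because the statistic is used
  comparatively, but absolute a.u. values depend on field geometry.
- The absolute odds-ratio scale "per unit density" is not reproducible
  from the formula alone — the measurement units and any normalization
  behind the published per-unit ORs are not stated — so effect sizes are
  validated by parameter recovery, not by re-deriving the trial
  estimates.
- The segmentation chain is a functional stand-in: equivalence with the
  original implementation's operators cannot be claimed, only adequacy
  on ground-truthed synthetic data.
- The renderer's simplifications mean classifier accuracies reported
  here are upper bounds on real-slide performance.

## A short end-to-end example

```{r example}
library(TILDensity)
res <- runPipeline(pipelineConfig(n_patients = 40, seed = 1),
                   outdir = "til-out")
res$percentages
fitTable(res$fits$uni_pre)
```
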