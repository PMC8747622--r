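---
title: "Estimating leaf SPAD from hyperspectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf SPAD from hyperspectral images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

SPAD meters give a fast, non-destructive relative reading of leaf
chlorophyll, but only at the few square millimetres under the clamp.
Hyperspectral imaging in the visible/near-infrared (400–1000 nm, here 176
bands at roughly 3.6 nm sampling) sees the whole leaf at once, and leaf
reflectance responds strongly to chlorophyll: absorption darkens the
visible bands while well-nourished, thicker mesophyll brightens the NIR
plateau. `spadspec` implements the full chain from raw sensor counts to a
per-pixel SPAD map:

1. **Reflectance calibration** of raw digital numbers against white and
   dark reference frames,
2. **Characteristic-band selection** by three algorithms of increasing
   aggressiveness — Spearman correlation screening (CA), stability
   competitive adaptive reweighted sampling (sCARS), and iteratively
   retaining informative variables (IRIV),
3. **Regression** of SPAD on the selected bands (PLSR, XGBoost, random
   forest, gradient-boosted trees) with 10-fold cross-validation,
4. **Inversion**: applying the fitted model to every leaf pixel and
   rendering the SPAD distribution map.

Because no leaf spectra ship with the package, a first-class synthetic
generator provides datasets and full hypercubes with known ground truth;
every claim the test suite makes is made against that generator.

## Reflectance calibration

Raw counts are converted per element:

$$R = \frac{DN_{raw} - DN_{dark}}{DN_{white} - DN_{dark}}$$

Zero denominators are masked (`NA`), never infinite. Values outside
$[0, 1.5]$ are *kept* — clipping would hide acquisition problems — but
counted and reported via a warning and the `out_of_range` attribute.
White/dark references may be full cubes or single-row frames, which are
broadcast down the rows (the line-scanner geometry). ROI spectra are
per-band means over 1-based, inclusive pixel rectangles; the combined
sample spectrum is the weighted mean of ROI spectra, with pixel-count
weights by default, so it equals the plain mean over all ROI pixels
(the weighting of the instrument software we emulate is unspecified, so
the default is the only choice that is also a pixel-level mean).

## The synthetic generator

Each sample's spectrum is a fixed smooth vegetation template — baseline
0.04, a Gaussian green peak at 550 nm (amplitude 0.10, width 35 nm), and a
logistic red edge centred at 715 nm rising to a 0.49 NIR plateau — plus a
band-localised linear term in standardised SPAD, plus noise:

$$x_{ij} = T(\lambda_j) + \beta_j \frac{y_i - \mu_0}{\sigma_0} + \varepsilon_{ij}.$$

* **SPAD values** are drawn per leaf tier. Defaults follow the measured
  tier means of seedling-stage pepper leaves — lower 66.0, middle 61.0,
  upper 48.3 — with a 4-unit SD per tier (the meter itself is only
  accurate to ±1 SPAD; 4 units is a realistic biological spread for
  50 leaves per tier). $\mu_0, \sigma_0$ are the population mean and SD
  implied by the equally weighted tier mixture, so datasets and
  hypercubes share one link scale.
* **Informative bands** default to ten anchors (550, 670, 700, 710, 720,
  850, 880, 910, 940, 970 nm) with slopes $\beta_j = -0.02$ below 750 nm
  and $+0.02$ above: higher SPAD darkens the visible and brightens the
  NIR, the direction observed in real leaves.
* **Noise** is white noise convolved along the spectral axis with a
  Gaussian kernel (default SD 5 bands, marginal SD 0.005 reflectance),
  giving the smooth, spectrally correlated residuals real spectrometers
  produce. `spectral_corr_length = 0` gives plain white noise.

Hypercubes encode reflectance to 12-bit DN (`dark` at 2 %, `white` at
95 % of 4095) as `raw = dark + R(white − dark)`, stored as floats so that
calibration inverts the encoding exactly; a `quantize` switch adds the
half-DN rounding of a real sensor.

What the generator does **not** emulate: radiative-transfer leaf optics
(no PROSPECT-style physics), vein structure, illumination gradients, or
sensor striping. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under a controlled model, not
field-readiness on any particular camera.

### A note on support-recovery experiments

With spectrally correlated noise, bands *adjacent* to an informative band
become genuinely useful to a multivariate model: they carry the same noise
realisation and none of the signal, so the model can difference out the
noise. "Exact recovery of the planted bands" is then not even the right
target — the extra neighbours earn their place. For experiments that score
selectors by exact support recovery we therefore switch the generator to
uncorrelated noise (`spectral_corr_length = 0`, `noise_sd = 0.001`), where
the planted set is the unique optimal support. This is a property of the
experimental design, decided up front, not a tuning knob.

Even under white noise, exact support recovery has a hard statistical
floor. With $n$ samples, the ${p \choose 2}$ band-pair sample
correlations have SD $1/\sqrt{n}$ (0.082 at $n = 150$) and extremes
around 0.35; the few noise bands whose realised correlation with SPAD —
or with an informative band's noise — lands in that tail *genuinely*
improve cross-validated prediction on the realised sample. IRIV
classifies them informative round after round (correctly, for that
sample), and backward elimination keeps them because removing them
measurably worsens the RMSECV. In our experiments at $n = 150$,
$p = 176$, the final selection typically contains all ten planted bands
plus one to seven such spurious survivors, a count that is invariant to
the noise level because the spurious benefit and the planted bands'
redundancy benefit are both fractions of the same residual variance.
Only a larger sample shrinks it.

## Correlation screening (CA)

Per band, Spearman's $\rho$ is the product-moment formula applied to
rank-transformed reflectance and SPAD (average ranks on ties), with
two-sided p-values from the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$. Selection keeps bands with
$|\rho| > 0.65$ **and** $p < 0.01$. The absolute value matters: green-band
correlations are strongly *negative* and are exactly the bands a
chlorophyll model wants. No multiple-testing correction is applied — the
per-band test at $\alpha = 0.01$ *is* the screening rule, and the
downstream regression, not the p-value, carries the inferential load.
Constant bands yield `NA`, never a fake zero.

## sCARS

Each of $N$ Monte-Carlo runs (default 500, matching schedules that need
several hundred runs before the RMSECV minimum appears) draws 80 % of the
samples, fits PLS1 on the currently retained bands, and weighs each band
by the *stability* of its coefficient: $|\bar{b}_j| / s_{b_j}$ over 20
within-run bootstrap refits. A config switch (`weight = "coef"`) restores
the classic single-fit $|b_j|$ weighting. Band culling is two-step:

* **Enforced selection** keeps the top $\lceil r_i p \rceil$ bands by
  weight, where the exponential decrease function
  $r_i = a e^{-k i}$ is pinned by $r_1 = 1$ and $r_N = 2/p$;
* **Adaptive reweighted sampling** draws that many bands with replacement,
  probability proportional to weight, and keeps the distinct draws,
  floored at 2 bands (the PLS minimum — the floor also makes the final
  run's retained count exactly 2, honouring the EDF boundary).

Each run's retained subset is scored by 10-fold RMSECV on the full sample
set at the best component count; the selection is the subset of the
minimal-RMSECV run. PLS component counts are chosen per fit by inner
5-fold CV up to 10 components — cheap here because NIPALS yields all
nested models in a single fit, so the whole RMSECV-versus-components path
costs about one CV pass. Weight ties break toward the lower band index,
making runs bit-reproducible under the seed.

## IRIV

IRIV asks, for every band, whether models that happen to *include* it
beat the same models with it removed, across a large population of random
variable combinations:

1. A binary inclusion design $A$ (500 rows by default,
   Bernoulli(0.5) entries, rows with fewer than 2 ones redrawn) defines
   500 random PLS models; each row's 5-fold RMSECV is $RMSECV_0^{(k)}$.
2. Flipping variable $i$'s column gives each row's counterfactual
   $RMSECV_i^{(k)}$. The ratio $\phi^{(k)} = RMSECV_0^{(k)} / RMSECV_i^{(k)}$
   is split into $\phi_0$ (rows where $i$ was included) and $\phi_i$
   (rows where it was excluded), and
   $DMEAN_i = \overline{\phi_0} - \overline{\phi_i}$.
   For an informative variable, removal inflates the denominator on
   included rows ($\phi_0 < 1$) and insertion deflates it on excluded
   rows ($\phi_i > 1$), so $DMEAN_i < 0$.
3. A two-sided Mann–Whitney U test (normal approximation, tie-corrected)
   on $\phi_0$ vs $\phi_i$ gives $p_i$, and the four-way classification is
   strong ($DMEAN<0, p<0.05$), weak ($DMEAN<0, p\ge0.05$), uninformative
   ($DMEAN\ge0, p\ge0.05$), interfering ($DMEAN>0, p<0.05$). Exact
   boundary hits fall to the weaker class of their side — measure-zero
   events, but pinned for reproducibility.
4. Strong + weak variables survive to the next round (fresh design, fresh
   folds); iteration stops when nothing is eliminated, fewer than three
   variables remain, or a 50-round safety cap is hit.
5. **Backward elimination** then greedily removes the variable whose
   deletion minimises RMSECV while that minimum does not exceed the
   current RMSECV, ties toward the lower index.

The inner loop — roughly $n_{rows} \times (p+1)$ cross-validated PLS fits
per round — is compiled (RcppArmadillo); a 150-sample, 176-band round
budget is a couple of minutes on one core. PLS component counts use
`min(5, p_{active}, n_{train}-1)` without inner selection: inside IRIV the
comparison is *between designs at the same capacity*, so a fixed cap is
both faster and fairer than per-fit tuning.

The ratio orientation in step 2 is pinned by a constructed test: a
variable whose removal provably inflates RMSECV must come out with
$DMEAN < 0$ and land in the "strong" class.

## Models and evaluation

PLSR is the package's own NIPALS PLS1 (cross-checked against an
independent R implementation and against `mixOmics::pls` in the test
suite); XGBoost and random forest wrap the standard libraries
(single-threaded, seeded); GBDT is least-squares gradient boosting over
`rpart` trees (mean start, depth-3 trees fit to residuals, shrinkage 0.1).
Ensemble defaults are 500 trees, depth 3, learning rate 0.1.

Accuracy is reported from seeded, tier-stratified 10-fold CV. Three
metrics per fold: $R^2$ as the **squared Pearson correlation** between
measured and predicted values — deliberately so, matching the convention
of the modelling literature this package follows; note this differs from
$1 - SS_{res}/SS_{tot}$ for biased predictors and cannot be negative —
plus RMSE and MAE. The reported $R^2_{cv}$, $RMSE_{cv}$, $MAE_{cv}$ are
unweighted means across folds; pooled versions over all out-of-fold
predictions are stored alongside, since the literature rarely says which
convention it used. Folds with fewer than 2 samples are refused (a
per-fold correlation needs two points), so leave-one-out is rejected by
construction.

## Inversion maps

Leaf segmentation thresholds NDVI $(NIR - red)/(NIR + red)$ at 0.3
(red ≈ 670 nm, NIR ≈ 800 nm) and keeps the largest connected component.
Model wavelengths are matched to cube bands by nearest neighbour within
half the band spacing (≈ 1.8 nm); a miss is an error, not a silent
substitution. Predictions are **not clipped** to the SPAD meter range —
out-of-range values are diagnostic of model pathology (linear models
extrapolate at leaf edges) and clipping would hide it. Maps render to a
colour PNG (green–yellow–red, fixed global limits so different leaves
share a scale) plus a grayscale companion; rendering is byte-deterministic.

## Numerical choices and degenerate inputs

* NIPALS stops a component early when residual variance drops below
  $10^{-12}$; later components repeat the last valid model, so requesting
  more components than the data supports is safe.
* RMSECV is pooled: $\sqrt{\sum_k SSE_k / n}$ over held-out folds.
* Empty predictor subsets fall back to the training-mean predictor inside
  the IRIV flip sweep (a row may lose its last variable).
* Zero-variance subsets make an sCARS run "failed": recorded, excluded
  from the minimum, never silently imputed.
* Coefficient-stability weights guard the SD with $10^{-12}$; an exactly
  reproduced coefficient would otherwise divide by zero.
* All pixel coordinates are 1-based and inclusive, as everywhere in R.

## Problem sizes used by the test suite

Unit tests run on 20–100 samples and 6–100 bands. The end-to-end
experiments mirror the study design at its native scale — 150 leaves,
176 bands, 10 informative — for IRIV recovery (5 seeds), sCARS
(500 Monte-Carlo runs), model evaluation (10-fold CV) and the three-leaf
inversion; the whole suite is a quarter-hour-class run on one core.

## Known limitations

* The generator's SPAD→reflectance link is linear per band; real links
  saturate. The ensemble-vs-PLSR comparisons on nonlinear links use a
  quadratic toy construction instead.
* sCARS weight stability is estimated from 20 bootstrap refits; the
  stability ranking for near-tied bands is itself noisy at that depth.
* The Mann–Whitney normal approximation is poor below ~20 design rows
  per side; the 500-row default keeps both sides comfortably large.
* `leaf_mask` assumes one leaf per scene (largest component); touching
  leaves would merge.
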