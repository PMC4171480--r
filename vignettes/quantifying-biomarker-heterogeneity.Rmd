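---
title: "Quantifying tumour biomarker heterogeneity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour biomarker heterogeneity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tumours are heterogeneous at the cellular level: the prognostic content of a
protein biomarker may live not in its average level but in the *distribution*
of its expression across the cells of a biopsy — for instance in a
subpopulation of proliferating (Ki67-positive) cells with atypically low
cytoplasmic CD99. `cellforest` implements a complete desk-scale pipeline for
this question on multi-channel immunofluorescence images of tissue microarray
(TMA) cores:

1. **Segmentation** — per-cell nuclear (DAPI) and cytoplasmic (CD99) masks;
2. **Quality control** — twelve image features and a logistic classifier
   separating in-focus, well-stained fields from degraded ones;
3. **Feature encoding** — per-cell compartment intensities and log2
   nucleus/cytoplasm ratios, pooled per patient and encoded as kernel-density
   vectors evaluated at 100 fixed grid points;
4. **Conventional cut-point analysis** — an exhaustive centile-pair grid of
   Cox models that *demonstrates* the optimism of threshold dichotomisation;
5. **Random survival forest (RSF)** — a bagged ensemble of survival trees on
   the density vectors, with out-of-bag (OOB) Harrell concordance error,
   variable-hunting feature selection and randomised cross-validation.

Because real TMA image sets are large external downloads, the package ships a
**synthetic data generator** that renders TMA-like multi-channel images with
exact ground truth and simulates survival cohorts whose hazard depends on a
planted cell subpopulation. Every pipeline stage is tested against that ground
truth.

# Segmentation

Nuclei: the DAPI channel is median-filtered and Gaussian-smoothed
(`img_preprocess()`; the median filter quantises intensities to 16-bit
precision internally), binarised by an exact Otsu threshold (the
between-class-variance maximiser over the empirical histogram — we implement
the exhaustive maximiser so its contract can be checked against brute force),
refined by a region-based level set with an edge-stopping weight
(`levelset_refine()`: two-phase piecewise-constant region force, curvature
smoothing, fixed iteration cap, mask-change tolerance `1e-4`), and split into
individual nuclei by a watershed tessellation of the Gaussian-smoothed
distance transform. Objects under `min_area` (default 30 px² at the 512-px
test scale) and border-touching objects are removed: partial cells would bias
area and intensity distributions.

Cytoplasm: the CD99 foreground (Otsu) is apportioned among nuclei by
gradient-guided propagation (`EBImage::propagate`, the Voronoi-based
region-growing used by marker-controlled watershed tools): with a spatially
uniform marker the inter-cell boundary is the exact perpendicular bisector,
and with `lambda` small the boundary follows the CD99 intensity landscape.
Cells whose cytoplasm is empty are retained with zero area and flagged.

Validation helpers mirror standard practice: Bland–Altman agreement of
matched areas (sample SD, 1.96·SD limits) and the Hausdorff distance (worst
boundary mismatch; micrometres when a pixel size is supplied).

# Quality control features

On the DAPI channel: x1 inverse coefficient of variation (mean/SD,
*population* SD — the convention is fixed and documented so the arithmetic
oracles are exact), x2 focus score (variance/mean), x3 the Haralick GLCM
correlation after quantisation to 8 equal-width levels with symmetric
accumulation over 1-px horizontal and vertical offsets, and x4 the power
log-log slope (PLLS): the least-squares slope of log10 squared FFT magnitude
against log10 radial frequency over all non-DC coefficients, ignoring
orientation. x5–x12 repeat the PLLS within eight equal-width bands of log10
frequency between the lowest non-DC radial frequency and the radial Nyquist
(the band edges are a package choice; no standard exists). Blur removes
high-frequency power, so x2 drops and x4 becomes more negative —
the directions the tests assert. Classification good/poor uses plain
maximum-likelihood logistic regression on standardised features (first 4 or
all 12), evaluated by leave-one-out cross-validation with a trapezoidal AUC
that equals the Mann–Whitney statistic on the held-out scores.

# Patient feature encoding

Per cell and channel we record compartment totals and means and the log2
nucleus/cytoplasm ratios of both. Ratios of strictly positive means are left
exact; a 1-intensity-unit offset is added to *both* compartments only when
one mean is zero, and cells without cytoplasm yield missing ratios rather
than fabricated ones. CD99 positivity uses the fixed rule *mean cytoplasmic
CD99 > mean nuclear CD99* (strict); a centile-threshold rule on the pooled
log2 ratio is also provided because the Ki67 index can be defined either way
— the rule is an explicit argument, never a hidden default. The Ki67 index of
a patient is the proportion of CD99-positive cells that are Ki67-positive
under a centile threshold of the pooled log2 Ki67 ratio.

For the forest, each patient's cells (pooled over their 1–6 images) are
summarised per feature and stratum (all / CD99+ / CD99−) by a Gaussian kernel
density estimate evaluated at **100 equally spaced points** of a grid shared
by all patients. The grid spans the pooled cross-patient 0.5–99.5 percentile
range (robust to outliers); bandwidths follow Scott's rule on each patient's
own stratum sample, with conservative fallbacks for degenerate samples.
Strata with fewer than 5 cells give a flagged missing vector — a KDE on 2–4
points is noise. Densities are evaluated exactly (`kde_eval()`), so the
trapezoid mass over an extended grid is 1 to numerical accuracy; the 100-grid
values themselves need not sum to 1 because the common grid deliberately
clips extreme tails.

# The cut-point bias demonstration

For every pair of integer centiles (default 1–99 × 1–99) of the pooled CD99
and Ki67 log2-ratio distributions, each patient's Ki67 index is recomputed
and a univariate Cox model (Efron ties) fitted. The grid is rank-based, hence
invariant to monotone transforms of the underlying ratios. **No multiplicity
correction is applied inside the grid — deliberately.** Under a
survival-independent null the single pre-specified pair yields uniform
p-values while the grid *minimum* is far smaller than 0.05 in most
replicates; the package's tests quantify exactly this optimism. Log-rank
scans over all dichotomised splits of a ranked index (minimum group size 5,
to avoid degenerate extreme splits) and Kaplan–Meier curves with Greenwood
confidence intervals complete the conventional-analysis toolkit.

# The random survival forest

Trees are grown on bootstrap samples (with replacement). At each node,
`mtry = ceiling(p/3)` candidate features are drawn; for each, `nsplit = 10`
random split points (values of in-node samples) are scored by the
standardised two-group log-rank statistic, and the best valid split is taken
— "log-rank random" splitting. A split is valid only if both children retain
at least `min_terminal_events = 3` events, which stabilises terminal
Nelson–Aalen cumulative-hazard estimates on cohorts of ~100 patients.
Terminal nodes store the cumulative hazard over the shared grid of training
event times; a subject's **mortality** is the sum of its ensemble cumulative
hazard over that grid, and `exp(-H(t))` gives the per-patient predicted
survival curve, supported up to the last training event. The OOB ensemble
(only trees where the subject was out of bag) gives the unbiased concordance
error; with 1000 trees every subject is OOB for ~368 trees.

Harrell's concordance error is `1 - C` with the convention: pairs with
distinct times are comparable when the earlier time is an event; tied-time
pairs only when exactly one is an event (the event counts as shorter);
prediction ties score 1/2. The implementation (vectorised) is checked against
a brute-force pair enumeration on random small instances.

**Variable hunting** repeats, `n_iter = 100` times: draw a random 80/20
partition; rank features by *minimal depth* in a forest on the 80% part;
forward-introduce features in rank order, refitting and keeping a feature
only while the 20%-test concordance error strictly improves ("no significant
features remain" is operationalised as *first non-improving feature stops the
pass* — an explicit, testable rule). Selection frequency over iterations is
the importance measure. Internal forests use reduced tree counts (default
100, and 50 in the large acceptance simulations) — selection frequency is
robust to this, and it keeps a 100-iteration hunt over 100 features in the
minutes range on one core. **Randomised cross-validation** repeats 50 random
two-thirds/one-third partitions, optionally running variable hunting
confined to the training part, and reports mean ± SD of the test errors.

All randomness flows from R's RNG (the C++ tree grower draws from it too), so
one `seed` argument makes forests, hunts and cross-validations bit-for-bit
reproducible.

# The synthetic generator: what it does and does not emulate

Cells are ellipses (axis ratio ≤ 1.25) with a concentric elliptical
cytoplasm, matching a "small round cell" morphology; a configurable fraction
of cells is placed at nucleus-touching distance to form 2–3 cell clumps that
exercise watershed splitting, the rest keep disjoint cytoplasm. Channel
models give nuclear/cytoplasmic mean intensities with cell-to-cell Gaussian
variation; the planted subpopulation is Ki67-positive and CD99-low, so the
fixed CD99 rule marks it negative — the cell class whose prevalence carries
prognosis. Ground-truth tables are computed from the noiseless rendering over
the final masks, so they agree *exactly* with pixel averages. Degradation is
Gaussian blur plus additive Gaussian noise (Poisson optional), clipped at
zero.

Cohorts: the subpopulation fraction is Beta(2, 5) across patients; survival
is exponential with log-hazard linear in the fraction (baseline median
survival ≈ 4 years at fraction 0, coefficient 1.5), censoring independent
exponential — the standard parameter-recovery setting, so a Cox fit on the
true fractions is an oracle for the generator itself. Default test images are
256 px (not 2048) with 15–30 cells: the area density is far higher than a
60× confocal field, which keeps segmentation runtimes at desk scale without
changing any algorithmic behaviour; sizes and densities are configurable.

Not emulated: tissue texture, stromal architecture, uneven illumination,
antibody batch effects, 3-D structure. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration, not robustness to every
real pre-analytical artefact — on real cohorts the QC stage exists precisely
because such artefacts dominate.

# Numerical choices and degenerate inputs

* Otsu: threshold is the midpoint of the optimal gap; constant images error.
* Level set: region force normalised to unit maximum, curvature clipped to
  ±1, `dt = 1`, re-initialisation every 10 iterations via distance maps.
* Watershed tie-breaks and propagation follow EBImage's deterministic scan
  order; identical inputs give identical label maps.
* GLCM: degenerate (single-level) quantisation errors; PLLS errors on
  all-zero images and on spectra with fewer than two distinct populated
  frequencies (e.g. a pure sinusoid).
* Empty Ki67-index denominators, empty KDE strata, constant PCA columns and
  all-censored survival are explicit errors or flagged missing values — never
  silently fabricated numbers.
* Problem sizes used by the test-suite simulations (e.g. 10 replicate null
  forests of 1000 trees at n = 100, p = 50; 50-repetition cross-validation
  at n = 200, p = 100; a 20×20 centile grid over 50 null replicates, with
  150 extra single-pair replicates so the uniformity check has resolving
  power) are the package's chosen desk-scale study conditions.

# Known limitations

* The level set is a generic region+edge formulation; it does not claim to
  replicate any specific published implementation's boundaries.
* The forward-selection stopping rule is greedy; correlated informative
  features can shadow each other (their selection counts split).
* KDE vectors ignore spatial arrangement of cells within a core.
* The cut-point grid refits ~10⁴ Cox models; on very large cell tables use a
  coarser centile grid first.
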