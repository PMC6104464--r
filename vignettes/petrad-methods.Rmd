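---
title: "Primary-tumour PET radiomics for nodal staging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary-tumour PET radiomics for nodal staging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

In endometrial cancer, nodal involvement drives prognosis and surgical
management, but visual FDG-PET reading of lymph nodes misses deposits below
the scanner's spatial resolution: its specificity is excellent while its
sensitivity is poor, and sentinel-node ultrastaging has made the missed
micrometastases visible. `petrad` implements the complementary strategy of
reading the *primary* tumour instead: quantify its uptake heterogeneity and
shape, classify patients from those features, and OR-combine that radiomic
call with the visual nodal reading so that a patient is labelled positive
when either source is positive. The OR rule's behaviour is a theorem, not a
hope: unified sensitivity is at least each component's sensitivity and
unified specificity at most each component's specificity.

The radiomic signal is carried by a frozen roster of 44 features per
volume of interest (VOI): 4 SUV/volume features (SUVmax, SUVmean, MTV in
mL, TLG = SUVmean x MTV), 6 shape features, 7 first-order histogram
features, and texture features from five 3D matrix families computed with
26-voxel connectivity after quantizing the in-VOI SUV range into N = 64
equal-width levels: co-occurrence (GLCM and its normalized form NGLCM — one
shared direction-aggregated accumulation feeding two feature name-spaces, a
documented redundancy), grey level size zone (GLSZM), neighbourhood grey
tone difference (NGTDM) and neighbourhood grey level dependence (NGLDM).
Neighbourhoods are mask-restricted: voxels outside the VOI are ignored,
never padded.

The centre-piece is the GLSZM zone percentage,

\[ \mathrm{ZP} = \frac{\#\{\text{3D zones of equal grey level}\}}{\#\{\text{VOI voxels}\}} \in \left[\tfrac{1}{N_{vox}}, 1\right]. \]

A lesion mixing very high-uptake foci with necrotic low-uptake regions
spans a wide SUV range; after 64-level quantization of that range its local
fluctuations fall inside single levels, producing few large uniform zones
and a low ZP. A homogeneous lesion spans a narrow range, its noise
straddles the fine level boundaries, and ZP is high. Solidity (VOI voxels
divided by grid voxels inside the convex hull of VOI voxel centers)
captures the irregular, lobulated margins of aggressive primaries.

## Statistical pipeline

*Univariate screening.* Each feature is tested with a two-sided Wilcoxon
rank-sum test (exact enumeration for tie-free samples of combined size at
most 20, normal approximation with tie and continuity corrections
otherwise) and summarized by the Mann-Whitney AUC with ties counted 1/2,
orientation-corrected so reported AUC is at least 0.5 with the direction
("positive-low" vs "positive-high") recorded. Cut-offs maximize Youden's
index over midpoints of adjacent sorted unique values, ties broken toward
higher sensitivity then smaller threshold; classification is strict
("value < cutoff" is positive for positive-low features, so a value exactly
at the cut-off is negative). The screen applies a raw p <= 0.01 gate, as in
the original protocol; a Benjamini-Hochberg column is reported for
information only. Generalization of a single-feature cut-off is assessed by
leave-one-out: the direction and cut-off are refitted on each n-1 subset.

*Feature reduction.* Starting from the smallest-p (largest AUC on ties)
feature, candidates are admitted in increasing-p order if p <= 0.01 and
their absolute Spearman correlation with every already-selected feature is
below 0.85.

*Multivariate model.* A one-hidden-layer network with sigmoidal hidden and
output units; inputs affinely mapped to [-1, 1] by training-set min/max;
(d+1)h + (h+1) trainable parameters (13 for d = 2, h = 3). Positive cases
get a 4x loss weight to counter the roughly 1:4 class imbalance — a loss
multiplier, not oversampling (an equivalent-in-expectation but
lower-variance reading of "quadruplicated"). Assessment uses the mean gmean
(sqrt of sensitivity x specificity) over repeated leave-one-out sessions,
each session splitting the retained patients into stratified
training/validation parts (72/13 for an 86-patient cohort). Model selection
is stepwise backward over input subsets crossed with hidden sizes 2-5,
stopping when no single-feature removal strictly improves mean gmean (ties
toward fewer inputs, then fewer neurons, then lexicographic names — the
stopping rule and tie-breaks are this package's choices, as no published
rule exists). The final predictor averages the outputs of an ensemble
(200 members by default) trained on fresh stratified splits of the whole
cohort and thresholds the mean at 0.5 (the decision threshold is likewise
this package's documented choice).

*Training algorithm.* No published account of the original training
procedure exists, so the package documents its own: full-batch resilient
backpropagation (iRprop-) on weighted cross-entropy, random uniform
initialization in [-0.5, 0.5], early stopping on validation loss with
patience 25 and at most 500 epochs, returning the best-validation
parameters; everything is seed-deterministic. iRprop- was chosen because it
needs no learning-rate tuning and converges in tens of epochs on these
tiny (13-41 parameter) networks. Both the split and the initialization are
re-seeded per session.

## The synthetic cohort generator

No imaging data accompany the original study, so the generator emulates the
*structure the analysis assumes* rather than any particular scanner. A
lesion is an ellipsoid of base uptake `base_suv` on a 2.73 x 2.73 x 3.27 mm
voxel grid with a background at 5% of base; heterogeneous lesions carry a
central necrotic sub-ellipsoid (volume fraction 0.3 at 10% of base uptake)
and Gaussian hot spots; boundary lobulation is a low-order (degree 2-3)
spherical-harmonic radial perturbation whose amplitude scales the
fractional radius change, giving smooth parameterized concavity for the
solidity features. Gaussian noise is added and the image is then smoothed
with an isotropic Gaussian — noise *before* the filter, because PET
statistical noise enters the data before reconstruction smoothing, so the
reconstructed image carries spatially correlated noise. Adding white noise
after the filter instead makes nearly every voxel its own zone after
64-level quantization, saturating ZP near its maximum in every lesion and
erasing the very signal the analysis studies; the pre-filter ordering is
therefore a deliberate design decision. `noise_sd` is the standard
deviation of that pre-filter noise.

Default study condition (the package's frozen simulation of the clinical
cohort composition): 86 patients with exactly 16 LN-positive; LN-positive
lesions receive a necrotic core with probability 0.8, hot spots (1-3 foci,
1.6-2.2x base peak) with probability 0.7, and lobulation amplitude 0.3;
LN-negative lesions are homogeneous with amplitude 0.05; noise sd is 5% of
base SUV; visual nodal detection is Bernoulli at sensitivity 0.5 for
LN-positive and 1 - 0.99 for LN-negative patients; scanner ids rotate
round-robin. Unstated-by-any-source values were fixed once on physical
grounds: semi-axes uniform in 12-18 mm (7-25 mL, typical endometrial
primaries; lesions much smaller than ~10 mm are nearly all partial-volume
rim at this grid and carry no stable texture), base SUV uniform in 6-15,
and an effective image resolution of 9 mm FWHM — the combination of the
intrinsic scanner response (~6 mm), the 5-mm reconstruction post-filter and
iterative-reconstruction under-convergence; `tumour_params()` itself
defaults to the bare 5-mm post-filter value for single-lesion work. These
are modelling assumptions, not facts recovered from data.

What the generator does *not* emulate: sinogram-level count statistics,
attenuation/scatter, inter-scanner texture bias beyond the PSF/noise
settings, biological uptake texture within viable tissue, and lesion-size
confounding (both label groups share one size distribution by design, so
size-driven features carry no label signal). Passing end-to-end tests
therefore shows the pipeline recovers a heterogeneity signal *of this
synthetic form*; it does not validate the clinical effect size.

## Numerical choices and degenerate inputs

* Quantization: `level = min(N, floor((v - min)/(max - min) * N) + 1)`;
  constant VOIs map to level 1 everywhere.
* Constant VOIs: histogram sd/skewness/kurtosis/CV are reported as 0,
  entropy 0, uniformity 1; co-occurrence correlation is 0; NGTDM coarseness
  is capped at 1e6.
* Solidity uses hull membership of voxel centers with an inclusive boundary
  test (tolerance 1e-9, scaled). Planar (single-slice) masks fall back to
  the 2D hull in their plane; collinear masks degenerate to solidity 1.
  The 3D hull is a small built-in quickhull over the per-line extreme
  voxels (a superset of the hull vertices).
* Masks must be single 26-connected components with at least 2 voxels;
  multifocal masks are rejected, not merged.
* Segmentation is mask-mean iterative thresholding (threshold = 0.42 x
  in-mask mean, init at 40% of SUVmax, voxels exactly at threshold
  included); the clinical tool it stands in for is proprietary, so no
  equivalence with clinical contours is claimed. Oscillating iterations
  return the last mask with a `converged = FALSE` flag.
* Stratified splits put `round(val_n * prevalence)` positives in the
  validation part, keeping at least one member of each class in training.
* Percentages are rounded half-up to integers only at reporting time.

## Problem sizes used in tests and the acceptance script

The test-suite experiments run at the study-condition defaults (86-patient
cohorts, 20 seeds for the recovery experiment); oracle equivalence is
checked exhaustively on 1000 random small VOIs (grids up to 4^3, up to 4
levels) against brute-force reimplementations. The model-selection and
permutation-null checks use reduced protocols (24-30 patient toy cohorts,
2 sessions, 100-200 epochs) — the statistical behaviour under test (chance
level under permuted labels, separability recovery) is scale-free. The
acceptance script uses 6 cohort seeds, 3 LOO-gmean sessions and a 50-member
ensemble; these sizes are the package's own reporting choices.

## Known limitations

* The GLSZM-ZP contrast between label groups in the synthetic condition is
  carried mostly by the necrotic core and hot spots; sibling features
  (small-zone emphasis, co-occurrence contrast, histogram kurtosis) sense
  the same bimodal lesion model and often rank comparably or better in the
  univariate screen, unlike in clinical data where ZP was the single
  strongest feature. ZP's univariate rank on synthetic cohorts is
  typically within the top dozen of 44, not reliably top-3.
* The iterative-threshold segmenter is a stand-in; all analysis functions
  accept external masks.
* GLCM and NGLCM share one accumulation; their feature values coincide and
  are kept under two name-spaces only for roster compatibility.
* Visual-detection labels are generated independently of lesion phenotype
  given the LN label; any clinical correlation between primary-tumour
  appearance and nodal detectability is not modelled.
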