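---
title: "Mapping peritumoral progression from preoperative multimodal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peritumoral progression from preoperative multimodal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After maximal resection and chemoradiotherapy, glioblastoma recurs in or
next to the resection cavity in the large majority of patients: tumour
cells infiltrate the non-enhancing tissue around the contrast-enhancing
(CE) lesion well before that tissue changes on conventional MRI.
`periprog` implements a voxel-wise analysis of the *peritumoral*
non-enhancing region that asks whether preoperative multimodal MR —
structural (T1C, FLAIR), diffusion (ADC, FA, DTI-p, DTI-q) and perfusion
(rCBV) maps — can already distinguish the tissue that will later show
radiological progression from tissue that will not.

The pipeline has five stages, each an exported module:

1. **ROI geometry** — progression ROI, non-progression distance shells,
   contralateral NAWM control;
2. **DTI p/q decomposition** — two of the seven input maps;
3. **voxel-wise radiomics** — the 294-feature vector per voxel;
4. **classifier** — a feed-forward network trained voxel by voxel, with
   probability heat maps and external validation;
5. **group statistics** — paired ROI-mean comparisons and the
   significant-feature screen.

A sixth module, the synthetic phantom generator, stands in for the patient
cohort: the source study deposits no images, so every stage is exercised
on seeded phantoms that reproduce the reported direction of each
modality's progression contrast.

## ROI geometry

The progression lesion, already co-registered to the preoperative grid, is
reduced to the *peritumoral progression ROI* by subtracting the
preoperative CE lesion (`progression_roi()`). Non-progression tissue is
stratified by distance to the CE lesion into four shells with outer edges
at 5, 10, 15 and 20 mm (`shell_masks()`). Two conventions needed fixing
where the study description is ambiguous:

* **Bands, not cumulative regions.** The shells are half-open bands
  (d<sub>k−1</sub>, d<sub>k</sub>] from the CE surface; the group analyses
  plot the four bands as separate comparators, which is only meaningful if
  they are disjoint. A cumulative reading (0–5, 0–10, …) is recoverable by
  unioning bands.
* **Distances are physical.** `mask_edt()` is an exact Euclidean distance
  transform (separable lower-envelope algorithm, compiled) that honours
  anisotropic voxel spacing; distances are measured to the nearest CE
  voxel centre, the standard discrete surrogate for surface distance.

The NAWM control mirrors the abnormal region (CE ∪ progression ∪ the
20 mm envelope) across the midsagittal grid plane (`nawm_mask()`). This is
a grid flip, not a symmetry registration — registration is out of scope —
so it presumes a roughly midline-symmetric brain mask, which holds for the
phantoms and for typical preprocessed patient grids. If the mirror leaks
outside the brain the function warns and returns the intersection.

## DTI decomposition

`decompose_pq()` maps an eigenvalue triple to
MD = (λ₁+λ₂+λ₃)/3, p = √3·MD (the norm of the isotropic tensor
component — the convention of the DTI-decomposition literature),
q = √(Σ(λᵢ−MD)²) (the anisotropic, deviatoric norm) and
FA = √(3/2)·q/√(Σλᵢ²). The decomposition is orthogonal
(p² + q² = Σλᵢ², checked to 10⁻¹² in the tests) and scale-equivariant.
Negative eigenvalues are rejected rather than clamped — they indicate an
upstream fitting problem — and the FA of an all-zero tensor is an error,
not 0: a zero tensor has no principal direction, and silently returning 0
would bias downstream ROI means.

## The 294-feature registry

Per modality the registry holds 13 first-order statistics (mean, SD,
median, min, max, variance, skewness, kurtosis, energy, entropy,
uniformity, RMS, mean gray level) and 29 second-order texture features: 21
from the co-occurrence matrix and 8 from the run length matrix. Seven
modalities give 91 first-order + 203 second-order = 294 columns.

The published feature list names only 26 second-order features per
modality, yet the published counts require 29. The registry closes the
gap with three standard members of the same families — GLCM *sum average*,
GLCM *maximum probability*, and GLRLM *run length non-uniformity
normalized* — flagged `reconciliation = TRUE` so they can be dropped or
swapped without renumbering anything.

Choices the study leaves open, fixed here once:

* **Neighbourhood** — a 5×5×5 voxel cube centred on the voxel (clipped at
  the volume edge), configurable via `window`. Voxel-wise texture needs a
  local support; 5³ is the smallest cube that gives GLCM/GLRLM statistics
  meaningful room at 32 gray levels.
* **Quantization** — per-patch min–max binning to `n_levels = 32` levels,
  the common radiomics default. A constant patch maps to level 1. Binning
  per patch makes texture features invariant to adding a constant to the
  image, which the tests assert.
* **Directions** — the 13 unique 3D offsets at Chebyshev distance 1,
  symmetrized and summed before normalization, for both GLCM and GLRLM.
* **Degenerate values** — 0·log 0 ≡ 0 in every entropy; skewness/kurtosis
  of zero-variance patches and correlations of zero-variance marginals
  are 0. The feature table is therefore free of missing values, which the
  classifier requires.
* **Moment convention** — population (divide by n) moments for patch
  statistics; kurtosis is the raw fourth standardized moment (not excess).

The extraction kernels are compiled (Rcpp); pure-R brute-force
enumerations of every matrix and formula live in the test suite and are
required to agree to 10⁻⁹ relative tolerance on every patch of a seeded
8³ volume.

## Classifier

`progression_net()` fits a fully connected network — 294 standardized
inputs, one hidden layer of tanh units, a sigmoid output — by minimizing
mean binary cross-entropy with Møller's scaled conjugate gradient:
conjugate directions with a scalar damping term λ adapted by the
comparison ratio between predicted and actual loss reduction, and no line
search. The source description reads "10 hidden layers", which in the
toolbox it names denotes hidden *neurons*; one hidden layer of 10 units is
therefore the default (`hidden` is configurable). Likewise the model is
called convolutional there, but operates on per-voxel feature vectors with
no spatial weight sharing, so a fully connected network is what is
implemented.

Rows are split 70/15/15 into training/validation/test
(`random_split()`; remainder voxels go to training). Features are z-scored
by training-partition statistics — the raw features span several orders of
magnitude across modalities. Training stops on a vanishing gradient, at
`max_iter`, or when the validation cross-entropy has not improved for
`patience` consecutive accepted steps; the weights with the best
validation loss are kept. Fits are bit-reproducible given the seed, which
drives the split and the initialization.

`probability_heatmap()` evaluates a fitted model at every voxel of a mask
and returns the probabilities as a 3D map; `external_validate()` re-trains
the classifier per repeat (fresh split and initialization seeds) on a
pooled training cohort and scores pooled voxels of held-out subjects,
erroring if any subject appears on both sides. Class imbalance is reported,
not corrected: progression voxels are a small minority, so accuracy and
NPV run high while PPV is the discriminating number, and reweighting would
change the probability calibration that the heat map displays.

## Group statistics

`roi_means()` averages any map over the seven regions (CE, progression,
NP-5 … NP-20, NAWM). `paired_ttest()` is the classical two-sided paired
t-test; zero-variance differences are flagged rather than erroring
(x = y gives t = 0, p = 1). `feature_screen()` tests each of the 294
features across subjects, progression mean vs the pooled non-progression
mean. Raw p-values are the default — the source analysis reports
uncorrected significance across the registry — with Benjamini–Hochberg
available via `adjust = "BH"`. The pooled comparator (union of the four
bands) is used because the screen summarizes "progression vs
non-progression"; band-by-band comparisons remain available through
`roi_means()`.

## The phantom generator

`generate_subject()` builds a spherical brain, an off-midline spherical CE
core (radius jittered ±15% per subject), and a progression region shaped
as a directional spherical cap of configurable thickness abutting — and by
construction disjoint from — the core. Real lesions are irregular, but no
tested quantity depends on lesion shape; the sphere/cap geometry buys
exact analytic oracles (the CE voxel count is verified against brute-force
distance counting).

Each modality is `baseline + shift·1[progression] + noise`. The default
effect table fixes the *direction* of each shift to the reported contrast
pattern — FLAIR, T1C, rCBV elevated; ADC, DTI-p, FA depressed; DTI-q
null — and its magnitude to 0.8 noise standard deviations. Only ROI-level
means and p-values are published, not voxel-level distributions, so the
magnitude is a free parameter: 0.8·σ is large enough for parameter
recovery on a desk-scale cohort and is the single place the phantom's
difficulty is set. Baselines are arbitrary units on deliberately different
scales per modality (they exercise the classifier's feature
standardization); no attempt is made to match physical ADC or rCBV
units. Noise is Gaussian, smoothed to a 2 mm FWHM by circular convolution
with a kernel normalized to unit L2 norm, which preserves the marginal
variance exactly — so the configured `noise_sd` is the true voxel-wise SD
and the shift-recovery test can use exact standard errors.

What the phantom does *not* emulate: acquisition physics, bias fields,
motion, registration error, irregular lesion shapes, spatially
heterogeneous infiltration, or inter-subject anatomical variability.
Passing tests therefore demonstrate that the pipeline recovers known
effects under its own assumptions — not clinical performance. The
published patient-cohort numbers (training accuracy 92.6%, external
accuracy 78.0%) depend on 57 real patients and are not reproducible here;
the phantom analogues (held-out accuracy, PPV/NPV profile, null-cohort
collapse to the majority rate) are what the acceptance script reports.

## Problem sizes and numerical choices

* Default phantom grid: 26³ voxels at 2.5 mm isotropic spacing, CE core
  7 mm, cap 6 mm — a 14-subject cohort (10 training + 4 held-out) yields
  ≈5×10⁴ peritumoral voxels, the scale at which the recovery and
  calibration analyses are run.
* Oracle-equivalence testing uses a 3³ window at 8 gray levels on an 8³
  volume (512 patches, every patch checked); the kernels are the same code
  paths at any size.
* Screen calibration uses 10 null cohorts of 8 subjects with 400 sampled
  voxels per subject; features within a modality are correlated, so the
  pooled type-I rate is judged against a widened band (2–8%) rather than
  the independent-test binomial interval.
* SCG constants follow the standard implementation (σ₀ = 5·10⁻⁵ for the
  finite-difference curvature probe, initial λ = 5·10⁻⁷); the damping
  update guards against λ overflow by declaring a stall.
* Ties and edges: distance bands are half-open on the outside; quantization
  bins are left-closed with the patch maximum in the top bin; edge patches
  are clipped, not padded.

## Known limitations

* The NAWM mirror assumes approximate midsagittal symmetry of the brain
  mask and a lesion confined mainly to one hemisphere.
* With many more parameters than training voxels the network can
  interpolate pure-noise features; the validation-based early stopping
  guards the reported numbers, but very small training tables (hundreds of
  rows) are outside the intended operating range.
* `feature_screen()` assumes approximate normality of per-subject ROI-mean
  differences (they are means over hundreds of voxels) and, by default,
  applies no multiplicity correction — by design, to mirror the source
  analysis it reproduces.
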