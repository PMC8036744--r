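---
title: "Methods: MALDI-IMS molecular subtyping with consensus stroma exclusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MALDI-IMS molecular subtyping with consensus stroma exclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

High-grade serous ovarian cancer (HGSOC) stratifies into four
expression-defined molecular subtypes — C1 (mesenchymal), C2
(immunoreactive), C4 (differentiated) and C5 (proliferative) — that carry
prognostic information but are normally assigned from RNA (e.g. a NanoString
nCounter panel). MALDI imaging mass spectrometry (MALDI-IMS) acquires a full
peptide mass spectrum at every 50-µm pixel of a tissue-microarray (TMA)
core, so a classifier trained on per-pixel spectra against per-core RNA
labels can read the subtype directly off the proteomic image. Two
complications shape the design:

* **Class imbalance.** Subtype prevalences are far from uniform (roughly
  38/28/16/19% for C1/C2/C4/C5), so training sets must be rebalanced.
* **Stromal contamination.** Tumor cores contain stroma whose spectra carry
  no subtype signal; pixels of stromal origin dilute training and test data.
  The package therefore trains a second, compartment-labeled classifier
  ensemble and removes a spectrum only when *all three* members call it
  stromal (consensus exclusion), then retrains the subtype ensemble on the
  filtered data.

`maldisubtype` implements both prongs end-to-end and ships a synthetic
spatial data generator so that every stage is testable without patient data.

# Processing model

## Spectral preprocessing

Spectra are processed in the canonical order **baseline removal → TIC
normalization**:

* *Convolution baseline removal* (window `width = 20` points): the baseline
  is the moving-average-smoothed lower envelope (a rolling minimum followed
  by a rolling mean, both over the window), subtracted and clamped at zero.
  Peaks narrower than about a quarter window keep their apex height within
  5%; a flat spectrum is removed entirely.
* *TIC normalization* rescales each spectrum to unit total ion count.
  All-zero spectra cannot be normalized; a single such spectrum is an error,
  while batch processing drops them with a warning naming the pixel.

## Peak picking and the feature matrix

Per-spectrum local maxima above `snr_threshold` (default 5) times the
spectrum's median-absolute-deviation noise are pooled over all spectra and
clustered by single linkage with gap `> bin_tolerance` (default 0.25 Da — the
same tolerance used for cross-dataset feature parity, for internal
consistency). Intensity-weighted cluster centers seen in at least 1% of
spectra form the aligned peak axis. Feature values are the maximum intensity
within ± tolerance of each center (a local maximum is monotone in peak
height and simpler than integration; absent signal gives 0).

## Feature parity

Two acquisitions of the same tissue chemistry never produce numerically
identical peak lists. To apply a model trained on one dataset to another,
the source axis is matched to the reference axis by greedy nearest-pair
matching in ascending |Δm/z| order; each center is used at most once and
pairs at ≥ 0.25 Da are rejected. Matched columns are renamed to their
reference centers; unmatched centers on either side are reported, never
silently dropped.

## Balanced stratified subsets

Training data are rebalanced core-wise: all spectra of the most infrequent
class are kept; cores of every other class are sampled without replacement,
adding that class's spectra, until the class first reaches the rarest
class's count (cores are atomic, so overshoot is bounded by one core). This
is repeated three times on independent seed streams, and each replicate is
split 70/30 into train/test, stratified per class. The default split unit
is the **core** — all spectra of a core land on one side — because
pixel-level splits of spatially correlated spectra leak information; a
spectrum-level mode exists for comparability, with the choice surfaced as a
flag rather than asserted.

## Signature selection and the classifier ensemble

Per replicate, features are standardized with statistics computed on the
training rows only, a 500-tree random forest ranks features by mean
impurity-decrease (Gini) importance, and the top `floor(0.25 × p)` features
are kept (540 features → 135), ties at the cutoff broken by ascending m/z.
Hyperparameters — the features-per-split fraction (log-spaced over
[0.05, 0.8]) and minimal node size ({1, 5, 10, 20}), a 4 × 4 grid — are tuned
once by stratified 3-fold cross-validation on the first replicate's
training representation, maximizing mean balanced accuracy with ties broken
toward the smaller fraction, then the smaller node size; the winning
parameters are applied to all three learners, and the stroma-filtered prong
reuses them (after exclusion, only subset construction, splitting and
feature selection are repeated — not the grid search). Tree count is fixed
(500 for final learners; 200 inside the tuning folds, where only the
*ranking* of parameter combinations matters).

## Consensus stroma exclusion

The stroma ensemble is trained identically (binary stratification over
stroma/malignant) on the compartment-labeled dataset after parity mapping.
Each member votes "stroma" when its stroma probability is ≥ 0.5 (no tuned
threshold). A spectrum of the subtype-labeled dataset is excluded **iff all
three votes are stroma** — the excluded set is exactly the intersection of
the members' stroma sets, so consensus can only remove a subset of what any
single member would remove. The subtype ensemble is then rebuilt from
scratch on the filtered matrix.

## Evaluation

* **One-vs-one AUC** (Hand-and-Till M): for each unordered class pair,
  restricted to samples of the two classes, the rank-based probability that
  a random class-i sample outscores a random class-j sample on the class-i
  probability is averaged with its mirror image; the overall measure is the
  mean over pairs. For two classes it reduces exactly to the binary AUC
  (tested against an independent rank-sum oracle).
* **Balanced accuracy**: mean per-class recall.
* **FDR**: per predicted class, 1 − precision; macro-averaged over classes
  predicted at least once. (Multiclass FDR is not standardized; macro
  1 − precision is this package's definition.)

Metrics are computed per member on its own held-out test rows and
aggregated across the three replicates (mean AUC; balanced accuracy
mean ± sd). Spectrum-level evaluation is primary; core-level roll-ups
(argmax of the mean simplex over a core's spectra, ties broken by the fixed
class order C1 < C2 < C4 < C5) are a reporting convenience.

## NanoString-style ground-truth labels

Count panels are normalized in the standard chain: background thresholding
(per sample, counts below mean + 2 sd of the negative controls are raised
to that threshold — raised, not zeroed, and idempotent), positive-control
normalization and housekeeping (CodeSet content) normalization (for both,
the factor is the grand arithmetic mean of per-sample geometric means
divided by the sample's geometric mean; the housekeeping set is ACTB,
GAPDH, GUSB, TBP), then log2. Housekeeping probes are thresholded and
scaled along with endogenous ones, which makes the per-sample housekeeping
geometric means exactly equal after normalization. Subtype labels come from
a *pluggable* nearest-centroid step (highest Pearson correlation over the
signature genes, ties by class order); the published 39-gene classifier is
proprietary to its authors and is deliberately not reconstructed.

## Peptide annotation

Signature m/z values are matched to a processed nLC-MS/MS reference list by
minimal absolute mass difference below 1.0 Da. Because 1.0 Da is a wide
window, exact ties are resolved toward the lower mass and flagged
ambiguous. Several features may match one peptide (many-to-one is
expected).

# The synthetic data generator

The generator is first-class, tested code; it emulates the acquisition the
analysis assumes:

* one spectrum per pixel on a shared profile axis (continuous-mode imzML
  semantics), default window 800–3200 Da at 0.25 Da steps — the acquisition
  window; the generator accepts wider ranges such as 600–3200 because
  reported peak ranges and acquisition windows do not always agree, and the
  package exposes rather than resolves that tension;
* 540 true peptide channels with Gaussian profiles (FWHM 0.5 Da; TOF
  reflector mode implies narrow, roughly symmetric peaks but no published
  shape, so Gaussian is a modeling choice) at per-core jittered centers
  (sd 0.05 Da, emulating calibration drift and exercising parity matching);
* 60 cores (30 patients × 2) of 10 × 10 pixels, core subtypes drawn iid from
  the observed prevalence (37.6/27.6/15.8/19.0%); the stroma-study
  companion dataset uses 19 patients / 35 cores;
* 20 subtype-marker channels (5 per class, fold-change 3 in malignant
  pixels of the associated subtype) and 12 compartment markers, half
  stroma-elevated (fold 3), half malignant-exclusive (suppressed to 2% in
  stroma). Three canonical channels carry fixed identities: 1106.719 Da
  (histone H1.2, malignant-exclusive), 836.359 Da (COL1A1,
  stroma-elevated), 976.490 Da (ACTA2, a mesenchymal/C1 marker);
* stroma (30% of pixels per core; 40% in the stroma study) as a contiguous
  blob from a thresholded box-blurred Gaussian random field, mimicking real
  compartment geometry rather than salt-and-pepper labels;
* noise: multiplicative log-normal on peak heights (CV 0.2), an
  exponentially decaying additive baseline (level 10 at the low edge) with
  a small additive noise floor (5% of the baseline level), and a
  per-spectrum log-normal TIC factor (CV 0.3). Marker channels draw their
  base heights with a floor, reflecting that published marker peptides are
  by construction clearly detectable peaks.

Subtypes act at core level because the ground-truth labels the analysis
consumes are per-core RNA calls. The generator does **not** simulate FFPE
chemistry, tryptic digestion, isotope envelopes, matrix crystallization or
spatial intensity gradients; consequently, passing tests demonstrate the
*pipeline's* correctness and the recoverability of planted effects under
this noise model — not performance on patient tissue, whose headline
numbers are reproducible only with the original cohort.

The NanoString panel generator plants subtype shifts (+1.5 log2 on a gene's
associated class) on 40 signature genes, a positive-control titration
ladder, Poisson(4) negatives, and two per-sample nuisance factors: RNA
content (CV 0.5, applied to endogenous + housekeeping probes) and assay
efficiency (CV 0.10, applied to everything except negatives) — content
variation dominates, as it does in FFPE extracts, so housekeeping counts
track content while positive controls track efficiency, and each
normalization step removes its own factor.

# Numerical and design choices

* All randomness flows through explicit integer seeds; sub-seeds are
  derived deterministically, and `ranger` classification `predict` (whose
  vote tie-breaking consumes the R RNG) is wrapped in a fixed RNG context
  inside tuning, so identical configs give bit-identical reports.
* Zero-spread features standardize to 0; degenerate all-zero spectra are
  dropped (batch) or error (single); an empty prediction matrix returns an
  empty table rather than an error.
* Tie-breaks are fixed everywhere: ascending m/z at the signature cutoff,
  smaller parameters in tuning, lower mass in peptide matching, class order
  C1 < C2 < C4 < C5 in label argmaxes.
* Problem sizes in the test-suite fixtures (12–20 cores, 10–40 channels,
  narrow windows) are chosen to exercise each property at sub-second cost;
  the package-default scale (60 cores × 100 pixels, 540 channels) is used
  for the end-to-end statistical checks and the acceptance script.

# Known limitations

* The imzML reader supports the continuous-mode dialect this package
  writes (shared m/z axis, 64-bit external arrays); processed-mode files
  are rejected explicitly.
* The stroma decision threshold (probability ≥ 0.5) is not calibrated;
  with miscalibrated members, consensus exclusion trades recall for
  precision by construction.
* Nearest-centroid labeling is a stand-in for the proprietary 39-gene
  classifier; on real panels users should plug in their own centroids.
* Survival analysis and external-cohort comparisons are out of scope.

# Worked example

```{r}
library(maldisubtype)

cfg <- pipeline_config(seed = 1L)   # default synthetic study conditions
run <- run_pipeline(cfg, out_dir = "run1")
run$comparison                      # mean AUC with vs without stroma exclusion
run$matches                         # peptide annotation of the signature
```
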