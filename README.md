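# maldisubtype

Molecular subtyping of high-grade serous ovarian cancer (HGSOC) from MALDI
imaging mass spectrometry (MALDI-IMS), for computational proteomics groups
working with tissue-microarray imaging data.

HGSOC falls into four expression-defined molecular subtypes — C1
(mesenchymal), C2 (immunoreactive), C4 (differentiated), C5 (proliferative).
`maldisubtype` classifies per-pixel MALDI spectra into these subtypes
against per-core RNA (NanoString-style) ground-truth labels, with a second
prong that removes spectra of stromal origin before retraining:

1. **Preprocessing** — convolution baseline removal (window 20 points), TIC
   normalization, MAD-threshold peak picking pooled over spectra and
   clustered (single linkage, gap > 0.25 Da) into an aligned m/z axis, and
   feature extraction (max intensity within ± tolerance of each center).
2. **Feature parity** — greedy nearest-pair matching of a second dataset's
   axis onto the reference axis (|Δ| < 0.25 Da) so one trained model
   applies to both.
3. **Balanced stratified subsets** — all spectra of the rarest class plus
   core-wise sampling of the others to parity, three replicates, 70/30
   core-level train/test split.
4. **Signature selection** — per replicate, the top 25% of features by
   random-forest Gini importance (540 features → 135).
5. **Classification** — a triplicate `ranger` random-forest ensemble, grid
   search tuned (resolution 4, 3-fold stratified CV), evaluated by
   one-vs-one multiclass AUC (Hand-and-Till M):
   A(i,j) = ½[Â(i|j) + Â(j|i)], averaged over all class pairs, plus
   balanced accuracy (mean per-class recall) and macro FDR (1 − precision).
6. **Consensus stroma exclusion** — three stroma-vs-malignant forests
   trained on a compartment-labeled dataset; a spectrum is excluded iff all
   three vote stroma; the subtype ensemble is then retrained on the
   filtered data.
7. **Annotation** — signature m/z values matched to an nLC-MS/MS peptide
   reference by minimal mass difference (< 1.0 Da).
8. **Ground-truth labeling** — NanoString-style normalization (background
   thresholding at mean + 2 sd of negatives; positive-control and
   housekeeping geometric-mean normalization; log2) and a pluggable
   nearest-centroid subtype assignment.

Patient-level MALDI-IMS data are not publicly distributable, so the package
includes a synthetic spatial data generator (`generate_tma()`,
`generate_stroma_labeled()`, `generate_nanostring_panel()`,
`generate_peptide_reference()`) that plants subtype- and
compartment-specific marker channels — including a malignant-exclusive
channel at 1106.719 Da (histone H1.2), a stroma-elevated channel at
836.359 Da (COL1A1) and a C1 marker at 976.490 Da (ACTA2) — in realistic
noise, and writes/reads continuous-mode imzML with CSV sidecars.

## Worked example

```r
library(maldisubtype)

cfg <- pipeline_config(seed = 1L)        # default synthetic study conditions
run <- run_pipeline(cfg, out_dir = "run1")
run$comparison
```

```
          variant  mean_auc balanced_accuracy fdr_macro n_spectra
1        complete 0.9572247         0.7841667 0.2152977      6000
2 stroma_excluded 1.0000000         1.0000000 0.0000000      4200
```

Read: on the complete dataset (stroma included, and stroma pixels carry no
subtype signal) the triplicate ensemble reaches a mean one-vs-one AUC of
0.957 with balanced accuracy dragged down to 0.78; consensus exclusion
removes the 1,800 stroma-origin spectra (perfect recall and precision under
this noise model), and the retrained ensemble separates the four subtypes
completely (AUC 1.0) — the stroma prong pays for itself, in the same
direction the method reports on tissue. `run$matches` annotates the
filtered signature against the peptide reference (here 34 of 135 features
match a listed peptide; the rest are unlabeled channels), and `run1/` holds
`report.json`, `comparison.csv`, `signature.csv`, `axis.csv`, `parity.csv`,
`exclusion_decisions.csv`, per-pair ROC coordinates and the config as YAML.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --out run1
```

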