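---
title: "Methods: proteomic triage of thyroid FNA specimens by MALDI-MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic triage of thyroid FNA specimens by MALDI-MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fine needle aspiration (FNA) is the standard work-up of thyroid nodules,
but 20–30% of aspirates are cytologically indeterminate. MALDI-TOF mass
spectrometry imaging (MSI) of the needle-wash cytospin offers an
orthogonal, protein-level view of the same cells the pathologist reads:
one linear-mode profile spectrum (m/z 3,000–20,000) per 50 × 50 μm pixel.
`msiTriage` implements a complete triage pipeline over such data: spectral
preprocessing, construction of training observations from
pathologist-annotated regions of interest (ROIs), a sparse logistic model
of malignancy, and three ways of scoring a new specimen, ending in a
benign / malignant / review ("alert") call.

## Preprocessing model

Each pixel spectrum is processed independently, in a fixed order:

1. **Baseline subtraction** — running-median baseline, window
   `2·hw + 1` points (default `hw = 50`). The median is insensitive to
   sparse peaks riding on the chemical baseline; the default window spans
   roughly 200 Da on the default 4,000-point axis, an order of magnitude
   wider than a protein peak, so peak apexes survive subtraction
   essentially intact. Windows are truncated at the spectrum edges.
2. **Smoothing** — unweighted moving average, default half-window 2
   points (a 5-point window). A half-window of 2.5 points is not
   realizable with an integer point window; 2 is the nearest feasible
   value and the parameter is exposed for users who prefer 3.
3. **TIC normalization** — division by the summed intensity, removing the
   arbitrary per-pixel intensity scale. A pixel whose spectrum sums to
   zero carries no information; it raises a classed "empty pixel"
   condition and is masked by every caller, never scored (scoring it as
   0 would drag pixel-mode quartiles towards benign).
4. **Peak picking** — local maxima (plateaus resolve to their leftmost
   point) kept when apex / noise ≥ 6. The threshold is inclusive. Noise
   is the 1.4826-scaled median absolute deviation of the processed
   intensities: a robust scale estimate that a handful of genuine peaks
   cannot inflate. The noise model is this package's choice; only the
   S/N ≥ 6 rule itself is inherited from the protocol being modelled.
5. **Intensity floor** — only peaks with TIC-normalized intensity
   ≥ 0.0003 are retained. The protocol sentence this rule descends from
   literally reads "less than 0.0003 … retained", which contradicts its
   evident purpose of removing residual noise peaks (the mean point
   intensity after TIC on a 4,000-point axis is 0.00025, so "keep only
   below 0.0003" would discard every real protein peak and keep the
   noise). The package therefore defaults to the noise-floor reading
   (`rule = "above"`) and offers `rule = "below"` for the literal one.
6. **Alignment** — all peak m/z values are pooled, sorted, and cut into
   clusters wherever the relative gap exceeds the tolerance
   (single-linkage binning); each cluster becomes a feature at its
   intensity-weighted mean m/z. The default tolerance of 2,000 ppm is
   set by linear-TOF peak widths (tens of Da), not by the ±30 ppm
   calibration accuracy; whether the original analysis binned or warped
   is unrecorded, and binning was chosen here for its transparency and
   testability. Absent features are imputed as 0 intensity, with a
   separate binary detection mask, because the prevalence filters below
   are defined on detection, not intensity.

Every operator is validated in the test suite against a brute-force
oracle (exactly, or to 1e−12 where summation order differs).

## From ROIs to training observations

The pathologist annotates ROIs containing thyrocyte clusters; ROIs can be
a single pixel. Per ROI, processed pixel profiles are averaged pointwise
and peaks are picked on the mean (averaging at the profile stage lets
noise cancel before detection).

Patients contribute wildly different numbers of ROIs (about 5–22 per
benign, 4–19 per malignant patient). To give training observations
comparable support, each patient's ROIs are partitioned into **equivalent
groups** — 5 per benign and 4 per malignant patient — of 1–7 ROIs each,
and the member-ROI means are averaged per group. With 9 + 9 training
patients this yields the design's 45 benign + 36 malignant observations.
How ROIs were assigned to groups is not recorded in the protocol; this
package deals ROIs greedily, largest pixel count first, to the group with
the smallest running pixel total (capped at 7 ROIs), which balances
spectral support and is deterministic given a tie-breaking seed.

Two prevalence filters then reduce the aligned features:

* **intra-patient**: a feature counts as present in a patient iff
  detected in ≥ 25% of that patient's ROIs (boundary inclusive);
* **inter-patient**: features present in ≥ 25% of the benign patients
  *or* ≥ 25% of the malignant patients are kept.

The inter-patient wording ("common to at least 25% of the benign and to
25% of the malignant … representative of benign and malignant lesions,
respectively") is ambiguous between a union and an intersection of the
two class-representative sets. The union is the default here — two
class-specific representative sets, merged — because a purely
class-specific marker is exactly what a discriminant model wants; an
`"intersection"` mode is provided. Filters use patient counts as
denominators and compare with ≥ throughout.

## The malignancy model

An L1-penalized (Lasso) logistic regression of class (malignant = 1) on
the filtered feature intensities, fitted with `glmnet`. Features are
standardized internally and coefficients reported on the intensity
scale. The penalty is chosen by cross-validated binomial deviance
(minimum of the mean CV curve). Folds are **stratified by class and
grouped by patient**: all ROI groups of a patient share one fold,
otherwise within-patient correlation leaks across folds and the penalty
is chosen too small. Fold count defaults to 5 and shrinks to the
smallest per-class patient count when needed (at least 3, below which CV
penalty selection is refused and a fixed penalty must be supplied).
None of folds, selection rule, or standardization are recorded in the
protocol; each is a configuration option here. The fitted model
serializes to JSON and reloads to bit-identical predictions.

## Scoring a new specimen

Three modes, all sharing the same preprocessing and the model's feature
grid:

* **per-ROI** — one probability per ROI mean spectrum;
* **whole-average** — one probability for the mean of every non-empty
  pixel, ignoring the morphological selection;
* **pixel-by-pixel** — one probability per pixel, rendered as a
  green-to-red probability map with a CSV sidecar.

Each mode's probabilities are summarized by quartiles using linear
interpolation between order statistics (R's default type 7 rule — made
explicit and configurable because threshold statistics depend on it).
The triage call compares the 3rd quartile (q3) with two thresholds:
q3 < 0.07 → benign, q3 > 0.28 → malignant, otherwise
`alert_indeterminate`. The 7%/28% defaults are the observed gap between
the classes in the training data of the study this package models, not a
derived rule; the raw q3 is always reported, and the band between the
thresholds is surfaced as an explicit "needs pathologist review" call
rather than forced into a binary answer.

## The synthetic cohort generator

No raw MSI data accompanies the study this package models, so the
generator is a first-class module that emulates the statistical structure
the analysis assumes, with known ground truth:

* per-pixel spectra as sums of Gaussian peaks (FWHM 40 Da — broad,
  linear-TOF-like; exact shape is untestable against any archive and is
  configurable) on a shared 4,000-point axis over m/z 3,000–20,000;
* a peak panel of 15 shared protein peaks plus 2 benign-up and 3
  malignant-up discriminant peaks. Discriminant peaks are *up-regulated*
  (4-fold by default) in their class rather than absent in the other;
  per-patient lognormal height variation (CV 0.5) makes each single
  feature an imperfect classifier, as real markers are;
* 2 patient-private peaks per patient — idiosyncratic contamination that
  the intra-patient filter keeps and the inter-patient filter must
  remove; this is what makes the feature funnel genuinely decrease;
* a decaying-exponential baseline, lognormal per-pixel TIC variation
  (CV 0.3), additive truncated Gaussian noise, and a per-patient mass
  axis scaling drawn uniformly within ±30 ppm (the instrument's external
  calibration accuracy);
* background (non-thyrocyte) pixels — 20% of each specimen by default —
  carrying their own broad low-mass spectral family (colloid/blood-like),
  not silence: the documented failure modes of this assay come from
  background *signal*, not absence of signal;
* ROI/pixel counts drawn log-uniformly within the reported per-class
  ranges (ROIs 5–22 benign / 4–19 malignant; pixels per ROI 3–39 /
  3–162), so the medians land near the reported skewed summaries.

Peak counts and intensities per class are nowhere recorded; these
defaults were chosen once for testability and realistic difficulty, not
fidelity to any particular specimen.

Three challenge scenarios reproduce the clinically hard specimens:

* **paucicellular** — malignant thyrocyte pixels cut to ≤ 10% of the
  standard count, while the background stays at the *standard specimen's
  absolute footprint*: a sparse aspirate covers the same cytospin area,
  it simply contains few cells. This is the design decision that makes
  the scenario reproduce the documented failure direction — background
  pixels dominate the pixel-mode quartiles;
* **heterogeneous mixture** — malignant pixels interleaved with ≥ 70%
  benign thyrocytes inside the same ROIs;
* **colloid-rich** — 80% background pixels at 3× elevated background
  signal.

All three depress the pixel-mode q3 of a truly malignant specimen well
below that of an adequate malignant specimen under the same model — the
misclassification mechanism the pipeline is expected to exhibit,
verified end to end in the acceptance tests as a direction. The exact
level the q3 falls to is dominated by the background pixels, which carry
none of the model's features and therefore all score exactly
1 / (1 + exp(−β₀)); on near-separable training data the intercept is
weakly determined, so that level varies with the seed even though the
direction does not.

## Numerical and degenerate-input policy

* Unsorted m/z axes are sorted (with intensities permuted), not
  rejected — acquisition software variants differ.
* All-zero pixels raise the empty-pixel condition; all-empty ROIs raise
  an "inadequate ROI" condition; a specimen with no scoreable pixels is
  an error, never a silent 0.
* Quartiles: type 7. Boundary comparisons: S/N and prevalence thresholds
  inclusive (≥); triage thresholds strict (<, >), with the boundary
  falling into the alert band.
* imzML I/O stores m/z as float64 and intensities as float32; round
  trips are exact up to float32 rounding. File UUIDs are derived from
  content so identical runs produce byte-identical files.
* Everything random (generator, group tie-breaks, CV folds) descends
  from explicit integer seeds; a full run is a pure function of
  (inputs, configuration, seed).

## Problem sizes used by the test suite

Unit tests run on reduced axes (500–2,000 points) and small cohorts
(2–3 patients per class), which exercise every code path at a few
seconds each. The acceptance tests run the full study design — 9 + 9
patients, 5/4 equivalent groups, the default 4,000-point axis — once per
seed for ten seeds for feature-recovery, and once end to end for the
training-classification, challenge-direction and determinism checks.
These sizes are the package's chosen trade-off between statistical
meaning and a desk-scale run.

## Limitations

* The generator emulates the *statistical* structure the pipeline
  assumes (class-specific peaks, patient effects, background families),
  not TOF physics: no isotope envelopes, detector saturation, or mass
  resolution varying with m/z. Passing tests demonstrate the pipeline's
  correctness and its behaviour under the modelled failure modes — they
  say nothing about performance on real FNA cohorts.
* The quantitative results of the study this package models (its 69
  filtered and 20 selected features, its exact quartile statistics and
  per-patient calls) depend on raw data that was never deposited and are
  not reproducible here; the pipeline reproduces the *design* (45 + 36
  observations, the feature funnel shape, the 7%/28% decision logic) and
  the failure directions.
* Protein identity of features is out of scope, as is co-registration
  with stained images.
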