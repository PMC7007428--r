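---
title: "Discriminating meningioma grades from ATR-FTIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating meningioma grades from ATR-FTIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirgrade)
```

## The problem

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy measures the mid-infrared absorbance of a tissue section
pressed against an internal-reflection crystal. The fingerprint region
(1800–900 cm^-1^) carries the main biomolecular bands — lipid ester C=O
near 1750 cm^-1^, Amide I/II/III near 1650/1550/1260 cm^-1^, nucleic-acid
phosphate stretches near 1225 and 1080 cm^-1^, carbohydrate bands near
1155 and 1030 cm^-1^ — so small compositional differences between tumour
grades appear as small, spatially structured intensity changes.

`ftirgrade` implements a complete chemometric workflow for a three-group
meningioma setting — WHO grade I (`G1`), WHO grade II (`G2`) and grade I
tumours that later recurred (`G1R`) — as three pairwise two-class
problems: preprocessing, outlier QC, training/validation partitioning,
PCA-LDA and PLS-DA classification, metric/ROC evaluation,
spectral-biomarker extraction, and a screen for grade I patients whose
marker profile follows the recurrence trend. Because clinical spectra of
this kind are typically not publicly deposited, the package ships a
synthetic cohort generator so that every stage is exercised end-to-end by
code and tests.

## The synthetic cohort model

`default_study_design()` emulates a realistic acquisition design: 70/24/5
patients in `G1`/`G2`/`G1R`, ten replicate spectra per tissue sample
(replicates share the patient's biology but are taken at different
sampling spots), acquisition over 4000–400 cm^-1^ at 8 cm^-1^ resolution.
The stored point spacing is `resolution/2 = 4` cm^-1^ — the usual
one-level zero-filling — which gives 226 points across the closed
interval 1800–900 cm^-1^.

A spectrum is built as

* a sum of Gaussian bands at the ten fingerprint assignments above plus
  broad background bands (Amide A/OH near 3290 cm^-1^, CH stretch near
  2925 cm^-1^, two broad fingerprint humps at 1400 and 1100 cm^-1^);
* per-patient randomness: each band's amplitude is multiplied by a
  log-normal factor (sd `patient_sd`) and each band centre shifted by a
  Gaussian jitter (sd `center_jitter_sd`), both shared by the patient's
  ten replicates — this is what creates genuine within-patient
  correlation that survives preprocessing and makes patient-level
  splitting meaningful;
* per-replicate randomness: log-normal band-amplitude jitter
  (`replicate_amp_sd`), a scalar log-normal gain (`scatter_sd`), a
  deterministic low-order polynomial baseline, and additive white noise
  (`noise_sd`);
* class effects: each marker multiplies the spectrum by a local
  Gaussian-windowed gain centred at the marker wavenumber, raising
  (`up`) or dividing (`down`) the local intensity by `1 + magnitude`.
  `up` followed by `down` of equal magnitude is an exact identity, which
  the tests exploit.

Two design choices deserve justification:

* **Vector random effects, not a scalar patient offset.** A scalar
  per-patient gain would be removed exactly by the preprocessing chain
  (the derivative is linear and vector normalisation cancels positive
  scaling), leaving nothing for patient-level partitioning to protect
  against. Band-wise amplitude and position jitter survive preprocessing
  and reproduce the within-patient correlation real replicate spectra
  show.
* **Class-specific heterogeneity.** Grade I meningiomas span many
  histological subtypes (meningothelial, fibrous, transitional, …), so
  the `G1` cohort is modelled as the most heterogeneous:
  `center_jitter_sd` defaults to 6/2/1.5 cm^-1^ and `patient_sd` to
  0.15/0.08/0.05 for `G1`/`G2`/`G1R`. This single assumption reproduces
  the qualitative behaviour reported for this kind of data: an
  equal-prior PCA-LDA misclassifies many grade I validation spectra
  toward grade II (specificity far below sensitivity) because the wide
  `G1` scatter spills across the pooled-covariance midpoint boundary,
  while PLS-DA — whose least-squares intercept absorbs the class
  imbalance — keeps sensitivity and specificity consistent. The
  acceptance suite asserts exactly this direction (a ≥ 20-point PCA-LDA
  gap vs a ≤ 15-point PLS-DA gap over 20 seeds at effect magnitude 0.06,
  the suite's "moderate effect" condition).

Default marker effects are placed at the wavenumbers reported
discriminant for grade II and for recurrence, with their reported
higher/lower directions; the default magnitude is 0.15 (fractional). True
effect magnitudes are unknowable from published tables (only directions
are printed), so these defaults are tunable model parameters, not claims
about tissue chemistry.

## Preprocessing

`preprocess()` applies, in order: truncation to the closed fingerprint
interval (900–1800 cm^-1^), Savitzky–Golay second-derivative filtering
(window 7 points, polynomial order 2), and vector (Euclidean)
normalisation. Truncation comes first so that out-of-window points never
leak into the boundary fits.

The SG kernel is the least-squares polynomial derivative estimator scaled
by `spacing^-2`; the sign convention is the mathematical second
derivative, so absorbance peaks become negative lobes. Edge points are
evaluated from the nearest fully interior polynomial fit (same-length
output, switchable to trim mode). The composition annihilates constant
and linear baselines exactly (the order-2 fit reproduces them even at the
edges) and is invariant to positive multiplicative gains; both facts are
asserted to 1e-10 in the tests.

A consequence used throughout: on the normalised second-derivative scale
a *raised* absorbance band appears as a *more negative* value at the band
centre. Marker "directions" in tables are therefore always measured on
the representation being compared, never assumed.

## Outlier QC

`t2q_test()` fits a PCA model (components chosen to reach 95% cumulative
explained variance by default), computes Hotelling's T² over the retained
scores and the Q residual off the model, with the usual F-scaled T² limit
and Jackson–Mudholkar Q limit at α = 0.05. A spectrum is flagged only
when it exceeds **both** limits; the report is diagnostic and nothing is
removed automatically. On homogeneous cohorts the joint flag rate stays
below α (far below, since the AND of two α-level tests is conservative);
on a mixed three-class dataset, or under the strong grade-I
peak-position jitter, the limits are mildly anticonservative (joint rates
of ~6–10% were measured) because a single PCA model is then not a null
model for the data. This is a property of the statistic, and one more
reason the report is advisory.

## Partitioning

`split_dataset()` runs Kennard–Stone maximin selection *within each
class* on patient-mean preprocessed spectra and sends the selected 70% of
patients — with all their replicate spectra — to the training side.
Ties break on the smallest index, making the split deterministic.
Venetian-blinds folds (every j-th training patient to fold j, 10 folds by
default) are attached for component selection. Patient-level grouping is
the default everywhere because replicate spectra of one sample would
otherwise leak between training and validation; a spectrum-level mode
exists behind a flag for comparison with workflows that split raw
spectra.

## Models

**PCA-LDA**: SVD-based PCA on mean-centred spectra, then a two-class
linear discriminant in score space — class means plus pooled within-class
covariance, assignment by smaller Mahalanobis distance with *equal*
priors, signed score `D²(neg) − D²(pos)`. A near-singular pooled
covariance (likely with replicated spectra) is ridge-regularised by
`1e-8·trace/k` with a warning.

**PLS-DA**: NIPALS PLS1 on a ±1-coded response with X-deflation per
latent variable; regression vector `W (PᵀW)⁻¹ q`; classification by
thresholding the predicted response at 0, ties to the positive class.
The positive class per comparison is `G2` vs `G1`, `G1R` vs `G1`, and
`G2` vs `G1R`.

`select_components()` computes venetian-blinds CV accuracy for k = 1..k_max
and picks the smallest k within one standard error of the maximum. The
one-standard-error rule is this package's choice; published workflows of
this kind often fix k per comparison (e.g. 10–17 components), and
`run_pipeline()` accepts an explicit `k` to emulate that.

## Evaluation

Accuracy, sensitivity and specificity are reported in percent from the
2×2 confusion counts; a metric with a zero denominator is `NA`, never 0.
ROC curves sweep the unique score values (ties grouped) and AUC is the
trapezoidal area, equal to the normalised Mann–Whitney statistic with the
half-credit tie convention — asserted against a brute-force pairwise
oracle and against `pROC`. Because tables of this kind are ambiguous
about the evaluation unit, reports carry both spectrum-level metrics and
patient-level ones (majority vote over a patient's replicates, ties to
the positive class).

## Spectral biomarkers

The difference-between-mean (DBM) spectrum is the per-wavenumber
difference of the two class means of *preprocessed* spectra; wavenumbers
with |coefficient| > 0.01 are flagged (the 0.01 scale only makes sense
after normalisation). `top_peaks()` detects local extrema of the absolute
coefficients (plateaus count once at their leftmost point) and keeps the
`n_peaks = 8` largest; `build_marker_table()` adds measured up/down
directions and one-way ANOVA p-values per wavenumber (spectrum-level
observations by default, patient-level as an option), tagging `*` for
p < 0.05 and `**` for p < 0.001. No multiple-testing correction is
applied by default — an FDR column is opt-in — matching common practice
in this literature, questionable as it is.

Two numerical facts shape how marker tables should be read, and how the
recovery tests are designed:

* A marker on a band **flank** produces derivative lobes displaced from
  the injected wavenumber, so its apparent peak can sit one or more steps
  away. The recovery experiments therefore inject markers at band
  centres, with magnitudes equalised for second-derivative visibility
  (`amplitude/width²`), and ask for recovery within ± one axis step.
* PLS regression coefficients localise at class-difference peaks only for
  small component counts; with many LVs the whitening against structured
  within-class covariance makes coefficients ring around strong bands,
  and a coefficient peak may sit where the *mean* contrast is ~0. The
  recovery experiment uses 2 LVs (what the one-standard-error rule
  selects on such data), and the recurrence screen takes its reference
  markers from the DBM spectrum rather than from a many-LV regression
  vector.

## The recurrence screen

For each grade I patient, the patient-mean preprocessed spectrum is
compared with the grade I class mean computed with that patient left out
(avoiding self-bias in a 70-patient cohort). A reference marker
"matches" when the sign of the patient's deviation at the marker
wavenumber equals the marker's recurrence direction; exact zeros never
match. The default rule flags a patient only when **all** markers match —
the strictest reading of "following the recurrence trend" — giving a
binomial null rate of about 0.5⁸ ≈ 0.4% per patient with 8 markers, so a
flagged fraction well above that is informative. `majority` and
`fraction q` rules are available.

`planted_cohort()` builds the validation scenario: 58 background grade I
patients, 12 patients generated with the full recurrence effect set but
labelled grade I, and 5 true recurrence patients, at large effect
(magnitude 0.25) and low noise (patient_sd 0.01, centre jitter 0.25
cm^-1^, noise 0.001). Under these conditions the screen flags exactly the
12 planted patients — 17% of the 70-patient cohort — which is what
`scripts/acceptance.R` recomputes.

## Problem sizes and numerical choices

The test suite runs the full emulated scale where the quantity under
test depends on it (990 × 901 generation, 226-point fingerprint, 50-seed
recovery runs, 20-seed model-behaviour runs) and small constructed
fixtures everywhere else. Other conventions: wavenumber axes are stored
high-to-low but all stages are direction-agnostic; Kennard–Stone and
venetian blinds are deterministic by construction; all generator
randomness flows from a single mandatory seed; exact score ties at a
decision boundary go to the positive class; degenerate ANOVA inputs
(no between-group effect) return p = 1 rather than NaN.

## Limitations

The generator does not model ATR penetration-depth dispersion, Mie
scatter, atmospheric bands, paraffin residues, or instrument drift, and
its class effects are local multiplicative bumps — adequate for testing
the analysis machinery, not for claims about meningioma biochemistry.
Passing tests demonstrate that the workflow recovers what the generator
plants under its assumptions; they cannot certify performance on real
tissue spectra, whose marker tables should be read with the same caution
as any unreplicated biomarker list.
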