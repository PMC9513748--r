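---
title: "Classifying single-vesicle SERS fingerprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-vesicle SERS fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersev)
```

## The problem

Small extracellular vesicles (sEVs, 30–150 nm) carry lipids, proteins and
nucleic acids that reflect their parent cells. On a plasmonic substrate,
surface-enhanced Raman spectroscopy (SERS) resolves one vesicle at a time,
yielding a molecular fingerprint per vesicle: an intensity vector over the
biological information-rich window 553–1581 cm⁻¹ (1023 points, ~1 cm⁻¹
spacing). Classifying these fingerprints turns a droplet of tissue extract,
blood or saliva into a liquid-biopsy readout.

The statistical difficulty is *label noise*: a cancer patient's sample
contains both disease-specific vesicles and perfectly normal ones, so
labelling every spectrum with its donor's diagnosis mislabels the normal
vesicles. The dilution worsens from tissue to blood to saliva, where
vesicles from unaffected organs dominate. `sersev` implements the full
chain that deals with this: preprocessing, fingerprint comparison,
relabeling, classification, donor-level validation, cross-fluid tracking,
map analysis, and a ground-truthed synthetic-cohort generator used by every
recovery test.

## Preprocessing

Per spectrum, in order:

1. **Fluorescence baseline** by asymmetric least squares: the baseline `z`
   minimises `Σ wᵢ(yᵢ−zᵢ)² + λ Σ(Δ²z)²` with iteratively reweighted
   `wᵢ = p` above the baseline and `1−p` below. Defaults `λ = 1e5`,
   `p = 0.01`, 10 sweeps. These values are tuned for the native grid:
   the stiffness a given `λ` imposes scales roughly as `λ/n³` for a feature
   spread over `n` points, so on much coarser grids the same `λ` leaves
   baseline residue. The package keeps a single default because the
   instrument grid is fixed; users resampling to coarser axes should scale
   `λ` down accordingly.
2. **Savitzky–Golay smoothing** (window 11, order 3): each point is replaced
   by the centre value of the local least-squares polynomial. The first and
   last half-windows are filled by evaluating the polynomial fitted to the
   first/last *full* window, so every polynomial of degree ≤ 3 passes
   through the filter unchanged — edges included. (Mirror padding was
   considered and rejected: a reflected polynomial is no longer the same
   polynomial, which breaks exact polynomial reproduction at the edges, a
   contract the test suite checks.)
3. **Min–max normalisation** to [0, 1], removing the large vesicle-to-vesicle
   amplitude variation of SERS enhancement. Constant spectra carry no
   fingerprint; they are dropped and counted rather than mapped to zeros,
   because a zero vector would sit at an arbitrary point of distance space.

Window 11 and order 3 preserve Raman bands of ~10 cm⁻¹ width at ~1 cm⁻¹
spacing while suppressing white noise; both are exposed in
`preprocess_config()`.

## Fingerprint comparison and the threshold τ

Euclidean distance on preprocessed fingerprints is the working metric;
`one_minus_pearson` is available where only band *pattern* should count.
The decision "does this patient vesicle look like a control vesicle?" is
operationalised by a single data-driven threshold:

> τ = 95th percentile of the leave-self-out nearest-neighbour distances
> within the control set.

A patient spectrum whose nearest control neighbour is within τ is as close
to the control population as control spectra are to each other, and is
treated as a *common* vesicle. τ adapts to the cohort's noise level with no
free parameter beyond the percentile (default 95).

Two properties of this calibration matter in practice:

* **Density dependence.** Nearest-neighbour distances shrink as a
  population is sampled more densely. τ calibrated on a dense reference
  therefore under-covers sparse populations. This is why the synthetic
  generator keeps per-subtype spectrum counts comparable between shared and
  group-unique populations (see below), and why *type discovery* does not
  reuse τ directly.
* **Expected leakage.** By construction ~5% of genuinely common spectra
  fall above τ; PP extraction is precise, not perfect, and the
  classification stage is expected to absorb this residual noise.

## Relabeling (PP extraction)

`extract_pp()` splits the patient spectra into the patient-unique
population (PP; nearest control neighbour beyond τ) and common spectra.
Training labels then follow one rule: PP spectra are `GC`, everything else
— common patient spectra *and* all control spectra — is `control`. Common
spectra are kept in training as controls rather than discarded, since they
are informative examples of the normal population. The comparison is done
per biofluid (PT/PB/PS for tissue/blood/saliva PP). The rule is single-pass
by design; no EM-style refinement.

`relabel_cv_comparison()` runs the repeated cross-validation twice on
*identical* splits (stratified by the raw donor groups) so the relabeling
benefit is a paired comparison. In synthetic cohorts at blood-like mixing
(40% unique), relabeling raises mean CV accuracy by tens of percentage
points; with almost no common spectra the two arms agree to within ~1
point, mirroring the qualitative pattern reported for tissue.

## Classification and cross-validation

The classifier is an RBF-kernel SVM (`e1071`, cost 1, tight SMO tolerance
for reproducibility) with inverse-frequency class weights — after
relabeling, PP is often the minority class. The kernel bandwidth uses the
median pairwise-distance heuristic on the training spectra. No feature
selection or dimension reduction precedes classification.

`cross_validate()` repeats a stratified 80/20 split 20 times; accuracy is
the plain fraction of correct predictions. Round seeds are spawned from the
master seed through one `sample.int` stream, so a report is reproducible
from `(data, seed)` alone. Stratum iteration is locale-independent (radix
order) for the same reason. LDA projections (`lda_project()`) serve
visualisation; with p = 1023 ≫ n the pooled within-class scatter is
singular, so it is shrunk toward `mean(diag(S)) · I` with intensity 0.1.

## Donor-level validation (LPOSO)

Spectrum-level cross-validation can flatter a method: spectra of one donor
appear on both sides of the split. "Leave-a-pair-of-samples-out" validation
holds out one GC donor and one control donor per fold, pairing donors
without replacement until every donor is out once per round; 10 rounds with
15+15 donors give 150 folds. Inside each fold, *everything* is re-derived
from the remaining donors: τ, the PP split, the kernel bandwidth, the SVM.
A fold whose relabeled training set has no PP spectra trains no model and
scores its held-out donors 0 (neutral) — without a patient-unique
population there is no evidence to call.

A held-out donor's score is the mean signed SVM margin over their spectra
(`fraction_positive` is available as an alternative aggregator). Per round,
the 30 donor scores are swept into one ROC; AUC is computed as the
rank-statistic (ties ½), which equals the trapezoidal area under the
empirical ROC, and the mean AUC across rounds is reported. Donor-level
scoring is the clinically coherent reading; spectrum-level ROC remains
possible by passing margins directly to `roc_and_auc()`.

## Tracking PP types across fluids

Within each fluid the PP spectra are clustered hierarchically (average
linkage). The cut height for *type discovery* is chosen by
`suggest_cut_height()`: the midpoint of the largest gap in the sorted merge
heights. When types are well separated, within-type merges accumulate at
small heights and between-type merges at much larger ones, and the widest
gap separates the regimes. This adapts to how sparsely each type is
sampled, which a τ calibrated on the (dense) control population does not —
reusing τ as the cut fragments sparse types.

Across fluids, a tissue type matches a blood (saliva) type when their
centroids are **mutually nearest** and within τ; mutuality prevents chained
many-to-one matches. Only types matched in *both* other fluids are
reported, with per-fluid memberships, centroids, an overall mean spectrum
(on normalised intensities), and a per-fluid source distribution. In
generated cohorts the per-type tissue counts dominate the saliva counts,
reflecting the configured dilution ordering.

## Raman maps

`band_intensity()` integrates the baseline-subtracted signal over a window
(default half-width 8 cm⁻¹) around a marker band — 1123 (protein), 1270
(phospholipids), 1341 cm⁻¹ (nucleic acid) — by the trapezoidal rule;
integration is preferred over peak maxima for robustness to one-point
jitter. Maps are built per lattice position of a fine scan (0.1 µm step);
the hotspot is the maximum after zero-padded 3×3 mean smoothing (zero
padding keeps partially covered edge windows from being inflated), ties to
the lowest (row, column). Pairwise Pearson correlation of flattened band
maps quantifies co-localization of the three substances within one
diffraction-limited spot.

## The synthetic cohort generator

No clinical spectra are distributed with the study this package
operationalises, so the generator is the package's test bed. It emulates,
with exported ground truth:

* 15 donors per group, 50–70 spectra per donor-fluid sample;
* vesicle subtypes as random subsets of a 28-band peak library (Lorentzian
  lines, including the 1123/1270/1341 cm⁻¹ marker bands), with
  shared, GC-unique and control-unique pools; nine GC-unique types are
  flagged cross-fluid;
* a group-unique spectrum fraction of 0.7 / 0.4 / 0.15 for tissue / blood /
  saliva — the configured dilution of disease-specific vesicles in
  circulation (a modelling choice, not a measured quantity);
* per-spectrum nuisance: lognormal global amplitude (σ = 0.15), per-peak
  height jitter, ±1 cm⁻¹ band-position jitter, a random smooth fluorescence
  background (quadratic plus broad Gaussian, amplitude 0.5), and white
  noise (σ = 0.01).

Design choices worth stating explicitly:

* **Every donor carries the full shared pool.** The premise of relabeling
  is that normal vesicle types are common to patients and controls alike.
  Donor heterogeneity (`subtype_prevalence = 0.7`) applies to the
  group-unique pools only, so no unique subtype is guaranteed pan-patient —
  matching the observation that no tracked type appears in every patient.
  (Subsampling the shared pool per donor additionally makes rare shared
  types look unique, which is a statement about sampling, not disease.)
* **Six group-unique subtypes per fluid** keep per-subtype spectrum counts
  comparable between shared and unique populations (~60–70 spectra per type
  at blood-like mixing). Strongly unequal per-type densities would bias the
  percentile calibration of τ for reasons unrelated to the relabeling rule.
* **What the generator does not model:** donor-level batch effects,
  correlated (pink) noise, cosmic-ray spikes, wavenumber miscalibration,
  multi-vesicle hotspot occupancy, and any real biochemical interpretation
  of the bands. Passing recovery tests therefore demonstrates internal
  consistency of the pipeline under the stated statistical structure, not
  performance on clinical data.

Map scenes use a point emitter under an isotropic Gaussian beam
(σ = 0.42 µm, i.e. ~1 µm FWHM spot) sampled at 0.1 µm, plus white noise.

## Problem sizes used by the test suite

The unit and property tests run on reduced problem sizes chosen as the
smallest that still exercise the property: coarser wavenumber grids
(64–257 points) where baseline fidelity is irrelevant, the native
1023-point grid wherever preprocessing quality or band integration matters,
4–8 donors for structural checks, and the full 15+15 donors for everything
protocol-level (LPOSO pairing, PP recovery, tracking). The acceptance
checks use the full donor count and native grid, with per-sample spectrum
counts of 6–14 for the classifier-heavy protocols and the full 50–70 for
PP recovery and tracking (tracking needs the full count: at 15% uniqueness,
saliva must still sample all nine cross-fluid types).

## Numerical choices and degenerate inputs

* ALS solves its penalized system with sparse Cholesky factorisations; a
  dense-solver re-implementation in the test suite agrees to ≤ 1e−6.
* Cross-set Euclidean distances use the expanded quadratic form with exact
  recomputation of near-zero entries, where the expansion cancels
  catastrophically.
* Nearest-neighbour ties break to the lowest reference index; this affects
  the reported neighbour only, never the distance.
* `cutree` at an infinite cut returns one type; a single spectrum forms one
  singleton type.
* Constant spectra: refused by `minmax_normalize()` (condition class
  `sersev_degenerate`), dropped and counted by `preprocess_cohort()`,
  rejected by `locate_hotspot()` and `colocalization()`.
* Unbalanced donor groups are rejected by `lposo_schedule()` rather than
  silently truncated.
* All orderings of character ids use radix (C-locale) sorting so results do
  not depend on the session locale.

## Known limitations

* The "customised distance metrics" of the original analysis are not
  specified anywhere; the package ships Euclidean and 1−Pearson behind a
  common argument and leaves the contract pluggable.
* Whether PP extraction should match spectra one-to-one (implemented
  default) or cluster-to-cluster is undecidable from the source; cluster
  level matching can be composed from `assign_subtypes()`.
* Donor-level LPOSO scores assume spectra within a donor are exchangeable;
  any within-donor acquisition drift would violate this silently.
* Headline clinical numbers (accuracies ~90/85/72%, AUC 0.96/0.91/0.65)
  belong to undeposited clinical data and cannot be reproduced here; the
  package's claims are the property-level behaviours above.
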