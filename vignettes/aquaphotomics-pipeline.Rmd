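---
title: "Methods: NIR biofluid classification and aquaphotomics in aquaphot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR biofluid classification and aquaphotomics in aquaphot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaphot)
```

## The analysis in one paragraph

Biofluid spectra in the 1300–1600 nm first overtone of the OH stretch are
almost entirely a water spectrum, peaking near 1450 nm. The diagnostic
hypothesis of aquaphotomics is that a systemic disease re-organises the
hydrogen-bond population structure of body water, and that this shows up
as coordinated intensity changes in twelve narrow water absorbance
sub-bands (the water matrix coordinates, WAMACs, C1–C12). `aquaphot`
operationalises that hypothesis as a standard chemometric pipeline:
scatter-corrected spectra are decomposed by PCA, a discriminant classifier
(LDA, QDA or soft-margin SVM) is fitted on the scores, and the whole
procedure is validated leave-one-subject-out and on a 75/25
calibration/test split — once on the full analysis window and once
restricted to the WAMAC wavelengths, with an aquagram summarising the
class-wise band pattern.

## The synthetic cohort generator

No patient spectra ship with the package; the generator produces cohorts
whose statistical structure matches the assumptions the analysis relies
on, so every downstream claim is testable.

A noise-free spectrum is a sum of Gaussians: one broad, dominant water
component (centre 1450 nm, σ = 38 nm, amplitude 1.0 AU — a realistic
absorbance for a 1 mm path length) and one narrower component per WAMAC
band, centred at the band midpoint with σ equal to half the band width
and base amplitude 0.02 AU. The bands are given as ranges in the
literature, not line shapes, so Gaussians at the midpoints are the
simplest faithful choice. One deliberate exception: the C8 component
(1448–1454 nm, the solvation-shell band that carries the canonical water
absorbance maximum) is centred at 1450 nm rather than its 1451 nm
midpoint. With the component at the midpoint, the composite maximum falls
between grid points at 1450.5 nm; anchoring C8 at the canonical peak
keeps the global maximum of the base spectrum exactly on the 1450.0 nm
grid point, which is the structural property the generator is meant to
guarantee.

Class structure enters as fractional shifts of the band amplitudes.
A `preset()` encodes the effect *directions* of the plasma and saliva
water spectral patterns (e.g. plasma: disease lowers C1–C4 and C8 and
raises C11–C12; the CD subtype additionally tilts the whole C1–C8 versus
C9–C12 balance). Effect *magnitudes* are free parameters: the source
analyses report directions and perfect accuracies but no effect sizes, so
the default preset realises a well-separated regime — a 5% amplitude
shift, i.e. 1 mAU at a band peak, against 0.2 mAU instrument noise (5:1)
— while the `null` preset sets every effect to zero for type-I-error
testing. Subjects jitter around their class effect (sd = 20% of the
effect per band), which creates the subject > replicate variance
hierarchy that makes replicate-leakage tests meaningful, and every
replicate picks up multiplicative scatter (slope sd 0.02), an additive
offset (sd 0.005 AU) and iid Gaussian noise — exactly the artifact family
SNV and MSC are designed to remove. The default cohort mirrors the study
design the pipeline targets: 3 healthy, 2 CD and 8 UC subjects, 3
replicate spectra each (39 spectra), 1280–1630 nm at 0.5 nm.

What the generator does *not* emulate: temperature-dependent band
shifts, instrument drift between replicates, non-water constituents
(protein/lipid overtones), or any physically derived line shape. Passing
tests therefore demonstrate that the pipeline recovers the class
structure it assumes — band-localised, subject-consistent amplitude
shifts — not that real plasma spectra carry such structure.

## Pretreatment operators

All operators preserve the wavelength grid and are composable via
`preprocess_spec()`. Data-set-level statistics follow a strict
fit-on-calibration contract: `fit_preprocess()` freezes them (currently
the MSC mean-reference spectrum) and `apply_preprocess()` replays them on
held-out spectra, so no test information ever enters a fit. A canary test
verifies that perturbing test spectra changes nothing on the calibration
side.

- **SNV** z-scores each spectrum with the sample (n−1) sd.
- **MSC** regresses each spectrum on a reference (default: data-set mean)
  and inverts the fitted slope and offset.
- **Savitzky–Golay** fits a least-squares polynomial in a sliding
  symmetric window and evaluates its `d`-th derivative at the centre,
  scaled by `step^(−d)` so derivative spectra are per-nm and
  grid-independent. Edge points are evaluated off-centre from the first
  and last full windows. A symmetric window must be odd, so the
  conventional "12-point" smoothing setting is interpreted as 12
  neighbours plus the centre — a 13-point window; the window stays
  configurable. Default polynomial order is 2 for both smoothing and
  derivatives (the customary chemometrics default).
- **Normalisation** offers unit-vector (default — the most common
  "normalize" in chemometrics software), min–max and unit-area variants;
  since the convention is software-dependent, all three are selectable.
- **Detrending** (default order 2), **linear baseline correction**
  (through the first and last point, endpoints map to 0) and
  **absorbance↔transmittance** (`T = 10^−A`) complete the closed set.

## Models

`pca_fit()` is a column-mean-centred SVD; explained variance percentages
are computed against the full-rank total, component signs are fixed by
making the largest-magnitude loading entry positive, and numerically null
components (relative variance < 1e−12) are dropped. `select_components()`
takes the smallest k whose cumulative explained variance reaches the
threshold (default 99%, the usual PCA-LDA calibration rule).
`hotelling_t2()` flags outliers against the F-distribution control limit
`k(n−1)/(n−k)·F₁₋α(k, n−k)`.

LDA and QDA are Gaussian discriminants implemented from their defining
math: shared pooled covariance `Σ(n_c−1)S_c/(n−C)` for LDA, per-class
covariances for QDA, empirical class priors by default (the cohort is
unbalanced — 3 healthy vs 10 diseased subjects — so empirical priors are
the honest default; uniform priors are selectable). Near-singular
covariances, inevitable with a 3-subject class in a ≥99%-variance score
space, receive a diagonal ridge of `1e−8 × trace/dim`, escalating by
factors of 100 a few times before failing with an error that names the
dimensionality. Exact discriminant ties break to the first class in
sorted name order.

The SVM solves the soft-margin dual by sequential minimal optimisation
with a deterministic working-set rule (the partner index maximises
|E_i − E_j|), so training never touches the RNG. Multiclass problems use
one-vs-one majority voting with ties broken by summed decision values.
Score columns are standardised to zero mean and unit variance before
training (the libsvm convention, with centre and scale frozen from the
training data): PC scores of scatter-corrected spectra live at scales of
~0.01, where an unscaled margin at the default C = 1 underfits. The
default kernel is linear with C = 1; RBF is available with
`gamma = 1/d`. Calibration R²/RMSEC for the SVM are defined by regressing
numeric class codes (healthy = 0, IBD = 1; healthy = 0, UC = 1, CD = 2)
of the true labels on those of the fitted labels — a declared convention,
since classifier R² is not standardised across software.

## Validation

The validation unit defaults to the *subject*: all replicates travel
together through splits and folds, and a subject's replicate predictions
are aggregated by majority vote with ties broken toward the
disease-positive class (a screening rule that favours sensitivity;
configurable). Spectrum-level validation is retained deliberately — a
regression test shows why it must not be the default: on a cohort with no
class signal but strong subject signatures, spectrum-level leave-one-out
reaches ~100% while subject-level stays at chance, because the held-out
spectrum's sibling replicates sit in the training fold.

The 75/25 split is subject-grouped, stratified per class with
`round(frac·n_subjects)` calibration subjects (clamped so both sides keep
at least one subject per class), and deterministic given its seed.

Quality metrics are computed one-vs-rest per class. Two total-accuracy
variants are reported side by side: the prevalence-weighted form
`(TN·TN/(TN+FP) + TP·TP/(TP+FN))/n·100` — a weighted mean of sensitivity
and specificity that never exceeds standard accuracy, with equality
exactly when each quadratic term is tight (FP = 0 or TN = 0, and FN = 0
or TP = 0; the test suite proves the inequality exhaustively for all
confusion matrices with n ≤ 20) — and the standard form `(TP+TN)/n·100`.
Metrics with zero denominators are reported as `NA`, never coerced to 0.

## WAMAC bands and aquagrams

`wamac_table()` packages the twelve bands with their inclusive nm ranges
and structural assignments. Band lookup uses closed intervals; the
printed C10 (1472–1482) and C11 (1482–1495) ranges share 1482 nm, which
is assigned to the lower-numbered band so that membership is unique (it
matters for band averaging). On the 0.5 nm grid the twelve bands retain
255 of the 601 analysis-window wavelengths.

The aquagram z-scores scatter-corrected absorbance per wavelength over
the *pooled* data set, `A'(λ) = (A(λ) − μ(λ))/σ(λ)` (sample sd), and
averages `A'` per class over each band's wavelengths — all of a band's
wavelengths contribute, rather than one representative point, mean
aggregation being the same convention the reference spectrum uses.
Default scatter correction is MSC against the data-set mean, with SNV
selectable. By construction every `A'` column has mean 0 and sd 1, and an
SNV-based aquagram is invariant to a constant offset on every spectrum.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run entirely on generated data:
the 13-subject default cohort (39 × 701) for end-to-end checks, 50
regenerated null cohorts for the type-I-error guard (exact binomial 99%
band around the majority-class rate), and small matrices (≤ 120 rows) for
the oracle comparisons against brute-force polynomial fits,
eigendecompositions, `MASS`, `e1071` and `signal`. Exact algebraic
identities are asserted at 1e−9…1e−12; iterative SVM geometry at 1e−3.

## Known limitations

- The generator's Gaussian band model is statistical, not physical; no
  claim about real biofluid spectra follows from the synthetic results.
- QDA with very small classes leans on ridge regularisation; with a
  2-subject class its covariance is close to meaningless, and grid cells
  that lose a class in a fold are reported as failed cells rather than
  rescued.
- The SMO solver targets the small problems this design produces
  (tens of spectra); it is not tuned for large n.
- Effect magnitudes, the Savitzky–Golay window convention and the
  normalisation variant are declared defaults, not inferred facts; all
  are configurable where analyses may need to vary them.
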