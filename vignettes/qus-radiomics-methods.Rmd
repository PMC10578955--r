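---
title: "QUS radiomics: models, parameters and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QUS radiomics: models, parameters and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator emulates and what it does not,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. The spectral model

Raw RF ultrasound from soft tissue is modelled as a superposition of
echoes from discrete sub-resolution scatterers. For a statistically
homogeneous region, the expected power spectrum of a gated, windowed RF
segment factorizes as

$$ S(f) \;\propto\; |P(f)|^2 \; \cdot \; \bar n \,\overline{a^2}\, f^4
   F(f; d) \; \cdot \; A(f, z), $$

with $P$ the pulse/system response, $\bar n \overline{a^2}$ the acoustic
concentration (number density × mean-square relative impedance
amplitude), $f^4$ the Rayleigh factor, $F$ a form factor encoding the
finite scatterer size $d$ (the frequency roll-off steepens as scatterers
grow), and $A$ round-trip attenuation. Dividing by the spectrum of a
reference phantom with known backscatter cancels $|P|^2$ (and, on real
hardware, diffraction/beamforming terms), which is the reference-phantom
method. The spectral chain therefore is:

1. **Window spectrum** — per-line Hamming taper, FFT (length = next power
   of two ≥ the gate, zero-padded, so all windows share one frequency
   grid), squared magnitude averaged across the window's lines.
2. **Normalization** — `10 log10(S/S_ref)` plus point compensation
   `+ 4 α f d` dB at the window-centre depth `d`. The coefficient `α`
   (dB/cm/MHz) follows the one-way-amplitude (20·log10) convention; the
   simulator applies exactly the inverse factor per scatterer, so the
   compensation rule and the forward model are a matched pair. Phantom
   attenuation has its own hook (default 0).
3. **Line fit** — OLS of dB values on frequency over the fixed 3–8 MHz
   band. SI is the 0 MHz intercept, SS the slope, and MBF is *defined*
   as the fitted value at the 5.5 MHz band centre, so
   `MBF = SI + SS·f_c` is an identity, tested to machine precision.
   The band is a configuration constant, not re-derived per spectrum:
   the −5 dB description and the 3–8 MHz numbers come as a package, and
   the printed band is taken as authoritative.
4. **Form-factor fit** — the measured backscatter coefficient
   `BSC(f) = BSC_ref(f)·10^{N(f)/10}` is fitted in dB space by
   `10 log10(AAC · f⁴ · F(f; ASD))`. For fixed ASD the optimal AAC is a
   closed-form mean offset, so the search is one-dimensional: a 0.5 µm
   grid over 10–300 µm plus parabolic refinement (self-consistency on
   noiseless model curves recovers ASD to ≤ 0.5 µm). A fit at a search
   bound is flagged `boundary` rather than silently returned.

**Form factors.** The Gaussian model is `F = exp(−0.827 k² a²)` with
`a` the effective radius. The fluid-sphere (Anderson) model is computed
from the classical partial-wave series with spherical Bessel functions
(downward Miller recurrence for `j_n`, upward for `y_n`), truncated when
a term falls below 1e−10 of the running sum, and normalized by its own
numerically evaluated Rayleigh limit so `F → 1` as `ka → 0`; the series
is validated against the `ka⁶` Rayleigh scaling within 1 %. The density
and sound-speed contrasts default to `g = h = 1.02` (weak fluid contrast)
— the clinically motivated choice for fluid-filled nodes; nothing in the
pipeline is sensitive to the exact contrast because only the *shape*
vs-diameter family matters, and both models are exercised in parallel
(their ASD estimates are rank-correlated by test). AAC is reported in dB
relative to an arbitrary-but-fixed calibration constant of the phantom
curve; only relative AAC values feed the texture stage, so the absolute
offset is documented as arbitrary.

## 2. Parametric maps

Maps use a 2×2 mm window with 94.1 % overlap in both directions. Window
and step sizes are converted to integer samples/lines by rounding
half-up with the step floored at 1; at the default geometry (40 MHz
sampling, 1540 m/s, 256 lines over 3.8 cm) this gives a 104-sample ×
13-line window stepping 6 samples × 1 line — asserted in tests as a
frozen property of the geometry. A window contributes a map pixel when
its **centre** lies inside the ROI mask (windows may overhang the edge);
centre-inclusion maximizes usable pixels on small nodes, and the map
pixel count is verified against a brute-force window enumerator.
Per-window fit failures invalidate single pixels and are counted, never
interpolated. Group comparison of ROI means uses Student's pooled
one-tailed t (configurable direction); the degenerate all-constant case
returns p = 0.5 by convention.

## 3. Texture features

Maps are discretized to `Ng = 16` equal-width bins between the ROI's own
min and max. Consequences, both tested: any positive affine rescaling of
a map leaves all texture features unchanged, and a constant map occupies
level 1. Fixed bin *count* (rather than fixed bin width) is the robust
choice across seven maps with incommensurate physical units.

The four matrix families follow the 2-D conventions of the standard
open-source radiomics tooling: GLCM distance 1, four directions,
symmetrized and direction-summed; GLRLM runs direction-summed over the
same four directions; GLSZM 8-connected zones; GLDM 8-neighbourhood with
zero tolerance, where the dependence column is *equal neighbours + 1* so
an isolated pixel has dependence 1 and no formula divides by zero.
Invalid pixels are hard boundaries: they never pair, never extend runs
or zones, and never count as neighbours. The 68-feature catalog (22 GLCM
+ 14 GLDM + 16 GLRLM + 16 GLSZM) is frozen in
`texture_feature_catalog()`; the 22 GLCM features are the classical 24
minus Sum Average (redundant with Joint Average for symmetric matrices)
and MCC — the two commonly disabled in the reference tooling; which two
were omitted originally is not recoverable, so the list is a documented
package constant. Zero-safe conventions: an empty matrix yields all-zero
features (entropy of the empty distribution 0, emphasis ratios 0);
Correlation of a nonempty zero-variance matrix is 1; skewness/kurtosis
of a constant sample are 0. Percentiles use linear interpolation (R
type 7), so the 90th percentile of 1…100 is 90.1.

Matrix counting is implemented in C++ (the per-patch workload of the TOT
stage makes R-level loops impractical); its ground truth is a pair of
deliberately naive R enumerators in the test helpers, plus a separate
naive feature evaluator standing in for the external reference
implementation, which is not installable in the offline build
environment. Matrices must agree *bit-identically* on 1000 random 8×8
images, features to 1e−6 relative.

## 4. Texture-of-texture

A TOT map evaluates one named catalog feature on every 3×3 patch of a
QUS map and writes the value at the patch centre. Two open choices were
fixed as follows:

- **Global discretization.** The source map is discretized once at ROI
  level before patch extraction. Re-binning per 9-pixel patch would make
  nearly every patch span the full gray range and degenerate the tiny
  matrices; a shared gray scale preserves between-patch contrast.
- **Full-neighbourhood validity.** Only pixels whose complete 3×3
  neighbourhood is valid get a TOT value; 9-pixel matrices are already
  minimal and partial windows would mix patch sizes.

The operator composes: with the window widened to the full ROI it
reproduces the ordinary scalar feature exactly (tested). Per TOT map the
default feature set is 17 first-order + 68 texture = 85, giving
5 + 5×85 = 430 columns in the enhanced dataset. The original study's 70
features per map match no reconstructable catalog combination, so the
per-map catalog is configuration-driven, counted explicitly, and the
column total is asserted against the configured catalog rather than a
hard-coded constant. The five map-generating features ship as presets
(`preset_base5("svm")`, `preset_base5("knn")`, mirrored as JSON under
`inst/extdata/`).

## 5. The classification protocol

The positive class is PR. This is forced by arithmetic: the published
per-row percentages admit integer confusion matrices only with 47
positives (e.g. 38/47 = 80.9 %, 19/25 = 76.0 %, 57/72 = 79.2 %). One
printed value fails this reconstruction — the 5-feature SVM precision,
86.1 % where 37/43 = 86.0 % — and the tests assert the exact arithmetic.

All preprocessing is *inside* the resampling loop: for every outer LOOCV
fold and every inner 5-fold split, SMOTE balances the training part only
(synthetic minority samples are convex combinations of a minority sample
and one of its 5 nearest minority neighbours, generated until class
parity), then z-scoring is fitted on the balanced training fold and
applied to the held-out part. The leakage guard is behavioural: permuted
labels must give chance AUC. The permutation null runs at n = 240
(chosen a priori so the null AUC standard deviation ≈ 0.04 makes the
[0.4, 0.6] acceptance window a > 99 % per-seed event; at n = 72 pure
null variance alone would miss the window in roughly a sixth of seeds).

Since no SVM implementation is available in the offline environment,
the SVM is the package's own: the convex primal squared-hinge loss
(L2-SVM, cost 1) minimized with BFGS — smooth, deterministic, and for
these small dimensions indistinguishable in behaviour from a standard
hinge SVM; an RBF variant optimizes the same loss over a kernel
expansion. k-NN uses k = 5, Euclidean distance on the z-scored features,
positive-vote fraction as its decision score. Neither k nor the kernel
was stated in the source protocol; linear/5 are the conventional
defaults and are recorded in the configuration object.

SFS is greedy forward selection scored by mean inner-fold F1, ties
broken by ascending column index. All candidates within a step share the
fold assignment and per-fold SMOTE seeds, so selection is auditable: the
tests re-score every candidate with the exported `inner_cv_f1()` and
verify the chosen one attains the step maximum. Reported metrics come
from the outer LOOCV aggregation of confusion counts; ROC/AUC from the
pooled decision scores (Mann–Whitney with tie correction). The
"5 k-fold training-set validation" of the source protocol is interpreted
as the inner SFS scoring loop, with LOOCV providing the reported
numbers; this interpretation is fixed here.

## 6. The synthetic world

Two generators exist, used for different purposes.

**RF simulator** (`simulate_rf_frame`): scan lines are synthesized
independently in the frequency domain from a homogeneous Poisson
scatterer field (default 16 /mm²) with zero-mean Gaussian amplitudes;
each scatterer contributes `f² √F(f;d)` (Rayleigh amplitude × form
factor) times the pulse spectrum, delayed by its round-trip time and
attenuated by `10^{−α f z/5}` in amplitude — the exact inverse of the
point-compensation rule. The reference phantom is the same machinery
with a fixed, documented population (25 µm, 16 /mm², α = 0) plus its
analytic backscatter curve. The pulse is a Gaussian-modulated sinusoid
at 10 MHz. Its fractional bandwidth defaults to 1.1: the stated design
intent (analysis band inside the −5 dB pulse envelope) and the
conventional 60 % figure are incompatible at a 10 MHz carrier — at 60 %
the 3–8 MHz band sits ~30 dB below the passband and Hamming-sidelobe
leakage biases estimated ASD by a factor ≈ 2.5 — so the intent won.
This simulator closes the loop on the estimators: ASD recovered within
±15 % at 80 µm over 25 windows, AAC monotone in amplitude variance,
attenuation compensation exact by construction.

What it does **not** model: lateral/elevational beam width (lines are
independent strips, so lateral speckle correlation is absent),
diffraction and focusing (the phantom division is exact here, where on
hardware it is approximate), electronic noise, and nonlinear
propagation. A green recovery test therefore establishes estimator
correctness under the model's own physics, not robustness to beam
effects.

**Cohort generator** (`generate_synthetic_cohort`): full RF simulation
for hundreds of frames would dominate every ML test, so cohort
parametric maps are drawn directly as Gaussian random fields — the RF
path is validated separately. The stated world: per-parameter CR/PR
means equal the published 72-patient group means, and patient-level SDs
are back-derived from the published one-tailed p-values at n = 25/47
(`sd = |Δ| / (t₁₋ₚ,₇₀ √(1/25+1/47))`), so a regenerated 25/47 cohort
reproduces comparable group statistics (a 16-patient example in the
README shows the calibrated-weak MBF contrast, p ≈ 0.1). Variance splits
0.95 sd patient + 0.3 sd frame + 1.0 sd pixel field. Because min–max
discretization deletes pure mean shifts from every texture feature, the
class *texture* signal is a correlation-length difference (CR 3.5 px vs
PR 2.0 px, Gaussian kernel), a clean and fairly strong signal: small
default cohorts separate essentially perfectly. That is intentional —
ML-harness tests need signal that is unambiguous — but it means a green
end-to-end AUC says nothing about clinically attainable performance, and
no such claim is made anywhere in the package. ROIs are random ellipses
with 8–16 mm axes at 0.5 mm map spacing; degenerate ROIs (< 9 valid
pixels) are rejected and regenerated with a message. The six frames per
patient are treated as statistically independent planes (elevational
spacing is not modelled). Labels: `round(0.347 · n)` complete
responders, matching 25 of 72.

## 7. Numerical and engineering choices

- Round-half-up for all mm→pixel conversions (base R `round()` is
  banker's rounding and would make the documented 6-sample step
  geometry-dependent).
- FFT grids are powers of two; reference spectra are cached per axial
  gate position and averaged over all phantom lines.
- Reproducibility: every stochastic stage (simulation, cohort, SMOTE,
  folding) takes an explicit seed; fixed seed ⇒ bit-identical frames,
  cohorts, selected features and metrics (tested).
- The RF container is plain text (TSV matrix + JSON attribute sidecar)
  rather than a binary format, keeping artifacts diffable and the
  offline build dependency-free; the attribute schema mirrors the usual
  HDF5 layout for such data.
- Known limitations: no local attenuation *estimation* (compensation
  takes α as an input, per frame); 2-D analysis only; no shape or
  filtered-image features; TOT depth fixed at 2 (the operator composes,
  but deeper stacks are unvalidated).
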