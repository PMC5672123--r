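---
title: "Spectral fingerprinting pipelines: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral fingerprinting pipelines: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(authentispec)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which parameters matter, what the synthetic
generator does and does not emulate, and where the design was genuinely open.

## The problem

A fingerprint spectrum — ATR mid-infrared absorbance, near-infrared
reflectance, or a binned ¹H-NMR spectrum of an extract — is a vector of
hundreds to tens of thousands of correlated intensities per sample. The
classification questions are binary: does a coffee sample belong to
*C. arabica* or *C. robusta* (easy; strong chemical differences such as the
diterpene Kahweol, essentially absent from Robusta), and does an Arabica
sample come from Colombia or from a neighbouring producer (hard; small
compositional shifts). With far more variables than samples, supervised
latent-variable classifiers can always separate the training data, so the
scientific content of any such analysis lives in its validation battery, not
in the fit.

## Preprocessing chains

Each technique gets its own ordered chain, assembled from primitive steps.
All region operations use one interval convention, left-closed right-open
`[lo, hi)` on the increasing axis; it reproduces the standard grid
arithmetic exactly (the 4000–10000 cm⁻¹ NIR grid at 4 cm⁻¹ has 1500 points
and its 4000–7600 cm⁻¹ selection 900).

* **ATR-mIR**: select 800–1800 cm⁻¹ (the fingerprint + carbonyl region), SG
  smoothing, SG second derivative, integral normalisation to 100, autoscale.
* **NIR**: select 4000–7600 cm⁻¹, SG second derivative, MSC against the
  training-mean reference, one OSC component, autoscale.
* **NMR**: remove the TMS (−0.2–0.2 ppm) and methanol (3.14–3.55 ppm)
  windows, select 0.5–9.5 ppm, bin to 1100 points, autoscale — no
  normalisation, because extracts measured at fixed receiver gain carry no
  multiplicative scatter to correct.

The Savitzky–Golay filter is a sliding least-squares polynomial fit
(`signal::sgolayfilt` supplies the kernel); derivatives are scaled by the
axis step so a second derivative has units of intensity per axis-unit².
A symmetric kernel needs an odd window; the conventional "window of 10
points" is therefore realised as window 11 with a third-degree polynomial.
Edge points are fitted with asymmetric windows so the output keeps the input
length. MSC regresses each spectrum on a reference by ordinary least squares
and inverts the fitted affine distortion; the reference defaults to the
training-partition mean and is stored, so test spectra are corrected against
the *training* reference. Binning sums intensities over equal-width
intervals (conserving the total exactly) and is how an 80501-point NMR
spectrum becomes the standard 1100-point fingerprint. "Total integral" is
taken as the sum of absolute intensities, which keeps the operation defined
for derivative spectra. The chain order here
(correction → normalisation → scaling) is the conventional one, with every
other order expressible through `preprocess_chain()`.

Every step with cohort-estimated state — the MSC reference, the OSC filter,
the autoscaler — is fitted inside `fit_chain()` on the training partition
only and replayed by `apply_chain()`. Cross-validation therefore never leaks
test information through the preprocessing; refitting these states per fold
is the conservative choice — a pipeline that fits them once globally can
only make its validated figures optimistic by comparison. Zero-variance variables at scaling time (e.g.
bins inside a removed solvent window) are dropped with a warning rather than
imputed, since 0/0 has no defensible value.

## Orthogonal signal correction

OSC removes from the spectra the structured variation that is orthogonal to
the class response before the classifier sees it. The defining optimisation
— find the score `t` in the column space of the centered training matrix
maximising explained variance subject to `t'y = 0` — is solved directly:
with `U` an orthonormal basis of the numerical column space (singular values
above `tol` relative) and `B` the part of `U` orthogonal to `y`, the score
is the top eigenvector of `B'XX'B`. The weight vector is recovered through
the retained-subspace pseudo-inverse so that `X_train w = t` holds exactly,
which makes `apply_osc()` reproduce the training deflation bit-for-bit and
renders a second application a no-op. The classical fixed-point iteration
(orthogonalise the score, regress, re-project) aims at the same solution but
its fixed point is not guaranteed orthogonal to `y`; solving the eigenproblem
removes both that failure mode and any iteration-count parameter. One
component is removed by default — the filter is conventionally applied once —
and the filter refuses fewer than three training samples. If the only
structure in `X` follows `y` (no orthogonal variation), the component is
null and nothing is removed.

## Quality control

PCA (via `stats::prcomp`, centered, unscaled, largest-|loading| entry of
each component made positive) feeds a per-group Hotelling *T²* statistic on
the first two components, `T²ᵢ = Σₐ t²ᵢₐ/λₐ`, with the 95% limit in its
F-distribution form. "95% of the T² distribution" is interpreted as this
conventional chemometric control ellipse; for large *n* it converges to the
χ²(2) limit (≈5.99). Rejection is a single pass per species and technique —
no refitting after removal — matching the narrative of a one-shot data
quality check. QC runs on the chain output restricted to *per-sample* steps
(region operations, SG, integral normalisation, binning): MSC, OSC and
autoscaling are excluded because their state is estimated from the whole
cohort, and a gross outlier would contaminate that state before being
caught — a contaminated MSC mean reference provably masks exactly the
artifacts QC exists to find. The QC input is configurable: `reject_outliers()` accepts whatever stage of
the chain the analyst hands it.

## Classifiers

Both families regress the coded response (+1 positive class, −1 negative;
decision threshold 0, exact ties to the negative class) on the preprocessed
spectra. PLS-DA is NIPALS PLS1 with sequential deflation; for a single
response each component is closed-form (`w ∝ X'y`), so the fit is
deterministic without convergence parameters. Predictions use the regression
vector `b = W(P'W)⁻¹q` and agree with the sequential-deflation route to
1e-10, a tested invariant. oPLS-DA extracts `n_orth` components whose
loadings are orthogonalised against the predictive direction, deflates them,
then fits one predictive component; its orthogonal scores are orthogonal to
`y` by construction, and with zero orthogonal components it reduces exactly
to one-component PLS-DA. Model complexity is parameterised on one axis:
complexity *k* means *k* predictive components (PLS) or 1 predictive +
(k−1) orthogonal (oPLS), so the two families share the Q²-versus-complexity
curve. No component count is hard-coded; `component_curve()` flags the first
local optimum of the validated curve, past which the additional components
chase training noise.

For loading-stability analysis the "first loading" of either family is the
loading of the response-correlated direction on the *undeflated* training
matrix (for PLS this is literally the first loading; for oPLS the orthogonal
deflation leaves the predictive weight unchanged, so this is the comparable
quantity). The post-deflation predictive loading depends on how many
orthogonal components were removed and is noticeably less stable across
resamplings, which would conflate model parameterisation with the chemical
question the stability analysis asks.

## Validation battery

`stratified_kfold()` deals each class round-robin into folds (class counts
within one of proportional allocation, folds partitioning the samples);
`monte_carlo_splits()` draws repeated independent stratified splits, 100
models by default with test fraction 1/7, chosen to match 7-fold
granularity. Q² is computed
per Eq. form `1 − PRESS/TSS` with the mean taken over the *test* samples of
the split. With ±1 coding and stratification that mean is near zero, which
is what makes Q² comparable across splits and to the pooled ROC. Pooled ROC
concatenates all test-set scores into one vector; the AUC is the trapezoidal
integral and equals the tie-corrected Mann–Whitney concordance — a tested
1e-12 invariant. Per-split AUCs feed box-plot quartiles; splits whose test
set contains one class are recorded as missing with a warning.
`loadings_stability()` sign-aligns each split's first loading to the first
split (maximising the inner product — without alignment the sd/mean of a
sign-ambiguous quantity is meaningless), sorts positions by decreasing mean
magnitude, and reports sd/|mean| per position, flagging positions below
1e-3 of the maximum as noise-level, where wild relative errors are expected
and irrelevant.

For the species task only a balanced subsample (19 per class with the
standard cohort) is modelled, preventing the majority class from dominating;
the subsample is drawn once per run seed rather than per split — the
alternative was equally defensible but would entangle subsampling noise with
split noise in the Q² spread.

## The synthetic suite

`generate_dataset()` realises a documented generative model: per-sample
spectra are a peak mixture (Gaussian or Lorentzian) with class-dependent
amplitudes, multiplied by a per-sample scatter slope, plus a random cubic
baseline, a fixed smooth confounder pattern loaded independently of class,
an additive offset and i.i.d. noise. All randomness flows from one integer
seed through an isolated RNG state; identical configs are bit-reproducible
and the global RNG is untouched.

`generate_coffee_suite()` instantiates one 97-sample cohort (75 Arabica — 34
Colombian — and 22 Robusta, with per-country counts matching the standard
collection) on the three instrument grids: 650–4000 cm⁻¹ at 0.96 cm⁻¹,
4000–10000 cm⁻¹ at 4 cm⁻¹, and a dense 80501-point 0.5–9.5 ppm grid that the
chain bins to 1100 points. Species information sits on a few strong peaks
(amplitude factors 2.2–3, including Kahweol-like NMR signals at
5.8/6.2/6.3/7.3 ppm), origin information on smaller factors (1.25 mIR, 1.10
NMR, 1.04 NIR). These effect sizes are free choices, calibrated once so that
the suite reproduces the qualitative pattern the pipeline is meant to
resolve: species discrimination essentially perfect for all techniques,
origin discrimination moderate and comparable for mIR and NMR, and clearly
weakest for NIR. Noise scales are technique-typical: strong multiplicative
scatter for the IR techniques (which their chains must remove), almost none
for NMR of standardised extracts (which is why the NMR chain applies no
normalisation). Twelve designated cohort members (9 Arabica, 3 Robusta; 2
affecting mIR, 5 NIR, 5 NMR) are corrupted the way bad acquisitions are:
narrow artifact peaks at instrument-characteristic positions, around eight
times the spectrum maximum, with random amplitude. A shared artifact
signature is what makes single-pass two-component T² QC able to catch them;
pure intensity scaling would be erased by integral normalisation and MSC
before QC ever saw it.

What the generator does **not** emulate: real chemical co-variation between
compounds, J-coupling multiplets, peak-position jitter (the usual motivation
for binning), instrument line-shape functions, or heteroscedastic noise.
Passing tests on this suite therefore demonstrate that the pipeline's
statistics behave as designed under a known truth — recovery of planted
effects, calibrated false-rejection rates, honest null behaviour — not that
any particular real dataset will reach the same figures.

## Numerical choices and degenerate inputs

Convergence-free algorithms were preferred throughout (closed-form NIPALS
PLS1, eigenproblem OSC, F-quantile thresholds). Rank deficiencies raise
errors naming the usable maximum; zero-variance QC groups raise errors
rather than producing zero-division statistics; all-zero spectra cannot be
integral-normalised and say which sample is at fault. Problem sizes in the
test suite are chosen small (tens of samples, hundreds of variables, a
reduced 8051-point NMR grid where the full density adds nothing to the
property under test); the acceptance script runs the full-density suite.

## Known limitations

Only two-class problems are in scope (PLS1, not PLS2; no multiclass DA).
JCAMP-DX support covers plain-numeric (AFFN) data, not compressed encodings.
The Hotelling limit uses the F-form ellipse rather than leverage/residual
(Q-statistic) diagnostics, so outliers orthogonal to the first two
components are invisible to QC — the planted artifacts are constructed to be
visible for exactly this reason, and real pipelines may want a residual
statistic as well. Variable selection (VIP), probabilistic quotient
normalisation and Pareto/vast scaling are not implemented.
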