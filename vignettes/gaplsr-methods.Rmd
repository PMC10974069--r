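---
title: "Methods: indirect soil heavy-metal estimation from leaf spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indirect soil heavy-metal estimation from leaf spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Heavy metals (here cadmium and arsenic) that accumulate in paddy soil are
taken up by rice and impair the plant — most visibly through reduced
chlorophyll and damaged leaf structure. Those physiological changes leave a
signature in the leaf reflectance spectrum, which opens an *indirect* route
to soil contamination mapping: measure leaf spectra in the field, calibrate a
regression from spectra to laboratory-measured soil concentrations, and use
the model where only spectra are available. `gaplsr` implements that
pipeline — spectral pre-processing, genetic-algorithm (GA) wavelength
selection, partial least squares regression (PLSR), and RPD-based model
assessment — together with a synthetic cohort generator so that every stage
is testable without access to field data.

## The synthetic cohort: a stated world

The generator emulates a small field campaign: 22 sites, leaf spectra on a
301–1145 nm grid at 3.3 nm resolution, soil Cd between 0.13 and 0.97 mg/kg
(mean 0.29), soil As between 3.23 and 9.32 mg/kg (mean 5.64), a Cd–As
Pearson correlation of 0.33, and mean soil pH 5.86. Those numbers are the
generator's *defaults*, not free dials; the test suite asserts that large
cohorts recover them.

**Metal marginals.** Concentrations are positive and right-skewed (the Cd
max/mean ratio is ≈ 3.3), so each metal is drawn from a truncated log-normal.
Only a mean and a range are stated, which under-determines the two
parameters; we read the range as the 0.5th/99.5th percentile pair of the
untruncated log-normal (fixing σ) and then solve μ by root finding so that
the mean of the range-truncated distribution matches the stated mean exactly
(closed-form truncated log-normal moments). Infeasible requests (mean outside
the range) are rejected.

**Dependence.** The two marginals are coupled by a Gaussian copula. Because
a copula correlation is not a Pearson correlation of the outputs, the latent
ρ is found by numerically inverting the map ρ → cor(Cd, As), evaluated by
48-node tensor Gauss–Hermite quadrature — fully deterministic, so the
calibration is identical for every seed.

**pH.** Only the mean (5.86) is stated. We use a normal with sd 0.35
truncated symmetrically to 5.86 ± 1.4 — a plausible paddy-soil range — so
the truncated mean is exactly the stated mean. pH is independent of the
metals and is never used as a predictor.

**Spectra.** Each leaf spectrum is a deterministic vegetation curve —
Gaussian absorption wells at 450 and 670 nm (chlorophyll), a green
reflectance peak at 550 nm, a logistic red edge near 718 nm, and a flat NIR
plateau near 0.48 — plus three stochastic layers: per-spectrum affine
scatter (gain sd 0.03, offset sd 0.01 reflectance units), i.i.d. channel
noise (sd 0.002), and noise on the stress indices below. Reflectance is
clipped to (1e-4, 1].

**Stress model (a deliberate design choice).** Metal stress enters through
two quasi-independent pathways: Cd (slope 0.5 per mg/kg on centred Cd, noise
sd 0.02) linearly shallows the two chlorophyll wells, and As (slope 0.04 per
mg/kg on centred As, noise sd 0.02) linearly depresses the NIR plateau. A
single shared stress index driving only the chlorophyll wells would be
simpler, but it provably caps how well *both* metals can be estimated: the
spectra would carry information about (Cd, As) only through one scalar, so
each metal's population R² could not exceed its squared correlation with
that scalar — about 0.66 under the stated marginals, i.e. RPD ≈ 1.7, well
below the ≈ 2–3 regime the pipeline is meant to exercise. Two pathways keep
every stated behaviour (the 670 nm well responds monotonically to Cd; zero
slopes and zero noise give identical spectra) while making both metals
separately recoverable. The slopes are fixed once, before any acceptance
measurement, and are not tuned against test outcomes.

**What the generator does not emulate.** No radiative-transfer leaf optics
(PROSPECT-class), no spatial autocorrelation between sites, no
within-site replicate structure, no wavelength-dependent instrument noise.
A green test therefore establishes that the *pipeline machinery* behaves as
specified on data with the stated statistical structure — not that field
spectra of real rice would reach any particular accuracy.

## Pre-processing

The order is fixed: strip channels below 380 nm (noisy spectrometer edge),
Savitzky–Golay smooth, then transform. Permuting trim and smooth changes the
values near the cut — a test enforces the order.

- **Savitzky–Golay**: window 11 channels, polynomial order 2 — a
  conventional mild smoother at 3.3 nm spacing (the method is named in the
  source protocol without parameters; both are configurable). Edge channels
  are fitted on the truncated window so the grid length is preserved.
- **AT**: absorbance, log10(1/R).
- **FD/SD**: first/second derivatives w.r.t. wavelength using central
  differences over the grid's actual spacing, one-sided at the two edges
  (the gap-free grid simplifies GA indexing; an edge-dropping variant is
  available). The second derivative uses the slope-difference form, which is
  exactly zero on constants and exact for quadratics on non-uniform grids.
- **AFD/ASD**: derivative after absorbance, per the transform names.
- **MSC**: each spectrum is regressed on (1, reference) and the affine fit
  inverted. The reference is the *modeling-set* mean, stored and reused for
  validation spectra — the reference choice is otherwise a leakage channel.
- **SNV**: per-spectrum standardization (sd with n−1).

## PLSR core

PLS1 via NIPALS with X-deflation on autoscaled data (centre + unit variance
for X columns and y; the chemometrics default, and the only sensible common
scale across transforms whose magnitudes differ by orders). Zero-variance
channels (which SNV/MSC can create) are dropped with a warning and get zero
coefficients. The regression vector is back-transformed so prediction maps a
raw spectrum to a raw concentration.

Component choice uses cross-validation — leave-one-out by default, because
the modeling set has 17 samples and LOO is deterministic (k-fold is
available). For each component count the model is refit on every training
fold and all held-out predictions are pooled; RMSEcv is the pooled root mean
squared error and R²cv is 1 − SSE_pooled/SST (the pooled rather than
per-fold-averaged convention — an explicit assumption). The chosen count is
the *first* minimizer of RMSEcv (parsimony on ties), with a default cap of
min(10, n − 2).

The per-fold CV engine is compiled (RcppArmadillo) because the GA evaluates
tens of thousands of cross-validations per run; an independent R-level
route (repeated `fit_plsr` refits) and an external scikit-learn oracle are
both tested against it, so correctness never rests on one code path.

## GA wavelength selection

Binary chromosomes over channels (a variable-cardinality mask — reported
selected-band counts vary, which rules out a fixed-size subset encoding).
Fitness is the cross-validated PLSR RMSEcv on the masked channels, with the
component count re-optimized inside each evaluation; lower is fitter. The
defaults are population 40, crossover probability 0.5, per-gene mutation
0.01, 100 generations, with 10 independent restarts; the operators are
tournament selection (size 2), uniform crossover, and bit-flip mutation,
with one elite carried forward unchanged (so the best-fitness trace is
monotone). Initial masks include each channel with probability 0.10 (~23 of
232 channels, the scale of typically selected band counts); masks below
`min_bands = 2` get infinite fitness (initial ones are resampled instead).
Restarts are aggregated by best fitness; per-channel selection frequencies
are logged as the complementary view. The budget is a fixed 100 generations
— no early stopping — so runs are exactly reproducible from the seed.

## Evaluation

Samples sorted by site id are split one-in-four: every 4th sample validates
(22 → 17 + 5). External validation uses models refit on the modeling set
only; a test perturbs validation responses and spectra and asserts that
masks, component counts and CV metrics do not move. RPD is
sd(observed validation)/RMSEev (the standard Williams definition — the name
alone does not pin a formula) on the five-level scale: ≤ 1.50 poor;
(1.50, 2.00] distinguishes high/low; (2.00, 2.50] approximate quantitative;
(2.50, 3.00] good; > 3.00 excellent. Printed ranges like "2.00 to 2.50" are
implemented half-open so every positive RPD maps to one tier. R²ev is
1 − SSE/SST rather than squared Pearson correlation (consistent with the
RMSE-based reporting; also an explicit assumption).

## Reproducibility and budgets

One root seed governs a run; stages derive sub-seeds by a stable string hash
of the stage name, and GA restarts use consecutive offsets. Identical
configurations give byte-identical reports (tested). The acceptance suite
scales two simulations down to stay within runtime budgets — the GA-vs-PLSR
majority comparison uses 2 GA restarts per seed instead of 10 (the claim
under test is the direction of the comparison, not its margin), and pipeline
unit tests use small GA populations; the full default sweep (8 transforms ×
2 metals, 10 restarts each) still runs end-to-end in the acceptance suite.

## Known limitations

- The generator's two-pathway stress model is a modelling convenience; real
  Cd/As stress physiology overlaps far more, and field accuracies will be
  lower than synthetic ones.
- With only 5 validation samples the external metrics are high-variance:
  across cohort seeds the full-band RPD typically spans ~1 to ~3.5 around
  the intended 2–3 regime, and single seeds can look much better or worse.
- In the synthetic world raw reflectance and scatter-corrected transforms
  often beat the derivative transforms (the planted signal is smooth and
  broad-band, and derivatives amplify channel noise), whereas field studies
  of this design typically favour derivative-of-absorbance spectra. Transform
  rankings on synthetic data say nothing about rankings on field data.
- Wrapper selection with n = 17 and LOO fitness can overfit the CV
  criterion; external-validation metrics in the reports are the honest
  check, and no guard beyond CV (e.g. randomization tests) is provided.
- The 0.5th/99.5th percentile reading of the metal ranges is one defensible
  convention; the published range/mean pair cannot identify the marginal
  uniquely.
- Exact channel counts are grid-derived (301 + 3.3k, trimmed at ≥ 380 nm →
  232 channels); sources quoting "230 bands" for this instrument cannot be
  reproduced exactly from the stated range and resolution.
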