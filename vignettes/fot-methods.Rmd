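---
title: "Methods: simulation and analysis of forced-oscillation lung-function tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of forced-oscillation lung-function tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscillab)
```

This vignette documents the models, parameter choices, and numerical
decisions behind `oscillab`. It deliberately states **no empirical results**
beyond what the package's test suite and `scripts/acceptance.R` compute at
run time; every quantitative claim made here is asserted there.

## 1. Forward models

Respiratory impedance is modelled with lumped mechanical elements
(pressure in cmH₂O, flow in L/s, so impedance is in cmH₂O/(L/s)):

* `pure_resistor`: Zrs(f) = R.
* `ric` (resistance–inertance–compliance in series):
  Zrs(f) = R + j(2πf·I − 1/(2πf·C)). Reactance is compliance-dominated
  (negative) at low frequency, inertance-dominated (positive) at high
  frequency, with resonance at fr = 1/(2π√(I·C)).
* `eric`: as `ric` but with a frequency-dependent resistance
  Re Zrs(f) = R + S·f. The slope `S` (cmH₂O/(L/s)/Hz) models the
  negative frequency dependence of resistance seen with ventilation
  heterogeneity; the simulated cohorts use this variant.
* `two_compartment`: two RIC branches in parallel,
  Zrs = (Z₁·Z₂)/(Z₁ + Z₂), for heterogeneity experiments.

Typical healthy-adult magnitudes anchor the defaults: R ≈ 2.8 cmH₂O/(L/s),
I ≈ 0.01 cmH₂O/(L/s²), C ≈ 0.02 L/cmH₂O, giving fr ≈ 11.3 Hz.

## 2. Excitation and disturbances

The excitation is a **multisine**: 15 components every 2 Hz from 4 to
32 Hz with seeded uniform random phases, rescaled to exactly 2 cmH₂O
peak-to-peak, sampled at fs = 1024 Hz for 16 s. All component frequencies
are integer multiples of fs/4096, i.e. they fall exactly on the FFT bins of
the analysis blocks — the generator refuses off-bin components
(`excitation_spec()`), which removes spectral leakage from the forward
path by construction.

Flow is synthesized per component as Q(f) = P(f)/Zrs(f) (exact phasor
inversion), so the noiseless record carries the model's impedance exactly.
Disturbances (`noise_spec()`) model a real exam:

* **spontaneous breathing** — a 0.25 Hz flow sinusoid of 0.4 L/s amplitude
  plus its Ohmic pressure response Re Zrs(f_b)·q_b; breathing lies far
  below the 4 Hz analysis band and is additionally suppressed by per-block
  detrending;
* **sensor noise** — white Gaussian noise on pressure (sd 0.02 cmH₂O) and
  flow (sd 0.01 L/s), a few-percent perturbation relative to the ~1 cmH₂O
  oscillation amplitude, calibrated so that default exams pass the γ² ≥ 0.9
  gate while noise remains visible in the estimates.

## 3. Cohort generator calibration

`default_groups()` defines three groups mimicking a cross-sectional study
design: healthy controls (n = 23), patients with normal spirometry
("NE", n = 21) and patients with abnormal/restrictive spirometry
("AE", n = 24), three exams per subject (204 records). Subject parameters
are drawn from truncated normal distributions:

| group | R (mean ± sd) | S | C | I |
|---|---|---|---|---|
| control | 2.77 ± 0.23 | −0.020 ± 0.010 | 0.020 ± 0.003 | 0.010 ± 0.001 |
| NE | 2.95 ± 0.35 | −0.045 ± 0.015 | 0.016 ± 0.003 | 0.010 ± 0.001 |
| AE | 3.91 ± 0.57 | −0.080 ± 0.020 | 0.011 ± 0.002 | 0.010 ± 0.001 |

The control and AE resistance distributions are typical published values
for healthy adults and restrictive disease; the remaining moments are
plausibility choices that produce the expected clinical ordering (higher
resistance, more negative slope, lower compliance, higher resonance
frequency with disease) with realistic group overlap — they are **study
conditions**, fixed before any accuracy evaluation, not tuned quantities.
Truncation (R > 0.1, C > 0.001, I ≥ 0, R + 32·S > 0.1) merely excludes
physically meaningless draws. Seeds are derived per subject and exam from
one master seed (`derive_seed()`), so any record can be regenerated in
isolation.

## 4. Impedance estimation and quality control

`welch_cross_spectra()` implements Welch's method: 4096-sample blocks
(4 s, Δf = 0.25 Hz) at 50 % overlap — exactly 7 blocks per 16 s record —
with a Hann taper and per-block linear detrend by default. The estimator is
the flow-referenced transfer function

Zrs(f) = G_pq(f) / G_qq(f),  γ²(f) = |G_pq|² / (G_pp·G_qq),

with G's averaged over blocks. γ² is clamped to [0, 1] against rounding.
An exam passes QC only if **all 15 components** have γ² ≥ 0.9 (inclusive
at the threshold); per-component flags are kept for diagnostics. Subject
impedance is the complex mean over the passing exams among the three.

**Numerical choice.** The per-block linear detrend slightly perturbs
bin-aligned sinusoids (relative error ~10⁻⁵ on noiseless records) because a
fitted trend is not orthogonal to the sinusoids over a finite block. This
is irrelevant at realistic noise levels but matters for exact oracle
tests, so `window_spec(taper = "rectangular", detrend = "none")` is
provided: with it, noiseless bin-aligned records invert to the forward
model to better than 10⁻⁶ (asserted in the acceptance tests). The default
(Hann + linear detrend) is kept for noisy data, where it suppresses
breathing leakage and block-level drift.

## 5. Oscillometry parameters

From the QC-passed, exam-averaged spectrum:

* `r0`, `s`: ordinary least squares of Re Zrs on frequency over 4–16 Hz;
* `rm`: mean Re Zrs over 4–16 Hz; `r4`: Re Zrs(4);
* `xm`: mean Im Zrs over the full measured band 4–32 Hz (the band where
  reactance information exists in the excitation);
* `fr`: linear interpolation of the first negative-to-positive zero
  crossing of Im Zrs. If reactance never turns positive by 32 Hz, fr is
  linearly extrapolated from the last segment and flagged
  (`fr_extrapolated`); extrapolation can be disabled.
* `cdyn`: −1/(2π·4·X(4)), defined only when X(4) < 0 (`cdyn_defined`);
* `z4`: √(R4² + X(4)²).

## 6. Statistics

Group comparisons gate on per-group Shapiro–Wilk normality (α = 0.05):
ANOVA with Tukey HSD when all groups pass, otherwise Kruskal–Wallis with
pairwise Mann–Whitney tests (raw p-values). Significance is inclusive at
p ≤ 0.05. Correlation analysis gates Pearson vs Spearman the same way and
labels |r| with conventional bands closed on the lower edge of the higher
band (0.25 reasonable, 0.50 moderate-to-good, 0.75 very-good-to-excellent).
For a family of correlations between m oscillometry variables and k
comparator variables, the modified Bonferroni level is α/(m·k) — e.g.
0.05/8, reported rounded half-up to 4 decimals as 0.0063.

## 7. ROC analysis and the Hanley–McNeil calculations

The AUC is the Mann–Whitney pair-counting statistic with midranks (ties
count ½), which equals the trapezoidal area under the empirical ROC
exactly. Curves auto-orient so AUC ≥ 0.5 unless the score's direction is
fixed by construction (`orient = FALSE`, used for cross-validated
classifier scores, where auto-orientation would bias a null AUC upward).
The Youden-optimal cut-off breaks ties toward higher specificity and then
the lower threshold — ranked on **exact integer pair counts**
(tp·n₋ − fp·n₊), since floating-point Se/Sp arithmetic can order exact
ties by rounding noise — and is reported as the midpoint between adjacent
observed scores. AUC bands: ≥ 0.70 moderate, ≥ 0.90 high (left-closed);
≥ 0.75 is flagged adequate for clinical use.

The Hanley–McNeil standard error uses Q₁ = A/(2−A), Q₂ = 2A²/(1+A) with
the finite-sample (n−1) weights. The **minimum sample size** iterates n
upward until δ = A₁ − A₀ satisfies

δ ≥ z_α·√(v(A₀)/n) + z_β·√(v(A₁)/n),  v(A) = Q₁ + Q₂ − 2A²,

i.e. the classical asymptotic per-observation variance kernel. With the
finite-(n−1) variance instead, the same design (0.75 vs 0.5, two-sided
α = β = 0.10) yields 21 rather than 20 per group; the kernel form is the
standard planning formula and is the package's canonical choice, with both
one- and two-sided conventions exposed (`hanley_mcneil_sample_sizes()`).

## 8. Decision support

Six classifiers are available behind one interface: a hand-written
log-space **Parzen** kernel-Bayes classifier (Gaussian product kernel,
per-feature Silverman bandwidths fitted on the training fold), linear and
RBF **SVM** (`e1071`, decision values oriented by training-class means),
**k-NN** (k = 5), **random forest** (500 trees) and **AdaBoost** on
depth-1 `rpart` stumps (SAMME weighting, 100 rounds; hand-rolled because
no boosting package is a hard dependency). Features are z-scored inside
each training fold; no statistic of a test fold ever enters training.
Evaluation pools out-of-fold scores from stratified 10-fold CV or LOOCV
(the exact k = n limit) into a single fixed-orientation AUC with Youden
Se/Sp.

`exhaustive_search()` evaluates all non-empty subsets of up to 20
candidate features (255 subsets for the eight oscillometry parameters),
ordered by size and then lexicographically, with strict `>` for the
argmax so ties resolve to the smaller, earlier subset. **Caveat:** the
subset is selected on the same cross-validated scores it is judged by, so
the winning AUC carries optimistic selection bias; treat it as a
model-selection score, not an unbiased performance estimate.

## 9. Problem sizes and runtime

Default problem sizes: 68 subjects × 3 exams of 16 384 samples; Welch with
7 blocks of 4096; 255-subset exhaustive Parzen search with LOOCV over 47
subjects (AE vs control). The full pipeline (`run_pipeline(default_config())`)
runs in minutes on one CPU with bounded memory — records are synthesized
and reduced subject by subject and never all held at once.

## 10. Limitations

* The synthetic cohort is a calibrated *in silico* stand-in, not patient
  data; absolute accuracy figures describe the simulation, not any clinic.
* Breathing is a single sinusoid and sensor noise is white and Gaussian;
  real artefacts (glottis closure, leaks, nonstationary breathing) are out
  of scope.
* The forward models are linear and time-invariant; FOT nonlinearity at
  high excitation amplitudes is not modelled.
* `cdyn` is undefined at non-negative X(4), and `fr` beyond 32 Hz relies
  on flagged linear extrapolation.
* Cross-validated AUCs from the exhaustive search are model-selection
  scores (Section 8); an untouched validation cohort would be needed for
  unbiased accuracy claims.
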