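---
title: "SSVEP gain-control analysis for Drosophila disease models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSVEP gain-control analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the model

A contrast-reversing grating modulating at temporal frequency $f$ drives a
steady-state visually evoked potential (SSVEP) in the *Drosophila*
electroretinogram (ERG). Because each stimulus cycle contains two contrast
reversals, the neuronal population response concentrates at *even*
multiples of $f$, dominated by the second harmonic $2f$; a small residual
appears at the fundamental $F1$ from asymmetric photoreceptor sampling of
the grating. The response is phase-locked to the stimulus, so averaging
*complex* Fourier coefficients across repeats (coherent averaging)
preserves the evoked component while phase-random noise performs a 2-D
random walk whose expected averaged modulus shrinks as $1/\sqrt{K}$ over
$K$ trials.

The package analyzes (and simulates) a sweep over 8 temporal frequencies
$\times$ 8 Michelson contrasts = 64 conditions. Each fly is summarized by
its 64-vector of coherently averaged $2f$ amplitudes — its *response
profile* — which feeds three analyses:

1. **Gain-control statistics.** PCA of the $N \times 64$ profile matrix;
   a between-groups factorial ANOVA (genotype $\times$ age) on the first
   PC score; Sidak-corrected pairwise simple effects within strata.
2. **Classification.** A regularized linear discriminant over the raw
   64-dimensional profiles, with four accuracy estimators: leave-one-out,
   Monte Carlo resampling, N-way confusion matrices, and a bootstrap
   pairwise test with a significance rule.
3. **Simulation.** A generative ERG model whose cohort structure mirrors
   the study design (five genotypes, five ages, ten flies per cell, three
   repeats per condition), so the entire analysis path is testable
   end-to-end without any recordings.

# The synthetic ERG generator

No public dataset accompanies the study this pipeline reproduces, and no
generative waveform model is stated in it; the simulator is therefore the
package's own parametric embodiment of the qualitative facts the analysis
depends on. A trial of duration 11 s at `sample_rate` 720 Hz is

$$x(t) = \alpha A \sin(2\pi f t + \phi) +
  \sum_{h=1}^{H} A\, r^{\,h-1} \sin(2\pi\, 2hf\, t + \phi) + \varepsilon(t),$$

with $A$ the deterministic response amplitude, $r$ the even-harmonic
roll-off (default 0.3, $H = 4$ harmonics), $\alpha$ the $F1$ leak
fraction (default 0.2), $\phi$ the stimulus phase (shared by repeats of a
condition: the response is stimulus-locked), and $\varepsilon$ white
Gaussian noise (`noise_sd`, default 45 on the nominal µV scale) whose
spectrum has independent random phase per frequency — all the analysis
requires of "noise".

The amplitude surface is a Naka–Rushton contrast saturation crossed with
a log-Gaussian temporal tuning:

$$A(f, c) = A_0 \cdot g_{\text{age}} \cdot
  \frac{c^n}{c^n + c_{50}^n} \cdot
  \exp\!\left(-\frac{\log_2^2(f/f_p)}{2\sigma^2}\right) \cdot s,$$

chosen because it reproduces the published surface shape (peak response
at 99% contrast and 6–8 Hz). Defaults: $A_0 = 30$ µV, $c_{50} \approx$
22–28%, $n = 2$, $f_p \approx$ 6.5–8 Hz, $\sigma \approx 1.5$ octaves,
per genotype. The stress factor $s$ is 1 unstressed, or the phenotype's
`stress_attenuation` under photic stress.

**What the phenotype defaults encode** (the study conditions, fixed once):

* all three early-onset (EOPD) phenotypes have a **twofold day-1 gain**
  over control, the kinase-null does not;
* the **control gain doubles from day 1 to day 7** (visual maturation)
  and then holds;
* later-age gains are broadly comparable across genotypes but each
  genotype carries subtly different $c_{50}$, $f_p$ and gain
  trajectories — the "small but significant" profile differences the
  classifier exploits;
* under photic stress the disease phenotypes attenuate to 0.35–0.45 of
  their unstressed amplitude (at least a 50% reduction), the kinase-null
  to 0.45, and the control is spared.

Between-fly variability is a lognormal multiplicative gain jitter
($\sigma = 0.25$ on the log scale), a conventional choice for
positive-valued physiological gains; the study itself is silent on
between-fly variance structure. Every fly derives its own RNG stream from
the design's root seed, so any fly is exactly reproducible in isolation
and cohorts are byte-identical across runs.

**What the simulator does *not* emulate:** onset transients beyond a
discardable first second, the 4-s inter-stimulus interval, 1/f or
artifactual noise, photoreceptor biophysics, and any genotype differences
beyond the parametric surface. Passing tests therefore demonstrate that
the *analysis machinery* is correct and calibrated — not that real ERGs
follow a Naka–Rushton $\times$ log-Gaussian model.

# Spectral conventions and numerical choices

* **Window**: the first second of each 11-s trial is discarded (onset
  transients); the remaining 10 s give 0.1 Hz bins. Every stimulus
  frequency (1–36 Hz) and harmonic falls *exactly* on a bin, so a
  rectangular window is exact and tapering would only bias amplitudes.
  The sample rate (720 Hz) keeps the highest generated harmonic
  ($8 \times 36 = 288$ Hz) below Nyquist; violations are an error, not a
  warning.
* **Amplitude convention**: a pure sinusoid of peak amplitude $A$ yields
  a coefficient of modulus $A$ at its bin ($2|X_k|/N$). The DC bin (mean)
  is removed before transforming.
* **Profiles store amplitude only** (not power, not phase), in canonical
  grid order: frequency-major, ascending contrast within frequency —
  frozen in the CSV schema (`amp_f<F>_c<C>` columns, one schema header
  line) so the index $\leftrightarrow$ condition map round-trips.
* **Off-bin requests error** (naming the frequency and bin spacing)
  rather than silently picking the nearest bin.

The published protocol lists *seven* contrast values (1, 4, 8, 16, 32,
64, 99%) for an eight-level sweep; the default grid inserts 2% between
1% and 4% — approximately geometric spacing — to complete the eight
levels. The contrast list is an ordinary argument, so any other
completion can be substituted.

# Statistical choices

* **PCA** is computed on the covariance (centered, unscaled) matrix:
  profile entries share one unit, and correlation scaling would inflate
  the weight of noise-dominated low-contrast cells. All flies to be
  compared enter one decomposition so every score is scaled by the same
  eigenvectors. Loading signs are fixed deterministically
  (largest-magnitude element positive).
* **ANOVA** is the fixed-effects factorial model on the PC1 score, for
  *balanced* designs only — unbalanced input errors rather than silently
  switching to an approximate sum-of-squares decomposition. For the
  default 5 × 5 × 10 design the df are (4, 225), (4, 225), (16, 225).
* **Simple effects** compare all group pairs within each stratum using
  the pooled residual mean square of the full factorial model (the
  behaviour of standard statistical packages), with a Sidak family of
  $m = \binom{g}{2}$ comparisons per stratum — the conventional reading
  of "all possible comparisons within each age group".

# The classifier

With 64 features and ten flies per class, the pooled within-class
covariance is singular whenever $N - K < 64$, so regularization is not
optional. The model shrinks toward a scaled identity,
$S_\lambda = (1-\lambda)S + \lambda\,(\mathrm{tr}(S)/64)\,I$, with
$\lambda$ chosen by Ledoit–Wolf analytic shrinkage on the pooled
within-class residuals (`shrinkage = "auto"`, recorded in the fitted
model and all reports) or fixed by the user. Priors default to uniform,
matching the balanced design. Ties in the arg-max are broken toward the
lowest class index, deterministically. If the within-class variance is
exactly zero (possible in bootstrap resamples built from duplicated
flies), the covariance degenerates to the identity and the rule becomes
nearest-mean — the arg-max is invariant to the spherical scale.

The four accuracy procedures:

* **Leave-one-out**: deterministic; each fly predicted from the other
  $N-1$. A known property worth stating: on *structureless* data LOO is
  slightly pessimistic (here ≈ 17–18% against a 20% five-class chance
  baseline), because the left-out fly's own class mean is estimated from
  9 rather than 10 flies, inflating its penalty term in the
  discriminant. This is intrinsic to cross-validated discriminants in
  the $d \gg n$ regime, not a defect; the Monte Carlo estimator, whose
  holdout is disjoint from training with balanced classes, is unbiased
  at chance (4.0% for 25 null classes).
* **Monte Carlo**: stratified 80/20 splits (fraction configurable),
  default 1,000 iterations, fully seeded.
* **N-way confusion**: (true, predicted) pairs accumulated across LOO
  folds or Monte Carlo holdouts; rows normalized by per-class prediction
  counts, so the diagonal is the per-class N-way accuracy and rows sum
  to 1.
* **Pairwise bootstrap**: for each of 1,000 iterations, flies are
  resampled with replacement *within* each of the two classes, the model
  is fitted on the resample and scored on the out-of-bag flies (an
  iteration with an empty out-of-bag set is redrawn and counted).
  Significance: fewer than 5% of iteration accuracies at or below 0.5.
  The source description of this rule reads "0.5 or greater", which
  taken literally would declare *poor* classifiers significant; the
  package presumes a typo and tests the below-chance tail by default,
  but `criterion = "paper-wording"` applies the literal reading for
  anyone who wants it.

# Problem sizes used by the tests

The test-suite and the acceptance script run the full
simulate → extract → analyze path at the per-cell sizes of the study
design rather than the complete 250-fly sweep: the day-1 age cell
(5 genotypes × 10 flies) for gain-elevation, surface-shape, and
classification checks, and the matched day-7 stressed/unstressed pair
(2 × 50 flies) for the photic-stress contrast. The generative process is
identical cell by cell, so these runs exercise every code path at full
fidelity; chance-calibration checks use 100 null datasets (LOO) and 20
datasets × 1,000 Monte Carlo iterations. Noise-suppression and type-I
calibration use 1,000 replicates each.

# Known limitations

* The simulator's parametric surface is a modelling convenience; real
  ERG surfaces need not be separable in frequency and contrast, and real
  noise is neither white nor stationary.
* Photic stress is modeled as a pure endpoint attenuation at day 7, not
  a day-by-day trajectory — only the endpoint is measured.
* Ages outside the five defined days error rather than interpolate;
  age-gain interpolation would impose a trajectory the data do not
  constrain.
* Published real-data accuracies and F statistics are not reproduction
  targets: the original recordings were never deposited, and the
  simulator makes no claim to match their effect sizes beyond the
  encoded twofold day-1 elevation and ≥50% stress reduction.

# A worked example

```{r, eval = FALSE}
library(flyssvep)

grid <- build_stimulus_grid()                 # 8 x 8 = 64 conditions
design <- cohort_design(ages = 1, seed = 1)   # day-1 cell: 5 x 10 flies
cohort <- simulate_cohort(design, grid, materialize = FALSE)
profiles <- build_profiles(cohort, discard = 1)

pca <- pca_fit(profiles)
pca$variance_fraction[1]                      # PC1 variance share

amp <- profile_matrix(profiles)
loo_accuracy(amp, profiles$genotype)          # 5-genotype LOO accuracy
pairwise_bootstrap(amp, profiles$genotype, "control", "EOPD-C",
                   iterations = 1000, seed = 1)
```

Or, end to end with artifacts on disk:

```{r, eval = FALSE}
cfg <- run_config(ages = c(1, 7), flies_per_cell = 10, seed = 1)
res <- run_pipeline(cfg, "run1/")
res$manifest$n_flies
```
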