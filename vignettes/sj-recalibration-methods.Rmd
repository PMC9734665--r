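---
title: "Modelling simultaneity judgments and audiovisual temporal recalibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling simultaneity judgments and audiovisual temporal recalibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sjrecal)
```

## The task and the observer model

In an audiovisual simultaneity judgment (SJ) task an observer sees a flash
and hears a tone separated by a stimulus onset asynchrony (SOA, signed in
milliseconds; negative = auditory first) and reports "simultaneous" or
"asynchronous". Aggregated over repetitions, the proportion of
simultaneous responses traces a unimodal curve over SOA.

`sjrecal` models this curve with a two-criterion observer: the observer
holds a low criterion $C_{Low}$ (on the audio-lead side) and a high
criterion $C_{High}$ (on the visual-lead side) on the SOA axis and calls a
trial simultaneous when the perceived SOA falls between them. With each
criterion blurred by Gaussian noise with scales $\sigma_{Low}$,
$\sigma_{High}$, the response probability is a difference of two
cumulative Gaussians:

$$p(\text{simultaneous} \mid s) =
  \Phi\!\left(\frac{C_{High} - s}{\sigma_{High}}\right) -
  \Phi\!\left(\frac{C_{Low} - s}{\sigma_{Low}}\right).$$

Two summaries matter downstream:

* the **point of subjective simultaneity** (PSS), the criterion midpoint
  $(C_{High} + C_{Low})/2$ — positive values mean visual-lead SOAs look
  simultaneous more often;
* the **window of subjective simultaneity**, the criterion distance
  $C_{High} - C_{Low}$ — the width of the SOA range judged simultaneous.

When the two $\sigma$ differ, the raw difference of CDFs can dip slightly
below zero in one tail. All probabilities entering the likelihood are
clipped into $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$,
which also protects $\log(0)$.

The direction convention ($\Phi((C - s)/\sigma)$, high minus low) makes
the curve unimodal with its peak between the criteria and gives the PSS
its sign convention. The nested two-parameter null model is one monotone
cumulative Gaussian, written increasing in SOA,
$p = \Phi((s - C)/\sigma)$, so that its limits are 0 and 1 at the two
extremes; its mirror image fits identically, so the screen below does not
depend on this choice.

## Maximum-likelihood fitting

Responses are aggregated to per-SOA binomial counts (`binomial_cells()`),
and both models are fitted by maximizing the binomial log-likelihood
$\sum_i k_i \log p_i + (n_i - k_i)\log(1 - p_i)$. The additive binomial
coefficient is omitted everywhere; it cancels from every deviance
difference used. Per-trial Bernoulli and aggregated binomial likelihoods
have identical optima, so the choice only shifts log-likelihoods by a
constant.

Numerical choices, in full:

* **Parameterization.** $\theta = (C_{Low}, \log(C_{High} - C_{Low}),
  \log\sigma_{Low}, \log\sigma_{High})$, which enforces the criterion
  ordering and positive scales by construction.
* **Optimizer.** Bounded quasi-Newton (L-BFGS-B) with an analytic
  gradient, relative tolerance $10^{-8}$ on the objective, at most 500
  iterations per start. The box allows criteria within four SOA spans of
  the grid center and scales from span/100 to five spans: parameters
  beyond that are not identifiable from the sampled SOA range, and the
  box keeps the monotone model's flat large-$\sigma$ ridge from running
  to infinity. A fit on the box boundary is a legitimate constrained
  optimum and is reported as converged.
* **Multi-start.** Eight deterministic starts (criterion pairs at
  $\pm\tfrac13$ and $\pm\tfrac23$ of the SOA span; each $\sigma$ at
  $\tfrac14$ or $\tfrac12$ span) plus one moment-based start that treats
  the normalized response mass over SOA as a density. The best start wins
  and gets one polish restart with a fresh Hessian; ties keep the first.
  The four-parameter surface is multimodal on sparse data, and in
  validation the start set matches a 60-start random reference to within
  $10^{-4}$ log-likelihood units.
* **Degenerate data.** All-zero or all-$n$ counts cannot identify the
  model; the fit is returned flagged non-converged, never dropped
  silently.

## Deviance screening

Participants who cannot discriminate simultaneity should not contribute
PSS estimates. For each participant and condition cell the package fits
both models and computes the deviance difference
$\Delta D = D_2 - D_4$ (deviance $D = 2(\ell_{sat} - \ell)$). A
participant is retained only when $\Delta D$ exceeds the $\chi^2_2$
critical value (5.991 at $\alpha = 0.05$ — the conventional level; the
screen's definition does not state one) in **every** fitted cell. In the
2×2 design this package screens on all four (adaptation × congruency)
cells — the strictest reading of applying the same rule to each fitted
curve; screening only the two adaptation conditions after pooling
congruency would be more lenient for noisy incongruent cells.

A caution established by this package's own calibration runs: the
monotone null sits on the boundary of the four-parameter space
($C_{High} \to \infty$), so under a true monotone observer the
likelihood-ratio statistic is stochastically smaller than $\chi^2_2$ and
the screen rejects well below its nominal rate (0–2% measured at 1000
simulated null datasets of 20 trials per SOA). The screen is therefore
conservative in the *retain* direction for genuinely unimodal observers
and should be read as a coarse adequacy filter, not a calibrated test.

The alternative PSS analysis, `fit_scaled_gaussian()`, fits
$p = a\,e^{-(s-\mu)^2/2\tau^2}$ with $a \in (0,1]$ by the same binomial
ML machinery and reports $\mu$ as the PSS. It is implemented as the
standard three-parameter variant (amplitude free, location, scale); where
an original analysis fixed the amplitude or used least squares, results
may differ in the tails but the location estimate is robust to that
choice for near-symmetric data.

## The synthetic experiments

The generator emulates a two-condition adaptation/test design used to
study audiovisual temporal recalibration under pitch–elevation
correspondence:

* **Adaptors.** Trains of alternating 20 ms auditory (1000/4000 Hz) and
  visual (circles 3° below/above fixation) stimuli at exactly 200 ms
  spacing, cycling a four-stimulus pattern whose order makes the visual
  member of each pitch–elevation-congruent pair lead (visual-leading) or
  lag (auditory-leading). Initial adaptation runs 60 s (300 events); each
  top-up runs 5 s (25 events = 6.25 patterns). Because stimuli are
  equally spaced, the congruency-implied pairs have a fixed 200 ms
  intra-pair lag, which is the asynchrony the observer adapts to.
* **Test designs.** Design 1: 11 SOAs (±350, ±250, ±150, ±100, ±50,
  0 ms) × 2 congruent pairings × 2 adaptation conditions × 10 occasions =
  440 trials in 8 blocks of 55, conditions alternating every 2 blocks,
  one pairing per block. Design 2: wider grid (±400, ±320, ±240, ±160,
  ±80, 0 ms), all 4 pairings (2 congruent, 2 incongruent) randomized
  within block, 880 trials in 16 blocks, conditions alternating every 4
  blocks. Starting condition is counterbalanced by participant parity.
  Block structure is generated for schema fidelity; fitting pools over
  it. The 60 s stimulus-observation phase that precedes blocks in design
  2 is representable as an event timeline only and has no modeled
  behavioral effect.
* **Observers.** A simulated observer holds one parameter set per
  (condition, congruency) cell. Adaptation is an additive PSS shift
  applied to both criteria equally — the window is deliberately
  unaffected, mirroring the empirical null result for window effects.
  Whether recalibration moves one or both conditions is empirically
  unresolved, so the split of the total shift between conditions is an
  explicit parameter (`shift_split`, default symmetric).

Population defaults, chosen once as field-realistic values and used
everywhere: baseline criteria −213/+237 ms (PSS 12 ms, window 450 ms,
typical of group means reported in this paradigm), $\sigma = 90$ ms, condition shift
13.5 ms confined to congruent cells, between-participant baseline-PSS sd
30 ms, shift sd 18 ms. The shift sd was set so that, after adding the
per-condition fit noise at 20 trials per SOA (≈ 10 ms sd per condition),
the simulated paired effect lands near $d_z \approx 0.6$, the published
size. What the generator does **not** emulate: lapses and response
biases, serial dependence between trials, drift across blocks, or any
true window change — so passing tests demonstrate pipeline correctness
under the stated observer model, not robustness to those features of
real data.

## Group-level inference

PSS and window estimates feed standard paired-design statistics:

* `paired_t()` — two-tailed paired t with
  $d_z = \bar d / s_d$ ($s_d$ with the unbiased $n-1$ denominator).
* `rm_anova_2x2()` — each effect of the fully-within 2×2 design is a
  single-df paired contrast on difference scores, so $F = t^2$ on
  $(1, n-1)$ and partial $\eta^2 = F/(F + df_2)$. This is algebraically
  identical to the classical sphericity-free 2×2 within-subject ANOVA
  (cross-checked against `aov()` in the tests).
* `simple_main_effects()` — the per-level paired contrast with its own
  error term on $(1, n-1)$, not a pooled one; this choice reproduces the
  $(1, n-1)$ degrees of freedom convention of the contrast approach.
  With a pooled error term the df and p-values would differ; the package
  documents rather than mixes the two conventions.
* `power_paired()`, `min_detectable_dz()`, `required_n()` — exact
  noncentral-t power mathematics for the two-tailed paired design
  (noncentrality $d_z\sqrt n$, df $n-1$); inversion by root bracketing
  (tolerance $10^{-9}$) and upward integer search.
* `tukey_outliers()` — fences at $Q_{1} - 1.5\,\mathrm{IQR}$ and
  $Q_{3} + 1.5\,\mathrm{IQR}$ with linear-interpolation quartiles
  (`quantile` type 7), flagging only; exclusion decisions stay with the
  analyst.

## Pipelines and reproducibility

`run_experiment_1()` and `run_experiment_2()` chain
simulate-or-ingest → aggregate → fit → screen → group statistics into a
report bundle carrying the configuration echo, package version, per-cell
fit table, screening audit, estimates, and test reports;
`write_report()` serializes it. One master seed drives everything;
per-participant trial-order and response streams are derived from it, so
identical seeds give identical bundles. Real data can enter through
`ingest_trials()`, which validates labels, grid membership and response
coding and reports the offending column and row; external column names
are mapped explicitly rather than guessed.

Problem sizes used in the package's own validation suite: parameter
recovery over 200 single-observer datasets and 100 simulated 20-observer
experiments; screen calibration at 1000 null datasets; pipeline type-I at
100 zero-shift experiments of 12 observers. These sizes put the
Monte-Carlo error well below the effects of interest (the 13.5 ms shift
is recovered with a standard error of about 0.5 ms across 100
experiments).

## Known limitations

* No lapse/guess parameters: extreme-SOA errors bias criterion estimates
  outward; with 11-point grids and 20 trials per point this mainly
  inflates window variance.
* The deviance screen's conservatism (boundary nesting, above) means its
  nominal $\alpha$ overstates its strictness.
* The scaled-Gaussian re-analysis is one standard variant of a family of
  historical fitting recipes.
* Group inference assumes the fitted PSS values are exchangeable
  participant-level measurements; fit uncertainty is not propagated into
  the group tests (the classical two-stage summary-statistics approach).
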