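---
title: "Methods: confidence-weighted human-machine group decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence-weighted human-machine group decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyborgcrowd)
```

## The problem this package models

A team of human observers and one machine face matcher watch the same
sequence of crowded-scene images and decide, trial by trial, whether a
memorised target face is present. Individually, humans in this kind of
visual search are mediocre (accuracies around 70%, with much better
rejection of nontargets than detection of targets), and a face-embedding
matcher is accurate overall but specificity-heavy: it almost never false
alarms, yet misses many targets. The question the package makes computable
is how much better *mixed groups* can be when each vote is weighted by an
objective estimate of its reliability: EEG-decoded decision confidence for
humans, and a distance-derived confidence for the machine.

`cyborgcrowd` implements the full analysis as a reproducible pipeline on
synthetic data: nothing needs to be downloaded, and every stage is testable
against its generative ground truth.

## The fusion model

Votes are encoded $d_p \in \{-1, +1\}$ ($-1$ = "target"). A group of $m$
humans decides via

$$d_{\text{group}} = \operatorname{rsign}\Big(\sum_{p=1}^{m} w_p\, d_p\Big),$$

where $\operatorname{rsign}(x)$ is the sign of $x$ with a fair coin at
$x = 0$. The five strategies differ only in the weights and membership:

* **a** — humans, $w_p = 1$ (standard majority);
* **b** — humans, $w_p$ = EEG-decoded confidence;
* **c** — humans + machine, all weights 1;
* **d** — humans + machine, confidence weights for both;
* **e** — each human first fuses with the machine
  ($\operatorname{rsign}(w_p d_p + w_M d_M)$), then the pair decisions are
  pooled by plain majority (the "inner crowd" variant).

When the machine detects no face it votes "nontarget" with weight 0, so it
is inert in weighted fusion and methods c/d collapse onto a/b on those
trials.

Ties are resolved by independent fair coins. In `run_campaign()` the coins
come from RNG substreams keyed by (method, group), one coin per trial, so
each (method, group, trial) tie is resolved independently and reruns are
bit-identical. Method e's inner-pair coins are keyed by agent and shared
across groups, because a pair's decision does not depend on which group
contains it. Whether the original analysis re-randomised ties per method is
unknowable from the published account; independent coins avoid confounding
method comparisons through shared flips. A tie counted as half a correct
decision ("expected-score" mode) would reduce Monte-Carlo variance but
change the estimand, so it is not used.

## Human confidence: the EEG decoder

The per-participant decoder follows the standard motor-imagery-style recipe
applied to correctness decoding:

1. **Preprocessing** (for continuous recordings): earlobe-average
   re-referencing, 0.15–40 Hz zero-phase Butterworth band-pass, and ocular
   artefact removal by least-squares regression of the EOG channel out of
   every scalp channel. The band-pass is an order-2 high-pass cascaded with
   an order-4 low-pass because a single band-pass with a 0.15 Hz edge has
   numerically marginal poles; both passes run forward-backward with
   steady-state initial conditions, so DC is removed exactly and edges are
   transient-free.
2. **Epoching**: response-locked windows from 1 s before to 0.5 s after the
   response, baseline-corrected by the mean of the 200 ms before stimulus
   onset, decimated to 32 Hz behind an anti-alias filter (in stages of at
   most 8, since IIR anti-alias filters with very low relative cutoffs are
   numerically fragile).
3. **CSP**: the two class covariances (correct vs incorrect trials) are
   averaged over epochs and simultaneously diagonalised;
   `csp_from_cov()` whitens the pooled covariance and eigendecomposes the
   whitened class-A covariance, so row $j$ of $W$ satisfies
   $w_j^\top \Sigma_A w_j / w_j^\top(\Sigma_A + \Sigma_B) w_j = \lambda_j$.
   Only the first and last filters are used, matching the two-feature
   design. Eigenvectors are sign-ambiguous, so each filter's
   largest-magnitude coefficient is forced positive. Scalar shrinkage
   towards $\mu I$ engages (with a warning) only when the pooled covariance
   condition number exceeds $10^6$.
4. **Log-variance features + ridge logistic regression**: the decoder
   outputs $w_p = P(\text{correct})$. The L2 penalty is parameterised by an
   inverse strength $C$ (default 1, i.e. $\lambda = 1/n$); only the form of
   the penalty is fixed by the design, so the strength is exposed in the
   config. Class imbalance is handled by plain likelihood — no reweighting
   — matching the original account's silence on the matter.
5. **8-fold cross-validation**: folds are stratified by correctness and
   rebalanced to exactly $n/k$ trials per fold when $k$ divides $n$ (so 288
   trials give the canonical 252/36 train/test split). CSP and the logistic
   model are refit per fold on training epochs only; every trial receives
   exactly one out-of-fold $w_p$.

An intercept-only fallback (smoothed base rate) covers degenerate training
folds with one class or all-constant features; stratification makes this
rare, but the fallback keeps the pipeline total.

## Machine confidence: threshold calibration and the distance transform

The machine consumes one embedding distance $d \ge 0$ per trial (the
minimum over detected faces) and votes "target" iff $d < t$. The threshold
is calibrated per cross-validation fold by exhaustive search: candidates
are the midpoints between consecutive distinct training distances plus one
point below the minimum and one above the maximum; the chosen $t$
maximises the configured metric (accuracy by default, F1 or Cohen's kappa
as alternatives) with ties broken toward the smallest candidate. No-face
trials enter the training metric as forced-nontarget predictions. Each test
trial is then decided with its own fold's threshold, and the mean ± SD
across folds is reported.

Confidence uses a two-branch logistic transform of the distance,

$$w_M = \frac{2}{1+e^{-10 (t-d)/t}} - 1 \;\; (d < t), \qquad
  w_M = \frac{2}{1+e^{-10 (d-t)/(1-t)}} - 1 \;\; (d \ge t),$$

equal to $\tanh(5(t-d)/t)$ and $\tanh(5(d-t)/(1-t))$ respectively. The
branch denominators ($t$ on the target side, $1-t$ on the nontarget side)
are the reading consistent with continuity at $d = t$ (where $w_M = 0$) and
with the published curve shape, which rises to $\tanh(5) \approx 0.9999$ at
both $d = 0$ and $d = 1$. Because the typeset source of this formula is
ambiguous, the transform is isolated in `machine_confidence()` so an
alternative reading can be swapped in one place.

## What the synthetic cohort emulates

* **Schedule** — 6 blocks × 48 trials, exactly 25% targets per block,
  block-level sequence × viewpoint tags. Blocks are treated as exchangeable:
  the original report does not say whether errors clustered by block or
  viewpoint, so the generator adds no block effects.
* **Observers** — sensitivity and specificity drawn from Gaussians with
  mean 0.569 (SD 0.109) and 0.774 (SD 0.158), clamped to $[0.01, 0.99]$.
  These means reproduce the reported population: the implied mean accuracy
  at 25% prevalence is $0.25 \cdot 0.569 + 0.75 \cdot 0.774 = 0.723$.
* **Correlated errors** — a Gaussian copula: per-trial difficulty
  $z_t \sim N(0,1)$ shared by all observers, each loading on it with
  `coupling` $\rho$ (default 0.5). Marginals are exact; larger $\rho$ makes
  errors co-occur, pulling pairwise Hamming loss below the independence
  level. $\rho = 0.5$ lands the mean pairwise Hamming loss in the low 30s
  (per cent), inside the reported 12.5–47.2% range, and produces the
  observed saturation of group sensitivity (many targets are missed by most
  observers at once). Only the observed losses are published — the latent
  model is this package's own construction.
* **EEG** — epochs are generated directly at the decoder's 32 Hz working
  rate: isotropic unit noise plus extra variance `snr` along one fixed
  spatial pattern for correct trials and an orthogonal one for incorrect
  trials, so the class covariances are $I + \text{snr}\, a_c a_c^\top$. The
  generative patterns are stored with the epochs for recovery checks. The
  default `snr = 0.18` was fixed by a 20-seed pilot so the out-of-fold AUC
  of the decoder sits near 0.72–0.75: informative but imperfect, matching
  the heavily overlapping confidence distributions of real EEG decoders; a
  much stronger decoder would be unrealistic and would invert the published
  small-group ordering between machine-assisted and BCI-assisted pairs.
  What this generator does *not* model: temporal/spectral EEG structure,
  artefacts, nonstationarity, or per-subject pattern variability — passing
  recovery tests therefore shows correctness of the decoding machinery, not
  real-data performance.
* **Distances** — class-conditional Gaussians truncated at 0. The published
  account gives no distributional form, only the machine's operating
  profile, so the defaults are solved analytically: with
  $\mu_T = 0.572, \sigma_T = 0.22$ (targets) and
  $\mu_N = 0.658, \sigma_N = 0.06$ (nontargets), the accuracy-maximising
  threshold at 25% prevalence sits at $t = 0.526$ with sensitivity
  $\Phi((t-\mu_T)/\sigma_T) = 0.417$ and specificity
  $\Phi((\mu_N-t)/\sigma_N) = 0.986$ — the reported machine profile. A
  single shared $\sigma$ cannot satisfy all three constraints at once,
  which is why the class SDs differ. No face is found with probability
  0.01, class-independently (the real data had 3 such trials out of 288).

All randomness flows from one master seed through named substreams
(`schedule`, `agents`, `decisions`, `eeg`, `distances`, fold assignment,
tie coins), so stages are independently reproducible and any stage can be
re-run from saved artefacts.

## Evaluation statistics

`summarize_by_size()` computes per-group accuracy/specificity/sensitivity
("target" is the positive class) and aggregates means and SDs per method
and size; undefined ratios are reported as `NA`, never silently zero.
`build_hamming_matrix()` adds the machine and the ideal decision maker
(votes = truths), against whom Hamming loss equals the error rate exactly.
`paired_wilcoxon()` compares methods on per-group accuracies: zero
differences are dropped, the exact signed-rank null is used for up to 25
untied nonzero pairs, and the normal approximation with tie correction
otherwise. Overlapping groups violate the test's independence assumption;
the comparisons replicate the analysis convention regardless, and should be
read descriptively. `confidence_distribution_tests()` contrasts confidence
for correct vs incorrect decisions with Kruskal-Wallis (location) and
median-centred Levene (spread) tests.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full design — 10
observers, 288 trials, all $\binom{10}{m}$ groups for $m = 1..10$, five
methods — which takes a few seconds per cohort; stochastic property suites
use 20 seeded replicate cohorts and require a majority of them to exhibit
each qualitative property, since single synthetic cohorts of 10 observers
are genuinely variable. Tie-breaking in threshold search is deterministic
(smallest candidate); CSP shrinkage triggers only beyond condition number
$10^6$; degenerate inputs (one-class folds, zero-variance features,
all-zero weight vectors, empty classes) either take documented fallbacks or
fail loudly with the offending trial named.

## Known limitations

* The synthetic cohort reproduces marginal behaviour and one shared
  difficulty factor, not block structure, learning/fatigue, or
  response-time correlates.
* The EEG generator's two-pattern variance model is the minimal structure
  CSP can exploit; it is not a biophysical simulation.
* Exact published figures (e.g. 84.4% machine accuracy, Table-1 p-values)
  depend on the original images and participants and are reproduced here
  only in distribution/ordering, not digit-for-digit.
* The confidence transform's branch normalisation is a documented
  reconstruction of an ambiguous formula.
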