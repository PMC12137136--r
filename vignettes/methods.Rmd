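---
title: "Adjudicating sustained versus ignition temporal profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating sustained versus ignition temporal profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustig)
```

## The scientific problem

Two influential accounts of conscious perception make opposite predictions
about *when* content-specific neural activity should be present during a
visual experience. A sustained-maintenance account (associated with
integrated information theory, IIT) predicts that posterior cortical
activity encoding the percept persists for the full duration of the
experience and returns to baseline at stimulus offset. An ignition account
(associated with global neuronal workspace theory, GNWT) predicts brief,
content-specific bursts in prefrontal cortex about 0.3–0.5 s after
stimulus onset and again after offset, with activity-silent maintenance in
between.

`sustig` implements the statistical machinery needed to put these
predictions against each other on trial-structured recordings — channel
screening, duration-tracking model comparison, cross-temporal
representational similarity analysis (RSA), decoding harnesses, and
phase-synchrony estimation — together with a synthetic-data generator
that plants each predicted profile with known ground truth, so every
stage of the pipeline can be validated end to end without any recorded
data.

## The experimental design the generator emulates

Trials present a single suprathreshold stimulus from one of four
categories (faces, objects, letters, false fonts; 20 identities each;
front/left/right orientation at a 2:1:1 ratio) for 0.5, 1.0 or 1.5 s,
inside a fixed 2.0-s trial followed by a truncated-exponential
inter-trial jitter. Blocks pair the pictorial or symbolic categories as
task-relevant (participants detect two rare target identities); the other
pair is task-irrelevant. The presets reproduce the published design
arithmetic exactly:

* **MEG**: 10 runs × 4 blocks, 8 non-targets per category per block,
  2–6 targets per block, jitter mean 0.4 s on [0.2, 2.0] s — 1,440
  trials, mean trial length 2.4 s.
* **iEEG**: the same with 5 runs — 720 trials.
* **fMRI**: 8 runs × 4 blocks, 4 non-targets per category per block,
  1–3 targets, jitter mean 3 s on [2.5, 10] s — 576 trials.

Three design choices deserve comment:

* *Exact totals with random target counts.* The published totals
  (1,440/720/576) are only consistent with the stated per-block target
  ranges if target counts balance across blocks. `generate_schedule()`
  draws them in complementary pairs per run — blocks receive `x` and
  `max + min − x` targets with `x` uniform on the stated range — so every
  per-block count is within the range while run totals (and hence the
  grand total) are exact.
* *Duration balance.* Cell counts such as 160 relevant face trials do not
  divide by three durations; durations are dealt maximally evenly within
  each category × relevance pool (cell counts differ by at most one, the
  remainder placed by the seed).
* *Jitter rate.* The design states the truncated-exponential mean and
  support but not its rate; `truncexp_rate()` solves for the rate
  numerically, and `sample_trial_lengths()` confirms the 2.4-s mean
  analytically and by simulation.

The high-gamma simulator plants one of three response families per
channel — `sustained` (boxcar from latency to stimulus offset),
`onset_transient` (a 0.2-s pulse at 0.3-s latency, the geometry of the
predicted ignition window), and `onset_offset` (the onset pulse plus a
pulse over [duration + 0.3, duration + 0.5] s) — scaled by per-category
gains and buried in Gaussian noise. The oscillation simulator plants
category-specific cross-channel phase coupling: within the active window,
on trials of the restricted category, the target channel's phase equals
the source phase plus a lag, jittered by a von Mises deviate whose mean
resultant length equals the coupling strength `kappa` (so `kappa = 1` is
a deterministic relation, `kappa = 0` independence, and the expected
pairwise phase consistency is about `kappa^2`). What the generator does
**not** emulate: 1/f background spectra, autocorrelated noise, trial-to-
trial latency jitter, volume conduction, and between-subject variance.
Passing recovery tests therefore demonstrate the correctness of the
statistics, not their field performance on real recordings.

## Channel screening

`task_responsive()` compares trapezoidal AUC of the evoked window
(0.05–0.35 s) against baseline (−0.3–0 s) per channel with a paired
Wilcoxon signed-rank test, Benjamini–Hochberg corrected across channels
within each task condition, and quantifies non-responsiveness with a JZS
Bayes factor (Cauchy prior scale 0.707). `category_dprime()` computes,
per channel and category,

$$d' = \frac{u_j - \tfrac1N \sum_i u_i}{\sqrt{\tfrac12 (\sigma_j^2 +
\tfrac1N \sum_i \sigma_i^2)}}, \quad i \neq j$$

on the 0.05–0.4-s AUC, with a one-tailed label-permutation test (10,000
shuffles by default, independent streams per condition) run separately on
task-relevant and task-irrelevant trials; a channel counts as selective
only if significant in both (the both-task rule). Permutation streams are
seeded; the minimum attainable p is `1/(n_perm + 1)`.

## Duration analysis

Responses are reduced to the three windows of interest (0.8–1.0, 1.3–1.5,
1.8–2.0 s; for every duration one of these is exactly the post-offset
0.3–0.5-s window). Eight design matrices are fitted per channel on the
trial × window observations: intercept-only, duration, window,
duration × window, a sustained regressor (1 iff the window ends before
stimulus offset), an offset-ignition regressor (1 iff the window is the
post-offset window), and the two theory regressors interacted with
category. Fits are ordinary least squares with a Gaussian maximum-
likelihood variance so that `BIC = k ln n − 2 lnL` is comparable across
models; the published analysis describes per-electrode linear mixed
models without naming a grouping factor, and at the single-channel level
the fixed-effects fit is that model. The winner is the minimum-BIC model,
except that models within 2 BIC points of the best are treated as tied
and the most parsimonious wins. Bayes factors between models come from
`exp(ΔBIC/2)`, reported in both directions by `bf_vs_reference()`.

`classify_profile()` crosses the winning model with the screening flags:
sustained-family winner → `sustained_selective`/`sustained_nonselective`;
ignition-family winner → `onset_offset`; an agnostic winner on a
task-responsive channel whose late window-of-interest response is
indistinguishable from zero (within two standard errors) → `onset`
(the response happened before the windows of interest); anything else is
`unclassified`.

## Cross-temporal RSA

`compute_rdm()` builds the dissimilarity `1 − r` between the feature
pattern of stimulus *a* at time *t₁* and stimulus *b* at *t₂*;
`class_contrast()` reduces it to mean(between-class) − mean(within-class)
per time-point pair. `surrogate_z()` re-runs the pipeline 1,024 times
(default) with shuffled trial labels and z-scores the observed contrast
cellwise. Two design points:

* *What is shuffled.* Surrogates permute the trial-to-stimulus
  assignment while the stimulus-to-class map stays fixed. This makes the
  surrogate contrast zero-mean by construction. (Re-labelling averaged
  stimulus patterns instead leaves the planted pattern structure in place
  and produces a rank-preserving, severely conservative tau null whenever
  single-trial SNR is high.)
* *Template correlation on the z scale.* Kendall's tau between the
  observed matrix and each binary theory template is computed on the
  window-subsampled **z-scored** matrix, and each surrogate is z-scored
  against the same null before entering the tau null distribution. This
  normalizes away the strong per-cell variance differences (cells inside
  the stimulus window fluctuate much more under label shuffles), which
  would otherwise dominate the rank correlation.

The four test windows are 0.3–0.5, 0.8–1.0, 1.3–1.5 and 1.8–2.0 s. For a
1.5-s stimulus the sustained template is 1 where both windows precede
offset; the ignition template is 1 where both windows are the onset or
post-offset window, including by default the onset × offset cross cells
(re-ignition of the same content; configurable to 0). If either tau is
significant against its surrogate null, the difference of transformed
correlations `(τ+1)/2` is tested against the surrogate difference null
(two-sided around the null mean), and all p-values are FDR corrected
together. Cluster inference on the z matrix uses a forming threshold of
z = 1.5 (upper tail) with 4-neighbour connectivity and cluster-mass
ranking against the surrogate max-mass distribution.

With unequal trial counts, `rdm_subsample_average()` subsamples every
stimulus to the minimum count, repeats 100 times, and averages the
correlations on the Fisher z scale (the "Fisher-corrected" distance):
the returned dissimilarity is `1 − tanh(mean(atanh r))`.

## Decoding

All classifiers are linear SVMs (`e1071`, cost fixed at 1 — the only
stated choice in the published pipeline is linearity) with class weights
inversely proportional to class frequency. Within-task decoding uses
stratified 5-fold cross-validation with 3 repeats per time point;
cross-task decoding trains on 80% of one task condition and tests on the
held-out 20% of the other. Feature ranking (one-way F statistic, top k,
ties to the lower index, constant features last) happens strictly inside
the training partition; temporal generalization reuses the training-time
features at every test time. Orientation decoding uses balanced accuracy
(mean per-class sensitivity) against its 1/3 chance level; binary
category decoding is tested against 50%.

Cluster-mass inference re-runs the decoding with permuted labels
(1,000 permutations by default), derives the pointwise forming threshold
from the per-tail `1 − α/2` quantile of the permutation accuracies (the
published forming rule states p < 0.05 without naming the reference
distribution, so the permutation null itself supplies it), and ranks
observed cluster masses against the max-mass null; two-sided inference
runs one pass per tail and doubles the cluster p-values.

The beta-binomial Bayes factor compares the marginal likelihood of `k`
correct in `n` trials under a flat Beta(1, 1) alternative against a null
prior Beta(1000, 1000) centred at chance and updated with the
shuffle-derived accuracies. How a shuffle accuracy (a rate) should update
the prior is open; each shuffle contributes its implied correct-trial
count `round(acc × n)` to the alpha count and the remainder to beta,
which incorporates any bias present in the empirical null. The
posterior-only versus posterior+prefrontal comparison uses the paired
t-test with the repeated-cross-validation variance correction (variance
multiplied by `1/J + n_test/n_train`), one-sided for improvement.

## Connectivity

`morlet_tfr()` convolves with analytic Morlet wavelets (σ_t =
cycles/(2πf); 4 cycles in the 2–30-Hz band, f/4 cycles above 30 Hz, f/2
where the duration analysis specifies it), via FFT with ±5 σ support;
samples within one wavelet half-width of an epoch edge are flagged in an
edge mask rather than reflected, avoiding fabricated phase. Pairwise
phase consistency is the bias-free pair average

$$\mathrm{PPC}(f,t) = \frac{2}{N(N-1)} \sum_{j<k}
\cos(\Delta\theta_j - \Delta\theta_k)$$

computed through the resultant-vector identity `(|Σe^{iΔθ}|² − N)/(N(N−1))`.
Content-selective synchrony contrasts within-category against
across-category PPC, equating trial counts by subsampling the larger set
(100 repetitions by default, skipped when counts already match), with
category-shuffle cluster permutation for inference.

GED spatial filters contrast a signal against a reference covariance:
per-trial covariances over the analysis window, trials beyond 3 z-scores
of covariance distance excluded, the reference shrunk toward its diagonal
(`(1−γ)R + γ·mean(diag R)·I`, γ = 0.01 by default — the published
pipeline says "regularized" without a value), and the generalized
eigenproblem solved by Cholesky whitening. The top eigenvector is the
filter; its generalized eigenvalue equals the signal/reference variance
ratio of the component on the training data.

## Numerical and testing choices

* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical schedules and tensors.
* 2D cluster connectivity is 4-neighbour by default (8 available);
  permutation p-values have floor `1/(n_perm+1)` (doubled two-sided).
* `bin_decimate()` requires the bin width to be an integer multiple of
  the sample period and drops a trailing partial bin; bins align to the
  epoch start and carry left-edge timestamps.
* The JZS Bayes factor integrates the g-prior mixture numerically
  (`stats::integrate` on the inverse-gamma representation of the Cauchy
  prior); it agrees with independent quadrature to at least four digits.
* Degenerate inputs error loudly: zero pooled variance in d′, constant
  templates in the tau test, singular reference covariances at γ = 0,
  windows outside the epoch, carriers at or above Nyquist.

Problem sizes in the test-suite recovery studies were chosen to make the
planted effects comfortably detectable while keeping each study small:
temporal-profile recovery uses 100 channels per profile at amplitude
3 × noise SD on the iEEG-preset irrelevant trials; representational
recovery uses 16 stimuli × 100 trials at per-trial amplitude 0.3 × noise
SD (an aggregate per-stimulus pattern SNR of 3) with 200 surrogates per
replicate; chance calibration uses 100 datasets of 320 trials; error-
control calibration uses 200–400 null replicates with 99–100 permutations
each.

## Known limitations

* The generator's noise is white and Gaussian; real high-gamma envelopes
  are autocorrelated and heavy-tailed, so real-data error rates may
  differ from the calibrated ones.
* The surrogate-based template tau test loses power when single-trial
  SNR is very high relative to trial counts (label shuffles then retain
  rank structure); the template *selection* (which theory's template
  correlates better) is robust across regimes.
* `fit_models()` offers no random-effects structure beyond the residual
  term; with grouped data (e.g. repeated identities) a mixed model could
  be substituted per channel.
* The decoding harness refits the full pipeline per permutation, which
  is exact but expensive; the defaults (1,000 permutations) assume a
  compute budget of minutes per contrast, not seconds.
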