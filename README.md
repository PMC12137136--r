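# sustig

Statistical machinery for adjudicating between two competing predictions
about the temporal profile of content-specific neural activity in
trial-structured recordings: **sustained maintenance** (content-coding
activity persists for the full duration of a percept and returns to
baseline at stimulus offset, the signature predicted by integrated
information theory for posterior cortex) versus **ignition** (brief
content-specific bursts ~0.3–0.5 s after stimulus onset *and offset*
with silent maintenance in between, the signature predicted by global
neuronal workspace theory for prefrontal cortex).

The package provides, end to end:

* a **trial-schedule generator** reproducing the exact design arithmetic
  of the underlying category × identity × orientation × duration ×
  task-relevance paradigm (MEG/iEEG/fMRI presets: 1,440 / 720 / 576
  trials), plus simulators for high-gamma envelopes with planted
  sustained / onset / onset+offset response profiles and for narrowband
  oscillations with planted category-specific phase coupling;
* **channel screening**: signed-rank task-responsiveness with FDR and a
  JZS Bayes factor, and category selectivity via
  `d' = (u_j − mean(u_i)) / sqrt((σ_j² + mean(σ_i²))/2)` with a
  label-permutation test and the both-task rule;
* the **duration analysis**: OLS fits of eight temporal design matrices
  (null, duration, window, duration × window, sustained, offset-ignition,
  and the theory models × category) on the windows of interest
  (0.8–1.0, 1.3–1.5, 1.8–2.0 s), BIC winner selection and
  `BF = exp(ΔBIC/2)` model evidence, and response-profile classification;
* **cross-temporal RSA**: correlation-distance RDMs between stimuli at
  all time-point pairs, within- versus between-class contrast,
  1,024-shuffle surrogate z-scoring, z = 1.5 cluster inference, and
  Kendall-tau adjudication against binary sustained/ignition templates
  over the four test windows (0.3–0.5, 0.8–1.0, 1.3–1.5, 1.8–2.0 s);
* **decoding harnesses**: class-weighted linear SVMs with top-k F-score
  feature selection, 5-fold × 3-repeat CV, cross-task train/test,
  temporal generalization, balanced accuracy, cluster-mass permutation
  inference, beta-binomial Bayes factors (flat Beta(1,1) alternative vs
  a Beta(1000,1000) chance-centred null updated with shuffle
  accuracies), and the posterior vs posterior+prefrontal comparison with
  the variance-corrected paired t-test;
* **connectivity**: complex Morlet time-frequency estimation, pairwise
  phase consistency `PPC = 2/(N(N−1)) Σ_{j<k} cos(Δθ_j − Δθ_k)`,
  within- vs across-category synchrony contrasts with cluster
  permutation, and GED spatial filters with covariance-outlier rejection
  and diagonal shrinkage;
* a shared **stats engine**: cluster-based permutation inference (1D/2D,
  4/8-connectivity, one- and two-sided), Benjamini–Hochberg FDR, and
  BIC/JZS Bayes-factor utilities.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
choices and limitations.

## Worked example

Simulate an iEEG-style session with three channels — a face-selective
sustained channel, an onset+offset (ignition) channel, and a pure-noise
channel — then screen them and let the duration models compete:

```r
library(sustig)

sch <- generate_schedule(design_spec("ieeg"), seed = 1)   # 720 trials
nt  <- trial_table(sch[sch$relevance == "irrelevant", ])  # analysis set

ch <- channel_info(c("post01", "pfc01", "noise01"),
                   roi = c("posterior", "prefrontal", "other"))
profiles <- list(
  response_profile("sustained",    amplitude = 3, selectivity = c(face = 1)),
  response_profile("onset_offset", amplitude = 3),
  response_profile("none"))
ep <- simulate_highgamma(nt, ch, profiles, noise_sd = 1, sfreq = 64, seed = 2)

vals <- lapply(list(c(0.8, 1.0), c(1.3, 1.5), c(1.8, 2.0)),
               function(w) window_reduce(ep, w, "auc"))
fits <- fit_models(vals, build_designs(nt))
fits$winner
#> [1] "iit_x_category" "gnwt"           "null"

resp <- task_responsive(ep)
resp[, c("channel", "responsive")]
#>   channel responsive
#> 1  post01       TRUE
#> 2   pfc01       TRUE
#> 3 noise01      FALSE

sel <- category_dprime(ep, n_perm = 1000, seed = 3)
subset(sel, category == "face")
#>   channel category dprime_irrelevant p_irrelevant selective
#> 1  post01     face        3.71424538  0.000999001      TRUE
#> 2   pfc01     face       -0.04921134  0.654345654     FALSE
#> 3 noise01     face       -0.01562855  0.554445554     FALSE

classify_profile(fits,
                 selective  = tapply(sel$selective, sel$channel, any)[ch$name],
                 responsive = resp$responsive)
#> [1] "sustained_selective" "onset_offset"        "unclassified"
```

The planted sustained face-selective channel wins the sustained-model ×
category fit (`iit_x_category`) and is labelled `sustained_selective`;
the ignition channel wins the offset-ignition model (`gnwt`); the noise
channel keeps the intercept-only model — and the BIC Bayes factor
`bf_vs_reference(fits, "gnwt", "null")` on that channel is ≈ 16.6,
substantial evidence for the null over ignition.

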