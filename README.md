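# pupilmem

Single-trial analysis of the **subsequent memory effect** in auditory free
recall with pupillometry, for cognitive hearing science.

In the Sentence-final Word Identification and Recall (SWIR) paradigm, a
listener hears lists of seven sentences in multi-talker babble (wearing
hearing aids with noise reduction on for half the lists, off for the other
half), repeats each sentence-final word, and freely recalls all seven words
at the end of the list. The pupil dilates transiently while each sentence is
processed; the size of that dilation indexes the attention devoted to
encoding the word. `pupilmem` asks, word by word: *does a larger task-evoked
peak pupil dilation (PPD) during listening predict that the word will later
be recalled?*

The package implements the full analysis chain:

- **Trace cleaning** — sliding-window blink detection (1 s window, 3 SD
  threshold), padded removal (77 samples before, 181 after), linear
  interpolation, discarding trials with < 60% valid data and participants
  with > 15% missing sentences, with a structured cleaning report.
- **Feature extraction** — epochs of [-1, 4) s around each sentence onset;
  baseline = mean diameter over the 1 s before onset; PPD = in-window
  maximum minus baseline; repeated-word filtering; time-course and
  per-participant summaries with ggplot2 figures.
- **Inference** — a binary logistic mixed model of recall with fixed effects
  PPD, Reading Span score, noise reduction, age and PTA (continuous
  predictors centered) and crossed random intercepts for participant and
  serial position:

  `logit P(recalled) = b0 + b1 PPD_c + b2 RS_c + b3 NR + b4 age_c + b5 PTA_c + u_participant + u_position`,

  `u_participant ~ N(0, s2_p)`, `u_position ~ N(0, s2_t)`, fit by maximum
  likelihood with the Laplace approximation (PIRLS inner loop, exact
  analytic outer gradient). Odds ratios `exp(b)` with Wald 95% CIs, Type-II
  Wald chi-square tests, likelihood-ratio test against the null model,
  variance inflation factors, Nakagawa marginal/conditional R-squared
  (`pi^2/3` logit residual variance), an exploratory quadratic-PPD model,
  and the post-hoc Pearson correlation between mean PPD and Reading Span.
- **Power** — a priori repeated-measures power via the noncentral F
  distribution (`lambda = f2 n m / (1 - rho)`), with `min_n()` returning the
  smallest sample size reaching a target power.
- **Synthetic studies** — `simulate_study()` generates raw two-eye traces,
  events and participants with known ground truth (blinks, drift,
  event-locked dilations whose latent amplitude drives recall), and
  `end_to_end_recovery()` pushes replicates through the whole pipeline to
  measure bias, RMSE and CI coverage. The HINT adaptive SNR staircase, the
  SWIR training SNR adjustment and Reading Span scoring are included.

## Worked example

```r
library(pupilmem)

sim      <- simulate_study(sim_config("small"), seed = 42)
cleaned  <- clean_study(sim$samples, sim$events)
features <- filter_repeated(extract_features(cleaned, sim$events, sim$participants))
fit      <- fit_recall_glmm(features)
cat(format_fit_table(fit), sep = "\n")
```

```
                 beta (95% CI)          Odds ratio (95% CI)    p
(Intercept)       0.81 (-0.92,  2.54)    2.25 ( 0.40, 12.68)   0.357
ppd               1.98 ( 0.14,  3.81)    7.22 ( 1.16, 45.04)   0.034
rs_score          0.07 (-0.06,  0.20)    1.07 ( 0.94,  1.22)   0.300
noise_reduction   0.16 (-0.49,  0.81)    1.18 ( 0.61,  2.26)   0.624
age               0.09 (-0.03,  0.21)    1.09 ( 0.97,  1.23)   0.147
pta               0.00 (-0.16,  0.17)    1.00 ( 0.85,  1.18)   0.982
sigma2: participant 1.418, trial 3.330; logLik -122.43
```

This small synthetic study (6 participants x 6 lists x 7 sentences; 252
trials, 1.19% discarded by the validity rules, 14.4% of valid trial data
interpolated across blinks) recovers the positive PPD-recall association it
was generated with: each additional millimetre of peak dilation multiplies
the odds of later recall by about 7 (the generating slope is 0.60 per mm —
at this tiny scale the estimate is noisy but its CI excludes zero, p = .034).
The other effects are generated near zero and are correctly not detected.
The trial (serial position) variance is large because the generator includes
a strong recency profile. `summary(fit)` adds the Type-II Wald tests, VIFs
and Nakagawa R2; at full scale

```r
rec <- end_to_end_recovery(sim_config("small"), n_replicates = 100, seed = 1)
rec$summary
```

reports per-parameter bias, RMSE and 95% CI coverage of the whole pipeline.

The power module reproduces standard repeated-measures sample sizes:

```r
min_n(power_spec(eta_sq = 0.10, alpha = 0.05, target_power = 0.80, m = 2))
#> [1] 20
```

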