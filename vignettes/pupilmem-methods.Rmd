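---
title: "Methods: single-trial pupillometry and subsequent memory recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial pupillometry and subsequent memory recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilmem)
```

## The scientific question

When a listener hears a sentence in background babble and must later recall
its final word, the pupil dilates transiently during listening. The magnitude
of that task-evoked dilation indexes how much attentional processing the
listener devotes to the item, and items that receive more attention during
encoding are more likely to be recalled later — the *subsequent memory
effect*. `pupilmem` implements a single-trial version of this analysis for
the Sentence-final Word Identification and Recall (SWIR) paradigm in hearing
aid users: seven sentences per list, the last word repeated after each
sentence, and free recall of all seven words at the end of the list, with
hearing-aid noise reduction on for half the lists and off for the other
half.

The pipeline has four stages: (1) cleaning of raw eye-tracker pupil traces,
(2) extraction of the baseline-corrected peak pupil dilation (PPD) per
sentence, (3) a binary logistic mixed model of word-level recall, and (4)
supporting computations — a priori repeated-measures power, behavioral SNR
protocols, and a synthetic-study generator used to validate the whole chain.

## Pupil trace cleaning

Traces are recorded at 1200 Hz per eye. The right eye is analysed by default
unless the left eye has more present (non-missing) samples, counted before
any cleaning; ties go right. Eye choice is made per participant.

**Blink detection.** A sliding window of 1 s (1200 samples) is centred on
each sample and shrunk at the recording edges. A sample is a blink candidate
when its diameter lies more than 3 standard deviations below the window mean,
with the window statistics computed over present samples only. Samples that
the tracker already reported missing are treated exactly like detected blink
samples, because a dropout usually is a blink as the tracker sees it.

**Padding and removal.** Each flagged run is extended by 77 samples (64 ms)
before and 181 samples (151 ms) after — the eyelid partially occludes the
pupil on both sides of full closure — and overlapping extensions are merged.

**Interpolation.** Removed samples are replaced by the straight line between
the nearest surviving neighbours. Leading or trailing gaps with an anchor on
only one side are filled by nearest-value hold and still counted as
interpolated, so that trial windows stay complete while the report records
how much of them is reconstructed.

**Validity filtering.** A trial is the 5 s epoch around one sentence
([-1 s, +4 s) from onset). Trials with *less than* 60% of their samples
surviving (judged before interpolation) are discarded; exactly 60% is kept.
Participants for whom *more than* 15% of administered sentences were
discarded are excluded; exactly 15% is kept. Both comparisons are strict, as
worded in the field's convention. Every exclusion carries a reason code in
the cleaning report.

Two readings were genuinely open and are resolved as follows. "Valid data"
per trial is taken as pre-interpolation survival — coverage after
interpolation would make the 60% rule vacuous, since interpolation leaves no
gaps. And padding applies to tracker dropouts as well as threshold-detected
blinks, since both are manifestations of the same lid movement.

**Numerical notes.** The windowed statistics are computed from cumulative
sums centred by the global mean, and the threshold carries an absolute guard
of 1e-9 mm; without these, rounding in the running sums can flag samples of
an exactly constant stretch (where the true SD is zero and the mean error,
however tiny, decides the comparison). The guard is orders of magnitude
below any physical pupil signal. Segment indices are 1-based inclusive, the
R convention.

**On idempotence.** Re-running the cleaning stage on its own output is not
exactly a no-op: interpolated spans carry no measurement noise, so a second
pass sees slightly tighter window SDs and can re-flag a handful of marginal
samples near former blink flanks (in synthetic traces, well under 0.1% of
samples and a few percent of first-pass flags). This is a property of
re-applying a threshold rule to interpolated data — which the pipeline never
does in normal operation — not of the detector, which matches a brute-force
per-sample oracle exactly. The test suite asserts near-idempotence at those
rates.

## Peak pupil dilation

The baseline is the arithmetic mean over the 1 s before sentence onset. One
second is the longest pre-onset interval with homogeneous acoustics in this
paradigm: the babble starts 3 s before the first sentence of a list but only
1 s before sentences 2–7, so a longer window would mix silence into the
baseline of most trials. The statistic (mean vs last sample) and the window
length are configuration options; the defaults are as above.

PPD is the maximum diameter in the 4 s from sentence onset minus the
baseline — algebraically identical to the maximum of the baseline-corrected
samples. Negative values (net constriction) are retained, not clipped.
Baseline correction makes PPD invariant to additive offsets, which removes
slow arousal drift between trials; the offset-invariance and window
restriction are tested as properties.

Only sentences whose target word was correctly repeated enter the recall
model (about 2% are typically lost), since a word that was never heard
cannot be encoded.

## The recall model

Word-level recall (1 = recalled) is modelled with a binary logistic mixed
model: fixed effects for PPD, Reading Span score, noise reduction (on vs
off, reference off), age and PTA, and crossed random intercepts for
participant and for serial position. Continuous predictors are centered by
subtracting the mean. PTA enters as the mean of the left- and right-ear
four-frequency averages, appropriate for the symmetric losses this paradigm
targets.

The trial random factor is serial position (7 levels), chosen because its
purpose is to absorb primacy and recency structure; an alternative reading —
one level per sentence token (list x position) — is available via
`trial_factor = "token"`. With only 7 levels the position variance is weakly
identified and a boundary (zero) estimate is legitimate; the fit flags it.

**Estimation.** The marginal likelihood is approximated by the Laplace
method: for given fixed effects and variance parameters, the random-effect
vector is profiled out at its conditional mode, found by penalized
iteratively reweighted least squares (PIRLS, converged to 1e-8 on the
penalized log-likelihood, with step halving). The outer problem maximizes
the Laplace log-likelihood over the fixed effects and the two log standard
deviations jointly. A cheap first stage searches the variance parameters
alone with the fixed effects profiled inside PIRLS; the main stage then
refines all parameters with `nlminb` under bound constraints
(|beta| <= 15, log-SD in [log 1e-3, log 10]), driven by the exact analytic
gradient of the Laplace objective obtained by implicit differentiation
through the PIRLS mode (the mode condition removes first-order sensitivity
of the penalized log-likelihood, leaving the data score plus the derivative
of the log-determinant, which for the logit link involves
mu(1-mu)(1-2mu)). The gradient is verified against central differences in
the tests, and whole fits are cross-checked against an independent Laplace
implementation (`lme4::glmer`) to ~1e-3 on the log-likelihood scale.

Standard errors come from the fixed-effects block of the inverse joint
observed information (the Schur complement of the random-effects block),
conditioning on the estimated variance parameters — the usual Wald
covariance for this model class. 95% CIs are `beta +/- 1.96 SE`; odds ratios
exponentiate both. With both variances pinned to zero the model reduces
exactly to plain logistic regression, and the implementation is required (by
test) to match `stats::glm` to 1e-6 in coefficients, SEs and log-likelihood.

**Degenerate inputs.** A constant outcome, or any |beta| exceeding 15 on the
logit scale during estimation, raises an explicit complete-separation error
rather than returning a divergent fit.

**Boundary fits.** When a variance's maximum-likelihood estimate is zero —
common for the participant intercept at very small cohort sizes — the log-SD
scale can only approach the boundary asymptotically, and the outer optimizer
crawls down an endless valley instead of converging. The fitter detects this
(an unsettled fit with a non-vanishing projected gradient), refits with the
offending variance pinned to zero, and keeps the pinned fit when its
likelihood is at least as good, flagging the component as a boundary
estimate. Convergence is judged by the projected gradient (components
pushing into an active bound are excluded) with a fallback on measurable
objective improvement, because near-zero variances induce extreme curvature
that makes a raw gradient norm meaningless.

**Reported statistics.** Type-II Wald chi-square tests per term (single-df
terms reduce to squared z-scores); a likelihood-ratio test against the null
model that keeps the intercept and both random intercepts (df = number of
dropped fixed effects); variance inflation factors `1/(1 - R2_j)` from
regressing each predictor on the others; and Nakagawa R2 for logit links,
with `pi^2/3` as the distribution-specific residual variance — marginal uses
the fixed-predictor variance alone, conditional adds both intercept
variances. Wald z p-values and the Type-II chi-square p-values coincide for
single-df terms; both are available. The exploratory quadratic model adds
squared centered PPD and reports the inverted-U turning point `-b1/(2 b2)`
when the curvature is negative. The post-hoc Pearson correlation between
per-participant mean PPD and Reading Span score uses `stats::cor.test`.

## Repeated-measures power

The a priori power computation is the within-subjects noncentral-F
calculation: `f2 = eta2/(1 - eta2)`, noncentrality
`lambda = f2 * n * m / (1 - rho)`, numerator df `(m-1) epsilon`, denominator
df `(n-1)(m-1) epsilon`, and power the upper tail of the noncentral F beyond
the central critical value. The defaults `rho = 0.5` and `epsilon = 1` are
the conventional values assumed when a design reports only the effect size,
alpha, power and the number of measurements; they are exactly what is needed
to reproduce minimal sample sizes of 4 (eta2 = 0.59) and 20 (eta2 = 0.10) at
alpha = 0.05 and power 0.80 with two measurements. `min_n` returns the
smallest n whose power reaches the target; the CDF-based power is checked
against Monte-Carlo simulation of the F statistic.

## The synthetic-study generator

`sim_config()` fixes the study conditions: 21 participants, 28 lists of 7
sentences, 1200 Hz sampling, cohort moments of age 58 (SD 11.3) years, PTA
49.2 (SD 11.5) dB HL per ear, Reading Span 41.8% (SD 12.1, quantized to the
24-word score grid). The recall model coefficients default to
(0.61, 0.60, 0.03, -0.01, -0.01, 0.01) for intercept, PPD, RS, noise
reduction, age and PTA — a realistic operating point taken from published
fits of this paradigm, clearly a simulation default rather than a claim —
with participant intercept SD 1.0 and position intercept SD 0.3 drawn on top
of a fixed primacy/recency profile whose last position dominates (recency is
very strong in this task).

Traces are built as participant baseline (~4 mm; the field reports
amplitudes in mm and this convention is documented rather than arbitrary
units) + slow two-component sinusoidal drift (0.1 mm) + event-locked
dilations + white measurement noise (0.015 mm). The dilation kernel is
gamma-like, peaking 2 s post-onset, cosine-tapered to exactly zero by 4 s so
that it cannot leak into the next sentence's 1 s baseline at the ~6 s
sentence spacing; sentence onsets snap to the sample grid. With noise,
drift and blinks disabled, the extracted PPD therefore equals the latent
amplitude to machine precision — a test anchors this identity. Blinks are
inserted as Poisson (0.2/s) dropouts of 100–300 ms plus brief partial-closure
dips (0.1/s, 30–70 ms, 1.5–2.5 mm deep): the dips are short enough that a
3-SD/1-s-window rule can catch them, giving the detector genuine work; the
left eye receives 1.5x the blink rate so that eye selection has something to
choose between. Babble timing follows the paradigm (3 s lead before
sentence 1, 1 s before sentences 2–7).

Recall outcomes are driven by the *latent* amplitude, not the extracted PPD,
so measurement noise in extraction attenuates the fitted PPD slope exactly
as it would in real data. The recovery harness therefore also refits each
replicate with the true amplitudes substituted for PPD, reporting that
attenuation ceiling alongside bias, RMSE and CI coverage.

What the generator does **not** emulate: luminance responses and gaze-angle
artifacts, non-stationary blink clustering, fatigue trends across lists,
heavy-tailed tracker noise, or any acoustic signal processing. Passing
recovery tests therefore show that the pipeline is faithful to its own model
class at realistic signal-to-noise, not that real recordings satisfy that
model.

## Problem sizes used by the test suite

The suite validates at three scales, chosen to keep a full run within a
practical interactive budget while preserving statistical meaning: oracle
equivalence on random traces up to 5000 samples; calibration of the PPD Wald
test on 400 feature-level null studies of 50 participants x 196 sentences
(rejection rate required within [0.03, 0.07] at alpha = 0.05); and
end-to-end CI coverage for the PPD slope over 100 full-pipeline replicates
of a small preset (6 participants x 6 lists x 7 sentences at 1200 Hz),
required within [0.86, 0.99]. The full-scale default study generates in
well under five minutes; the small preset in a few seconds.

## Known limitations

- The Laplace approximation is the estimation method by design; adaptive
  quadrature, random slopes and Bayesian fits are out of scope.
- Wald CIs are symmetric on the logit scale; profile or bootstrap intervals
  are not provided (the reported tables imply Wald).
- With 7 position levels the trial variance is weakly identified; treat its
  point estimate, and boundary fits, accordingly.
- Between-participant effects (RS, age, PTA) are estimated from as many
  clusters as there are participants; at the small preset their CIs are
  honest but their coverage is governed by ~4 effective degrees of freedom.
- The eye-selection count uses pre-cleaning present samples; counting
  post-cleaning survivors is a defensible alternative the package does not
  implement.
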