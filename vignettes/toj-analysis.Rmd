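---
title: "Estimating cross-modal temporal biases from spatial TOJ data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cross-modal temporal biases from spatial TOJ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojkit)
```

## The task and the measurement model

In a spatial temporal-order-judgment (TOJ) experiment two brief stimuli are
presented in rapid succession, one in each hemifield, and the observer
reports the side of the first stimulus. The signed stimulus onset asynchrony
(SOA) is the lag between the two onsets; in the canonical design implemented
by `toj_design()` the SOAs are ±30, ±90, ±135 and ±400 ms, crossed with the
modality assignment of the two sides (2 modalities × 2 sides × 8 SOAs = 32
cells, 10 repetitions each, 320 trials in 10 blocks). Trials in which the
two stimuli share a modality are *unimodal*; trials pairing vision with
audition or touch are *bimodal*.

On bimodal trials the responses are recoded to 'visual first' and the SOA is
re-signed so that positive values mean the visual stimulus physically led
(`recode_trials()`). The proportion of 'visual first' responses as a
function of this SOA is modelled as a cumulative Gaussian,

$$
P(\text{visual first} \mid \text{SOA}) \;=\;
\frac{\lambda}{2} + (1-\lambda)\,
\Phi\!\left(\frac{\text{SOA} - \text{PSS}}{\sigma}\right),
$$

with three interpretable parameters:

* **PSS** (point of subjective simultaneity, ms): the SOA at which the two
  stimuli are perceived as simultaneous. Positive PSS means the visual
  stimulus must lead to appear simultaneous — the typical direction for
  sighted observers, for whom vision is perceived as delayed relative to
  audition.
* **σ** (ms): the SD of the underlying latency-difference noise; smaller σ
  means better temporal resolution.
* **λ**: the lapse rate, the probability of a stimulus-independent guess,
  split evenly between the two responses so that the asymptotes sit at
  λ/2 and 1 − λ/2.

## Probit-line estimation of PSS and JND

Rather than fitting the three-parameter curve directly, the analysis
linearises the per-SOA response proportions with the probit transform and
fits an ordinary least-squares line (`fit_psychometric()`):

* Each proportion is clamped into $[1/(2n),\, 1 - 1/(2n)]$ (n = trials at
  that SOA) before applying $\Phi^{-1}$, so that perfect performance still
  yields a finite probit. The clamp is the smallest perturbation that keeps
  the transform defined; it is documented here because it is the one place
  where this implementation could diverge numerically from other
  realisations of the same procedure at saturated SOAs.
* **Asymptote rule.** If pooled accuracy at the longest |SOA| is no better
  than at the second-longest, the ±400 ms points are dropped before the
  fit: a saturated (and clamped) tail only flattens the line. We pool both
  signs of the SOA and drop both tails together, treating "performance" as
  accuracy; a strict-equality variant and an off switch are available via
  `asymptote_rule`, because the operationalisation ("equal" on which
  measure, one or both tails) is genuinely open.
* **PSS** is the zero crossing $-\hat\beta_0/\hat\beta_1$, clipped into
  ±150 ms with a flag. The bound prevents extrapolated crossings far
  outside the sampled SOA range from dominating group statistics.
* **JND** is the SOA at which the line predicts 75% correct order reports,
  $\Phi^{-1}(0.75)/\hat\beta_1 \approx 0.6745/\hat\beta_1$ — half the
  25%→75% span of a symmetric line. JNDs are estimated and exported but the
  pipeline runs no group tests on them: for observers whose performance has
  not saturated by ±135 ms the JND extrapolates beyond the densely sampled
  range and is too unreliable to compare across groups.
* A non-positive fitted slope is flagged non-identifiable and PSS/JND are
  reported missing rather than as meaningless crossings.

The OLS line is unweighted across SOA points. A direct maximum-likelihood
cumulative-Gaussian fit is used in the test suite as an independent oracle:
at 10,000 trials per SOA the two estimators agree on the PSS to within
2 ms.

As a complementary, outlier-robust bias measure, `summarize_participant()`
reports the overall proportion of 'visual first' responses pooled over all
SOAs (the design is balanced, so an unbiased observer sits at 0.5), and the
bias size |p − 0.5|.

## Trial filtering

Before any fitting, `filter_trials()` removes, per participant and
experiment, trials with RT < 100 ms, and then trials with RT more than
2.5 sample SDs above that participant's mean RT, with the mean and SD
computed over the remaining non-experimenter trials pooled across
conditions (the single-pass, fast-rule-first order follows the order in
which the two rules are conventionally stated). Experimenter-entered
responses carry no usable RT and are never filtered; a missing RT on a
normal trial excludes the row with its own reason code. Thresholds are
computed once on the raw data — re-filtering the retained table is not the
identity (the SD shrinks), which is why the pipeline applies the filter
exactly once.

## Group-level inference

PSS values violate normality in small sight-recovery samples, so all t-type
group tests use permutation nulls (`perm_t_one_sample()`,
`perm_t_two_sample()`, `perm_anova_oneway()`):

* one-sample tests flip the signs of the mu0-centred values (valid under
  symmetry of the null distribution); two-sample tests permute group
  labels;
* enumeration is exhaustive when there are at most 32,768 arrangements
  (n ≤ 15 for sign flips), in which case the identity arrangement is
  included and p = count/total; otherwise 10,000 Monte-Carlo draws are used
  with the add-one convention (count+1)/(n\_perm+1). The two conventions
  agree within Monte-Carlo error and both guarantee p > 0;
* one-tailed p-values are directional in the sign of the observed
  statistic. Planned, directional comparisons (each group's PSS against
  zero; each cataract group against its matched control) default to
  one-tailed; everything else to two-tailed. The tails, seed and
  permutation count are recorded in every `toj_test`.

The trial-level bias and accuracy analyses use binomial random-intercept
mixed models (`fit_binomial_glmm()`, backed by `lme4::glmer` with adaptive
Gauss–Hermite quadrature, 15 nodes by default — the marginal likelihood is
stable to well below 1e-6 at that order for these data sizes). The default
link is the logit: chance level (probability 0.5) then maps to 0 on the
link scale, which is what the per-group "bias against chance" contrasts
test; a log link is selectable for sensitivity analyses
(`link = "log"`), since with binomial data the choice between the two is a
documented ambiguity rather than a settled convention. Group effects are
tested by likelihood-ratio chi-square between nested fits
(`lrt_group_effect()`), pairwise contrasts by Wald z on the link scale
(`glmm_contrast()`).

**Effect sizes.** Because no standardised effect size is generally accepted
for permutation tests and mixed models, every test carries
$r_{\text{equivalent}}$: the one-tailed p-value is converted back to the
equivalent t on the participants-based degrees of freedom and mapped to
$r = t_{\text{eq}}/\sqrt{t_{\text{eq}}^2 + df}$ (`r_equivalent()`). For
chi-square group tests the df is reconstructed from the participant counts
(n − 1 within one group, N − 2 between two groups); p ≥ 0.5 clips r to 0
with a warning.

**Bias–resolution correlation.** Across participants from all groups,
Pearson's r between the bias size and the proportion of correct bimodal
judgments, with a leverage guard: within each group, participants more than
2.5 SDs from the group mean on either measure are excluded before pooling
(`bias_accuracy_correlation()`). The p-value permutes one variable.

## Reaction-time peak analysis

Response uncertainty is maximal for stimuli perceived as simultaneous, so
RTs should peak near the PSS if the bias is perceptual rather than a
response preference. `normalize_rt()` z-scores each participant's bimodal
RTs (experimenter-entered rows excluded); `fit_rt_peak()` then fits, by
maximum likelihood,

$$
\text{rt}_z \sim \mathcal{N}\!\left(b + a\,
e^{-(\text{SOA} - \text{peak})^2 / 2w^2},\ s\right),
$$

with the peak constrained to the sampled SOA range. The Gaussian-bump mean
was chosen over alternatives (e.g. a quadratic) because it is bounded,
peaks once, and nests the constant model at a = 0; the likelihood is
multimodal in the peak, so the optimiser restarts from a grid of peak
locations across the range. Each fit is compared against the constant-mean
model by likelihood ratio (3 df); flat profiles are flagged unreliable and
excluded from the group comparison (`compare_rt_peaks()`, a permutation t
on the peak SOAs), so boundary estimates from uninformative profiles cannot
dominate the test. At 320 trials with bump amplitude 0.8 and residual SD
0.35 the peak is recoverable to about ±8 ms (Cramér–Rao); profiles much
noisier than that carry little information about the peak location, which
is exactly what the reliability flag screens out.

## The synthetic-observer generator

`simulate_study()` exists so that every stage above can be validated by
parameter recovery without any human data. It emulates:

* the full factorial design (all four modality-side assignments × 8 SOAs ×
  10 repetitions, blocked and shuffled);
* cumulative-Gaussian observers with symmetric lapses on bimodal trials,
  and the analogous right-first function (PSS fixed at 0, own σ) on
  unimodal trials — the same functional family the analysis assumes;
* between-participant variability: per-group normal distributions of PSS
  and σ (σ draws truncated at 10 ms);
* RTs from the Gaussian-bump model centred on each observer's own PSS on
  bimodal trials and at baseline on unimodal trials, with Gaussian noise
  truncated at 0 ms;
* nuisance processes: whole-participant experimenter-entered sessions
  (responses flagged, RTs missing) and incomplete sessions (a binomial
  number of completed blocks).

Seeding is hierarchical: one master seed, deterministic per-participant
substreams, so a whole study is reproducible and individual participants
can be regenerated in isolation.

`default_study_spec()` mirrors a two-experiment sight-recovery study:
CC n = 10 with matched controls n = 10, DC n = 9 with matched controls
n = 9. The generative values — CC mean PSS −40 ms (vision perceived as
*earlier*), controls +35 to +40 ms (the typical direction), DC +70 ms, σ
around 80 ms for controls and 150–170 ms for the cataract groups, lapse
0.02 vs 0.05, RT baseline 450 ms with a 150 ms bump of width 150 ms and
100 ms noise, 5% experimenter-entered sessions, 97% block completion — are
stand-ins chosen to reproduce the qualitative result pattern and realistic
human magnitudes, not estimates of any particular dataset. What the
generator deliberately does **not** model: practice trials, feedback,
sequential effects, attention lapses that correlate across trials,
non-Gaussian RT shapes (real RTs are right-skewed), or asymmetric lapse
rates. Passing recovery tests therefore demonstrate that the pipeline is
correct under its own assumptions, not that those assumptions hold for any
given dataset.

## Numerical choices and degenerate inputs

* Proportion clamp 1/(2n) before the probit (documented above).
* Exhaustive-vs-Monte-Carlo switch at 32,768 arrangements; permutation
  p-values never 0; ties counted with a 1e-12 tolerance.
* Zero-variance inputs: one- and two-sample tests return p = 1 with a
  degeneracy note; zero RT variance excludes the participant from the RT
  analysis; a constant RT profile short-circuits to an unreliable flat fit.
* Participants with fewer than two usable RTs skip the SD-based outlier
  rule (the 100 ms rule still applies), with a warning.
* GLMM fits at the variance boundary (singular fits) are treated as
  converged; suspected complete separation (|coefficient| or SE > 10 on
  the link scale) is flagged.
* RT-peak optimisation: L-BFGS-B on (peak, baseline, amplitude, log width,
  log residual SD), width bounded to [5, 5000] ms, peak to the sampled
  range, 9 grid restarts; the constant model is restored if every restart
  ends below it, preserving the nested-likelihood invariant.

## Problem sizes used in the validation suite

The recovery and calibration studies shipped with the package use: 200
simulated participants for the PSS bias check (true PSS ~ N(0, 40 ms),
σ = 90 ms, λ = 0.02, 320 trials each); 10,000 trials per SOA for the
probit-vs-ML oracle; 1000 null replicates at 2000 permutations for the
type-I calibration of each permutation engine and 500 replicates for the
GLMM likelihood-ratio test (16 participants × 30 trials, random-intercept
SD 0.5); 60 seeds for RT-peak recovery; and 10 replicate two-group studies
(n = 10 per group, true PSS ±40 ms) for the end-to-end power check. These
sizes were chosen so the Monte-Carlo error of each check is small relative
to the tolerance it probes.

## Known limitations

* The probit line inherits a mild shrinkage of extreme PSS values when the
  ±400 ms tails are saturated but not dropped by the asymptote rule (the
  clamped tail probits pull the line toward zero). The ±150 ms bound and
  the complementary pooled-proportion bias measure limit the practical
  impact; the effect vanishes when the asymptote rule fires.
* `r_equivalent` for chi-square tests relies on a participants-based df
  reconstruction; other df conventions exist and would change r by a few
  hundredths.
* The RT-peak model assumes a single symmetric bump with constant residual
  SD; strongly skewed or bimodal RT profiles will be flagged unreliable
  rather than modelled.
* Group comparisons are restricted to the configured matched pairs; the
  pipeline never compares groups across experiments or age structures.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- toj_config(n_perm = 2000, seed = 42)
report <- run_analysis(cfg)
report$group_summary
report$tests
write_report_bundle(report, "toj-report")
```
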