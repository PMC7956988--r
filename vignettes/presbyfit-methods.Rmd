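---
title: "Models and methods in presbyfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in presbyfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`presbyfit` estimates the direct contributions of audibility (pure-tone
average, PTA) and age to aided consonant identification in presbycusis,
using a causal-diagram analysis to justify the regression structure and a
hierarchical Bayesian psychometric model to estimate it. This vignette is
the package's account of the science behind each layer: the assumptions,
the tunable parameters, and the places where a design choice was genuinely
open.

## The psychometric model

The outcome is the number of consonants identified correctly out of 48
trials of a 16-alternative forced-choice task, per listener and listening
condition (quiet, or a spectro-temporally modulated speech-shaped noise).
The model is a binomial regression through a guess/lapse link:

$$N_\text{corr} \sim \text{Binomial}(48,\ p), \qquad
  p = \tfrac{1}{16} + \left(1 - p_\text{miss}\,\text{cond} - \tfrac{1}{16}\right) p'$$

The lower asymptote $1/16$ is the guessing rate of the 16-alternative task.
The lapse probability $p_\text{miss}$ lowers the upper asymptote; it is
structurally zero in quiet (scores at ceiling are common there) and free in
noise, constrained to $[0, 1 - 1/16]$ so the link never decreases. The
logistic component is a standard varying-intercept regression,

$$\text{logit}(p') = \gamma_{0,\text{site}} + \beta_\text{PTA}\,\text{PTA}
  + \beta_\text{age}\,\text{age} + \beta_\text{cond}\,\text{cond}
  + \beta_\text{gender}\,\text{gender} \ (+\ \text{interactions}),$$

with PTA and age standardized by the mean/SD of the fit sample (the
constants are stored in the fit and reused for counterfactual
back-transformation — predictions in natural dB HL units would otherwise
silently drift when a model is applied to a different sample). Noise enters
twice, deliberately: additively on the log-odds scale through
$\beta_\text{cond}$, and multiplicatively through $p_\text{miss}$. One
consequence worth keeping in mind is that the two conditions have different
counterfactual PTA slopes even without any interaction term.

**Priors.** Weights and the grand intercept $\beta_0$ get conservative
$N(0,1)$ priors — an $L_2$-style regularization that shrinks unsupported
weights toward zero in place of stepwise selection. The between-site SD
$\sigma_0$ gets Half-Normal(0, 0.05) (0.05 is the scale/SD parameter),
enforcing pooling across the seven sites. The lapse probability is
$p_\text{miss} = (1 - 1/16)\,u$ with $u \sim \text{Beta}(1,1)$: the weakest
proper prior compatible with the slope-positivity constraint (the Beta
shapes are configurable in `psych_model_spec()`).

**Model variants.** Six term lists are supported: `main_effect`
(PTA + age + cond + gender), `full` (adds all PTA × age × cond
interactions), `pta_only` and `age_only` (each drops one predictor — gender
stays in *every* variant because it is the statistical control required to
block the selection-induced path when PTA or age is omitted, see below),
`esii_full` (the full model with the audibility index replacing PTA) and
`esii_group` (for joint NH/HI fits: the ESII terms plus group, group × age
and group × cond, but neither group × ESII — the NH group's ESII range is
too narrow to identify it — nor any higher-order group interaction). ESII,
when used, is standardized like PTA so weights stay comparable.

**Sampling and parameterization.** Fitting uses Gibbs sampling (JAGS via
`rjags`). Both the centered ($\gamma_{0,s} \sim N(\beta_0, \sigma_0)$) and
non-centered ($\gamma_{0,s} = \beta_0 + \sigma_0 z_s$, $z_s \sim N(0,1)$)
parameterizations of the site intercepts are implemented; they target the
identical posterior, and the test suite checks their agreement. The default
is centered: with dozens of listeners per site the intercepts are strongly
data-identified, which is precisely the regime where the centered form
mixes better under Gibbs updates (the non-centered form is the right choice
for gradient-based samplers and weakly identified hierarchies). Draws are
always stored in the non-centered layout. Convergence is gated on
split-R-hat (threshold 1.01 by default) with effective sample sizes
reported per parameter; a non-converged fit raises an error carrying the
offending statistics rather than returning silently.

## The causal layer

The assumed diagram (`presbycusis_dag()`) has six variables: Age and Gender
drive PTA; Age, PTA and Cond drive the probability of correct
identification (PC); and Age and Gender drive *Inclusion*, a selection node
conditioned by construction in any analysis of the recruited sample.
Selection nodes are implicitly added to every conditioning set — callers
never pass them, because there is no way to "un-condition" on having been
included.

Two consequences matter. First, the only testable implication among the
modelled variables is Gender ⊥ PC given {Age, PTA}; a near-zero posterior
gender weight is therefore a consistency check of the diagram, not a
substantive effect ("Table 2 fallacy"). Second, conditioning on Inclusion
opens the non-causal path Age → Inclusion ← Gender → PTA → PC. A subtlety:
this path *leaves* the exposure, so the classic back-door construction
(delete all edges out of the exposure, then test d-separation) would
wrongly certify the unadjusted age model. `blocks_selection_path()`
therefore uses the generalized adjustment construction — delete only the
first edges of proper causal paths from exposure to outcome — which
correctly reports that the age-only model needs gender as a control while
the model containing both Age and PTA does not.

d-separation itself uses the moralization criterion (ancestral graph,
marry co-parents, delete the conditioning set, test connectivity); the test
suite checks it query-by-query against an independent brute-force oracle
that enumerates undirected paths and applies the blocking rules, over
hundreds of random graphs of up to 7 nodes. Minimal separating sets are
reported with smallest cardinality first, ties broken lexicographically.
The diagram deliberately omits two arrows: the missing-data arrow induced
by floor-censoring (the censored fraction is a few percent, and the bias is
treated as negligible — a censored-likelihood option exists but is off by
default), and a PTA → Inclusion edge (the inclusion rule is PTA-dependent,
but the age/gender collider is the structure the analysis reasons about; a
variant with the edge is available via `presbycusis_dag(pta_inclusion =
TRUE)`).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the study
conditions under which every downstream claim is checked. It emulates a
multi-site clinical sample: HI ages from a truncated normal with mean 69,
SD 10 on [42, 92] (NH: mean 69, SD 7 on [58, 86]); a latent PTA linear in
age with gender-specific slopes (steeper for men, who decline faster) and a
residual SD wide enough that selecting the upper quartile still leaves the
study-like spread; audiograms scattered around the latent PTA along a
sloping high-frequency template whose tilt grows with age; and seven sites
with intercept shifts of SD 0.5 log-odds.

Inclusion mimics the study's percentile rule — an HI candidate's PTA must
exceed an age- and gender-specific cut, approximated linearly in age — plus
the hard limits (age > 40, PTA ≤ 70 dB HL, thresholds ≤ 85 dB HL; NH:
age > 55, PTA ≤ 25). The cut parameters were calibrated once so that the
*included* HI marginals match the study's sample (age ≈ 69 ± 10, PTA
≈ 39 ± 11 dB HL) while the cut's gender-specific age slopes differ from the
generative ones; that mismatch is what makes inclusion probability
non-multiplicative in age and gender, so the included sample exhibits the
age–gender collider dependence that the causal layer predicts, while age
and gender stay independent pre-selection. The two gender-specific
discrepancies are balanced so the aggregate age distribution barely shifts.
Scores below 3/48 are replaced by 3 and flagged (`apply_floor_censoring()`,
idempotent); at the default generative parameters the censored fraction
sits in the low single digits of percent.

What the generator does *not* emulate: per-consonant confusion structure
(only the 48-trial count), the real sites' actual effect values, test-retest
variability, and — most importantly — any listener-level variance beyond
what the model itself contains. Because the generator *is* the fitted model
plus the selection structure, variance-explained statistics on synthetic
data run far higher than on real cohorts, and passing recovery tests shows
correctness of the machinery, not realism of the model for actual
listeners.

## Stimuli and the audibility index

The stimulus layer works entirely at band-level (dB SPL on 32 gammatone
centre frequencies, log-spaced 80–8020 Hz, 1 ERB_N wide); no waveform is
synthesized. Speech is the packaged long-term average speech spectrum shape
anchored at 65 dB SPL in the 1 kHz band, amplified for HI listeners by the
linear prescription rule gain(f) = 0.48·HL(f) + intercept(f) (the intercept
table ships as an editable CSV of approximate published values, and every
gain profile records which table produced it). The masker is a
speech-shaped noise at −4.5 dB broadband SNR — defined against the
*unmodulated* masker power, since the alternative convention is equally
defensible; the amplitude envelope (depth 1 → (1+sin)/2, random starting
phase) is renormalized to preserve mean power precisely so that this SNR
definition stays unambiguous — with an optional spectral ripple silencing
every other gammatone channel (starting parity randomized).

The extended speech intelligibility index is computed per short time frame
(default step 9.4 ms, the highest-band frame length of the standard
extended-index frame scheme) and averaged over time. Per band,
audibility is `clip((speech − disturbance + 15)/30, 0, 1)` where the
disturbance is the power sum of the effective masker and an internal noise
equal to the reference-equivalent threshold level plus the hearing loss;
the frame index is the importance-weighted sum (SPIN weighting by default —
the closest available set for a nonsense-syllable task — with NNS and flat
alternatives). Forward masking extends each masker frame with a trail that
decays linearly in dB against log-time and reaches the listener's own
threshold after a fixed duration (defaults 100 ms, t0 = 10 ms — config
constants chosen to reproduce the qualitative normal-hearing/impaired
asymmetry, and flagged as approximations): because the endpoint is the
threshold, impaired listeners see shallower decays and more masking in the
dips.

Two standard corrections are deliberately omitted by default: upward spread
of masking and the high-level distortion factor. Their omission (and the
approximate packaged tables) means absolute index values for strongly
masked or strongly amplified conditions run higher than a full
standard-conformant implementation would give — near-ceiling quiet values
for aided listeners, and noise-condition values above what the full index
reports, since silenced ripple channels receive no upward-spread masking
here. The package therefore treats the index as a *relative* audibility
predictor; only its structural properties (bounds, monotonicity in SNR and
in threshold elevation, reduction to the single-frame index for steady
maskers, near-1 values for normal-hearing listeners in quiet) are asserted.

## Evaluation choices

* **PSIS-LOO** is implemented in the package (generalized-Pareto tail fit
  by the Zhang–Stephens profile-posterior estimator; tail size
  `min(0.2 S, 3 √S)`; smoothed weights truncated at the raw maximum;
  observations with Pareto k > 0.7 trigger a warning). It is validated two
  ways: against the closed-form leave-one-out predictive of a conjugate
  Beta–Bernoulli model, and against exact refit-based LOO on a small
  cohort. Model-comparison deltas are pointwise elpd differences with
  paired SE — the convention used in comparison tables alongside LOOIC.
* **Variance explained** uses the squared Pearson correlation between
  observed and predicted values on the latent log-odds scale, per
  condition, with a 0.5/0.5 continuity correction before inverting the
  link (48/48 is common in quiet) and probabilities clipped to
  (10⁻³, 1−10⁻³) before the logit; degenerate (constant) predictors return
  0% by convention. The definition is a package choice — several
  pseudo-R² exist — and is isolated in `rho_squared()` so it can be
  swapped.
* **Training deviance** is evaluated at the posterior-mean parameters
  (the posterior-average alternative is available behind a flag).
* **Counterfactual curves** hold every covariate but PTA at its reference
  (fit-sample mean age, female, the across-site mean intercept $\beta_0$);
  slopes are analytic per draw,
  $100\,(1 - p_\text{miss}\text{cond} - 1/16)\,p'(1-p')\,\beta_\text{PTA}/\text{sd}_\text{PTA}$
  percentage points per dB HL, verified against central finite differences.
* **Residual dispersion** inverts the link at each draw's own
  $p_\text{miss}$ (the posterior-mean alternative would understate
  uncertainty in the inversion) before taking the per-group SD of log-odds
  errors.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed, and
`run_pipeline()` writes a manifest (seed, package version, input checksums)
alongside its outputs. The test suite exercises the estimator at the
study's own scale where it matters — parameter recovery uses 384 HI
listeners × 2 conditions with 2 chains × 1500 post-warmup draws — and
reduced scales elsewhere: exact-LOO cross-checks use 20 listeners (41
refits), the simulation-based calibration check uses 24 replicates of 24
listeners with thinned rank statistics, and structural MCMC tests use
50-listener cohorts with short chains and a relaxed convergence gate
(those tests probe interfaces, not mixing). Sampler defaults mirror a
7-chain, 7000-iteration production setting only in documentation; the
package-level defaults (2 × 1500 after 1000 warmup) are sized for the
recovery regime demonstrated in the tests.

## Known limitations

Exact numeric reproduction of the original study's per-participant
audibility indices is out of reach by design (it depends on the recorded
stimuli and a standard-conformant index with spread of masking); the
package matches structure and group-level behaviour instead. The
floor-censoring mechanism is generated but not modelled (censored records
enter the likelihood as observed 3/48 counts). The Gibbs sampler reports no
divergence diagnostics (that concept belongs to Hamiltonian samplers);
split-R-hat, effective sample size and the parameter-recovery and
calibration tests carry the convergence evidence instead.
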