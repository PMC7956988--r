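# presbyfit

Causal and Bayesian modelling of aided consonant identification in
presbycusis.

## The problem

Speech intelligibility declines with age-related hearing loss through two
intertwined routes: **audibility** (elevated pure-tone thresholds, summarized
by the pure-tone average, PTA) and **age-related suprathreshold/cognitive
factors**. Because age and PTA covary strongly, naive regressions cannot
separate their direct effects — and study *inclusion criteria* that depend on
age and gender add a collider ("inclusion into the analysis") that can induce
spurious associations in the recruited sample.

`presbyfit` implements the full analysis chain needed to study this with
consonant-identification scores (counts of correct responses out of 48
trials of a 16-alternative /aCaCa/ task, in quiet and in a spectro-temporally
modulated speech-shaped noise):

* **Causal DAG layer** — d-separation with design-based selection nodes,
  implied conditional independencies, and adjustment-set checks that handle
  selection-opened non-causal paths (`presbycusis_dag()`, `d_separated()`,
  `implied_independencies()`, `blocks_selection_path()`).
* **Synthetic cohort generator** — multi-site cohorts of hearing-impaired
  (HI) and normal-hearing (NH) listeners with age/gender-dependent
  audiograms, a percentile-based inclusion rule that creates the age–gender
  collider, binomial scores, and floor-censoring at chance level
  (`simulate_cohort()` and friends).
* **Stimulus and audibility layer** — linear prescription gain
  (gain = 0.48·HL(f) + intercept(f)), long-term speech spectrum and masker
  band grids (8 Hz sinusoidal amplitude modulation, one-gammatone-in-two
  spectral ripple), and an extended speech intelligibility index (ESII)
  computed in short time frames with a forward-masking extension
  (`cambridge_gain()`, `masker_band_grid()`, `esii()`).
* **Hierarchical Bayesian psychometric model** — the core estimator. Scores
  follow

  ```
  N_corr ~ Binomial(48, p)
  p      = 1/16 + (1 − p_miss·cond − 1/16) · p′
  logit(p′) = γ0[site] + β_PTA·PTA + β_age·age + β_cond·cond + β_gender·gender  (+ interactions)
  ```

  with varying site intercepts γ0[site] ~ N(β0, σ0), N(0,1) priors on the
  weights, Half-Normal(0, 0.05) on σ0, and a flat prior on the rescaled
  lapse probability p_miss ∈ [0, 1 − 1/16] (structurally 0 in quiet). Six
  variants (main-effect, full-interaction, PTA-only, age-only, ESII-based
  full, ESII-based group model) are fitted by MCMC (JAGS) via
  `fit_psychometric()`, which returns a classed model object with `print`,
  `summary`, `coef`, `predict`, `simulate`, `residuals`, `plot` and
  `logLik` methods.
* **Model evaluation** — PSIS-LOO out-of-sample comparison (`psis_loo()`,
  `delta_looic()`, `compare_models()`), variance explained on the latent
  log-odds scale (`rho_squared()`), training deviance, counterfactual
  PTA curves with analytic slopes (`counterfactual_curve()`), posterior
  effect ratios (`effect_ratio()`), and residual dispersion by group
  (`residual_dispersion()`).

## Worked example

```r
library(presbyfit)

g <- presbycusis_dag()
implied_independencies(g)   # -> Gender ⊥ PC | {Age, PTA} (under selection)

ch <- simulate_cohort(cohort_config(n_hi = 384, n_nh = 75), seed = 1)
print(ch)
#> Synthetic cohort: 384 HI + 75 NH participants, 918 score records (seed 1)
#>   HI: age 69.1 (sd 9.2), PTA 39.6 (sd 10.0) dB HL
#>   NH: age 70.8 (sd 6.1), PTA 10.2 (sd 4.9) dB HL

hi <- ch$participants$group == "HI"
fit <- fit_psychometric(ch$participants[hi, ],
                        ch$scores[ch$scores$participant_id %in%
                                  ch$participants$id[hi], ],
                        chains = 2, iter = 1500, warmup = 1000, seed = 1)
print(fit)
#> Hierarchical guess/lapse psychometric model ('main_effect' variant)
#>   768 observations, 7 sites; 2 chains x 1500 draws
#>   posterior means:
#>  beta0    pta    age   cond gender sigma0  pmiss
#>  2.115 -1.359 -0.291 -2.103 -0.047  0.227  0.166

effect_ratio(fit, "pta", "age")
#> PTA/age effect ratio: 4.7 [4.0, 5.5]

psis_loo(fit)
#> PSIS-LOO: elpd_loo = -1721.2 (SE 22.1), LOOIC = 3442.5 (SE 44.2)
#>   Pareto k: max 0.26, 0 of 768 > 0.7
```

Reading the output: the noise condition and hearing loss dominate
identification performance (both ≈ −2.1 and −1.36 log-odds per SD), the
direct age effect is several times weaker (here the posterior ratio of
|β_PTA| to |β_age| is 4.7 with 95% CI [4.0, 5.5]), the lapse probability in
noise is ≈ 17%, and the essentially null gender weight matches the single
conditional independency implied by the causal diagram. `run_pipeline()`
wraps the whole chain (simulate → fit several variants → comparison table →
headline report) under one seed.

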