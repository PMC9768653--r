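---
title: "Methods: scoring, GCP extraction, model selection and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, GCP extraction, model selection and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcpbattery)
```

This vignette documents the statistical methods implemented in `gcpbattery`,
the assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The measurement model: trials to criterion

Each individual attempts three two-choice (or go/detour) cognitive tasks —
associative learning, reversal learning and inhibitory control — and each
task is scored as the number of trials up to and including the final trial of
the first run of six consecutive correct choices (`trials_to_criterion()`).
The best possible score is therefore 6; tests are stopped at 120 trials and
unpassed tasks are recorded as 120 with a censoring flag. Including the
criterion run in the count is forced by the published score range (6–120): a
convention that excluded the run would have a minimum of 0.

The run criterion is justified by chance-level analytics: a random chooser
at p = 0.5 produces six correct in a row in its first six trials with
probability 0.5^6 = 0.015625 (p = 0.016). `chance_pass_probability()`
generalises this to the exact probability of a run of any length within any
number of trials, computed by dynamic programming over current-run-length
states; this is provided for criterion design (e.g. choosing a run length
for a cap) and is validated against exhaustive enumeration in the test
suite. Sessions paused and resumed in the field are concatenated into one
sequence; no session-boundary effects are modelled.

## GCP: a single factor from three tasks

`extract_gcp()` performs an unrotated principal component analysis on the
correlation matrix of the three score columns. The correlation (not
covariance) matrix is forced by the reported loading convention: published
loadings for such batteries are variable–component correlations whose squares
sum to the first eigenvalue, and the eigenvalues sum to the number of tasks.
PC1 is oriented so that its loading sum is non-negative; because all three
variables count *trials* (lower = better), GCP is defined as the individual's
PC1 coordinate with the opposite sign, so that higher GCP means better
performance. GCP values are computed from the unit eigenvector, so their
variance equals the first eigenvalue; any rescaling (e.g. by the square root
of the eigenvalue) is immaterial downstream because predictors are
standardised before regression.

Missing cells are rejected rather than silently dropped: the battery design
is complete-case, and case deletion must be an explicit upstream decision.

### The permutation null for loadings

Could the observed loading pattern arise with independent tasks?
`permutation_null()` permutes the scores *within each task column*
independently (destroying between-task covariance, preserving marginals),
re-runs the PCA, and records the mean and standard deviation (n − 1
denominator) of the PC1 loadings in each of `n_sims` iterations (10 000 by
default). The observed mean is compared with the 2.5–97.5 percentile
interval (linear interpolation) of the simulated means; a shared factor is
indicated when the observed mean exceeds the upper bound, and similar
loadings across tasks push the observed sd toward the interval's lower end.

Two numerical choices matter here:

* **Orientation.** Each iteration's PC1 is sign-oriented by the same rule as
  the observed PCA (loading sum non-negative, the default; first-element
  orientation is available). Without an orientation rule the null mean would
  be exactly 0 by sign symmetry and the comparison would be meaningless.
* **Intervals.** Plain percentile intervals are used, not BCa; with 10 000
  draws of a smooth statistic the difference is negligible and percentile
  intervals are the transparent choice.

Calibration: for a matrix whose columns really are independent, the observed
data are exchangeable with their permutations, so the "mean above the upper
bound" verdict fires with probability just under 2.5% (slightly below, since
exceeding an interpolated 97.5th percentile of 1000 draws is marginally
stricter than ranking in the top 25 of 1001, and score ties shave a little
more). The test suite verifies the empirical rate over 500 independent-column
batteries stays in the 2–9% band around the nominal rate.

### Repeatability

When the battery is replicated, `repeatability()` estimates the intraclass
correlation of GCP from a one-way random-intercept model fitted by REML:
R = between-individual variance / total variance. Uncertainty comes from a
parametric bootstrap (simulate from the fitted model, refit; percentile CI),
and the p-value from permuting individual labels. This is the standard
LMM-based repeatability estimator used in behavioural ecology; at the
replicate design size exercised in the tests (18 individuals × 2 replicates)
its point estimate carries a small downward bias (~0.02 at R = 0.5), well
inside the tolerance checked.

## Determinants of GCP: AICc selection over mixed models

`run_determinant_models()` fits linear mixed models of GCP with group
identity as a random intercept: one model per candidate term (age, sex,
rank, group size, latency to approach, inter-trial interval, body mass,
foraging efficiency, testing order, time of day, study year), plus all
pairwise additive models and pairwise interactions among sex, age, rank,
group size, body mass and study year, plus the null model. Continuous
predictors are centred and scaled (n − 1 sd); categorical predictors use
treatment coding with the alphabetically first level as reference (so sex
effects are reported for males relative to females). Individuals of unknown
sex are excluded, with the count reported.

Choices a reader should know about:

* **ML, not REML, for ranking.** AICc comparisons across different
  fixed-effect structures require comparable likelihoods, which REML does not
  provide; ranked fits therefore use maximum likelihood by default. Because
  field analyses often rank REML fits (many packages' default), a
  `criterion_fit`/`method = "reml"` switch reproduces that behaviour; with it,
  likelihoods are only comparable between models sharing a fixed design, so
  use it knowingly.
* **Parameter count.** `k` counts fixed coefficients + one variance per
  random intercept + (gaussian only) the residual variance; `n` is the number
  of observations. AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1).
* **Top model set.** Models within 2 ΔAICc of the best *and* whose focal
  predictors' 95% Wald CIs (estimate ± 1.96 se) exclude zero enter the top
  set. Focal predictors are the model's highest-order terms: in an
  interaction model the main effects are retained for marginality and are
  conditional effects, so their CIs do not decide the model's support. AICc
  ties are broken toward fewer parameters; the null model is always shown
  for reference.
* **Study year** enters as a factor (discrete field seasons), not a numeric
  trend.
* Non-converged fits are flagged and excluded from defining the best AICc,
  never silently dropped; singular (zero-variance) random effects are
  reported but the fit is kept, matching standard practice.

## Reproductive success: Poisson mixed models

`aggregate_reproduction()` turns per-attempt records into individual-year
totals for dominant breeders: counts are cumulative within a season
(September–August), tenure seasons without successful breeding appear as
explicit zero rows, and a missing recruitment count makes the yearly total
missing — never zero. The ordering recruits ≤ independents ≤ fledglings is
validated.

`run_fitness_models()` fits, for each measure (fledglings, independents,
recruits per year), Poisson log-link mixed models with crossed random
intercepts for season and individual identity: one model each for GCP, age,
sex, group size and drought, the GCP × sex interaction, and the null model;
ranking and the top-set rule are as above. Group identity is deliberately
not a default random term (it overfits at these sizes — a singular fit — in
the motivating dataset); it can be swapped in via the `random` argument as a
robustness check. Rows missing the chosen measure are dropped from that
measure's model set only (listwise per measure, never imputed).

`mean_fledglings_since_age2()` and `fledgling_age_trend()` provide the
cross-sectional companion check: per-individual mean fledglings per year
from age 2 (the earliest breeding age), regressed on age × sex by ordinary
least squares. This is an approximation — a gaussian fit on per-individual
means, not a longitudinal model — and is labelled as such.

## Power analytics

`power_of_f2()` evaluates the power of a fixed-effect F test from the
noncentral F distribution with noncentrality λ = f²(u + v + 1), the
multiple-regression convention; `min_detectable_f2()` inverts it by
bracketed root-finding (tolerance 1e-6). With u = 1 and v = 30 (N = 32
individuals, one predictor) at α = 0.05 and power 0.80 the minimum
detectable effect is f² = 0.26. Texts differ on the noncentrality
convention, so λ = f²·v is exposed via `noncentrality = "v"`; the default is
the convention under which the published 0.26 arises. Minimum detectable
effects for interactions depend on unstated degrees of freedom and are not
pinned to published values.

## The synthetic generator

`synth_config()` + `simulate_roster()` / `simulate_trials()` /
`simulate_breeding()` generate complete, ground-truth-known datasets:

* **Rosters.** Groups of 2–7 adults (one dominant female + one dominant male
  per group), uniform ages on 1–13 years (dominants at least 2), a latent
  factor g ~ N(0, 1) shifted by −0.77 × standardised age for females only,
  and realistic covariate marginals (body mass around 75 g, lognormal
  latencies and inter-trial intervals, balanced testing order within group).
* **Trials.** Per-trial success probability 0.5 + 0.49(1 − exp(−(r t)^s)),
  with log r = base + loading × g + N(0, noise_sd) per task. The 0.99
  ceiling keeps censoring at 120 possible. The shape parameter s (default 8)
  makes learning curves abrupt — close to the all-or-none transitions seen in
  individual-level learning data — which is necessary for the scores to carry
  the strong cross-task correlations observed in real batteries: with the
  single-rate exponential (s = 1) the run-of-six criterion lets slow learners
  pass by luck at p ≈ 0.5 so often that per-task score–latent correlations
  cannot exceed ≈ 0.45 regardless of noise level, capping PC1 near 46%.
  Base rates (0.028, 0.0098, 0.032) and s were calibrated once so that
  default batteries reproduce published per-task means (≈39, ≈62, ≈35
  trials) and PC1 strength (≈59% at n = 38); default loadings (0.8, 0.9,
  0.6) echo the unequal task loadings of real batteries.
* **Breeding.** Dominants hold contiguous tenure windows (mean 4.7 seasons
  within a 10-season study period, matching the field design's 90
  individual-years from ~19 dominants); yearly fledglings are Poisson on a
  log link with β_GCP = −0.18 by default, year and individual random
  intercepts (sd 0.3 each), and a baseline chosen so the marginal mean is
  ≈1.4 fledglings per year. Independence is binomial within fledglings with
  a drought-dependent logit (drought is a Bernoulli flag with probability
  0.3 — the rainfall threshold that defines drought seasons is metadata, not
  simulated weather); recruitment is binomial within independents.

What the generator does *not* emulate: weather and rainfall dynamics,
dispersal and group turnover, helper effects on provisioning, within-group
social networks, session boundaries and motivational fluctuation within a
test, and any mechanistic claim about how the birds actually learn — the
learning-curve family is a generative stand-in chosen for monotonicity,
single-rate parameterisation and calibrated score distributions, not a
cognitive model. Passing recovery tests on these data therefore shows that
the pipeline's estimators recover known effects embedded in realistic score
and count distributions; it cannot show that the field data satisfy the
generative assumptions.

### A note on recovery metrics

Parameter-recovery tests compare extracted GCP with the true latent factor
by *rank* correlation: scores are a monotone but strongly nonlinear
(roughly exponential, and censored) transform of the latent factor, so
Pearson correlation understates recovery of the ordering that downstream
rank-based and standardised analyses use.

### Simulation sizes and determinism

Every generator call is fully determined by `synth_config(seed = ...)`
(stage-offset seeds for roster, trials and breeding), and the pipeline writes
byte-identical outputs for identical configurations. The test suite uses
scaled simulation designs chosen to bound Monte-Carlo error well inside each
tolerance: 500 batteries × 1000 permutations for null calibration, 100
replicates for factor and fitness-effect recovery at n = 200, and 200
datasets for repeatability recovery at 18 × 2.

## Known limitations

* Wald CIs are used throughout the selection machinery; profile or bootstrap
  CIs for mixed models would be slower and are not what the top-set rule was
  defined on.
* The exact likelihood engine behind published selection tables for this
  kind of analysis is typically REML-based; ranked values here use ML by
  default (see above), so AICc values match published tables only to engine
  tolerance, not bit-exactly.
* The recruits model inherits whatever GCP effect acts on fledglings, since
  recruits are nested within fledglings; the generator mirrors this, so
  "GCP affects fledglings only" cannot be expressed as zero marginal
  association for the downstream measures.
* `fledgling_age_trend()` is cross-sectional; it cannot separate
  within-individual ageing from selective appearance/disappearance.
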