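# gcpbattery

Analysis pipeline for cognitive test batteries in wild animals, built for the
common field design in which each individual attempts a small battery of
food-rewarded tasks (associative learning, reversal learning, inhibitory
control) scored as **trials to criterion**: the number of trials needed to
produce six correct choices in a row, capped at 120 trials.

The package is aimed at behavioural ecologists asking three questions of such
data:

1. **Is there a general factor?** Performance scores are correlated across
   tasks (Spearman) and summarised by an unrotated PCA on the correlation
   matrix. The first principal component, sign-flipped so that higher values
   mean better performance, is the individual's *general cognitive
   performance* (GCP). Whether the PC1 loading pattern could arise from
   independent tasks is tested with a within-task permutation null for the
   mean and sd of the loadings, and the stability of GCP across battery
   replicates is quantified by an LMM-based repeatability (intraclass
   correlation) with parametric-bootstrap CIs.
2. **What explains variation in GCP?** Linear mixed models (group identity as
   a random intercept) for candidate individual and social attributes and
   motivation proxies, ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with a
   top-model-set rule (ΔAICc ≤ 2 and focal predictors' 95% CIs excluding
   zero). A noncentral-F power module (`min_detectable_f2()`) reports the
   minimum detectable Cohen's f² for the design.
3. **Does GCP predict fitness?** Yearly counts of fledglings, independent
   offspring and recruits for dominant breeders are aggregated (cumulative
   within season, explicit zeros for unsuccessful tenure years) and modelled
   with Poisson mixed models (crossed year and individual random intercepts)
   over GCP, age, sex, group size, drought and GCP × sex.

Every stage is exercisable without field data through a synthetic-data
generator (`synth_config()`, `simulate_roster()`, `simulate_trials()`,
`simulate_breeding()`) whose ground truth is known, so calibration and
parameter-recovery properties of the whole pipeline are tested, not assumed.

## Worked example

```r
library(gcpbattery)

cfg    <- synth_config(seed = 42)          # 38 individuals, 10 groups
roster <- simulate_roster(cfg)
trials <- simulate_trials(roster, cfg)

sm <- build_score_matrix(trials)
print(sm)
#> Score matrix: 38 individuals x 3 tasks (criterion: run of 6 within 120 trials)
#> 0 individual(s) with missing tasks; 8 censored cell(s)
#>          task     mean min max  n
#> 1 associative 41.68421  11 112 38
#> 2    reversal 61.44737   7 120 38
#> 3  inhibitory 34.68421   8 120 38
```

Each score is the trial index on which the individual completed its first run
of six consecutive correct choices (best possible score 6); cells at 120 are
censored. Extracting GCP and testing the loading pattern against independent
tasks:

```r
g <- extract_gcp(sm)
print(g)
#> GCP extraction (correlation-matrix PCA, 38 individuals)
#> PC1 loadings:
#> associative    reversal  inhibitory
#>       0.814       0.733       0.783
#> eigenvalue: 1.812  % variance: 60.4
#> loading mean: 0.776  sd: 0.04

permutation_null(sm, n_sims = 1000, seed = 1)
#> Permutation null for PC1 loadings (1000 within-task shuffles)
#> mean loading: observed 0.776, null 95% CI 0.016-0.682 -> above CI
#> sd loading:   observed 0.040, null 95% CI 0.091-0.821 -> below CI
```

All three tasks load positively and strongly on PC1, which explains 60.4% of
score variance; the observed mean loading (0.776) exceeds what within-task
shuffling of the same scores can produce (upper bound 0.682), so the shared
axis is not an artefact of the score marginals. The fitness stage, on the
breeding records of the same synthetic population (generating GCP effect
−0.18 on log fledglings):

```r
br <- simulate_breeding(roster, config = cfg)
run_fitness_models(br, measure = "fledglings")$selection
#>                  model k   AICc dAICc top_set                note
#>                    gcp 4 291.79  0.00       *
#>  gcp + sex + gcp x sex 6 293.19  1.40         95% CI crosses zero
#>                   null 3 296.21  4.41
#>             group_size 4 297.82  6.03
#>                drought 4 298.08  6.29
#>                    sex 4 298.34  6.55
#>                    age 4 298.38  6.58
```

The GCP model is the unique top model: individuals with higher cognitive
performance fledge fewer young per year in these data. Finally, the design's
power:

```r
min_detectable_f2(u = 1, v = 30)   # N = 32, one predictor
#> [1] 0.2619719
```

so effects of f² ≥ 0.26 (a moderate effect) are detectable at 80% power.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/gcpbattery.R simulate --out synthetic --seed 1
Rscript inst/cli/gcpbattery.R score --trials synthetic/trials.csv --out scores.csv
Rscript inst/cli/gcpbattery.R gcp --scores scores.csv
Rscript inst/cli/gcpbattery.R run --trials synthetic/trials.csv \
    --roster synthetic/roster.csv --breeding synthetic/breeding.csv --out results/
```

`run` executes the full pipeline (`run_full_pipeline()`): scoring, GCP +
permutation report, determinant selection tables, the three fitness tables
and a manifest with seeds and input hashes; it also accepts a YAML config via
`--config`.

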