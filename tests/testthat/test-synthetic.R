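test_that("simulate_roster satisfies the group-structure invariants", {
  cfg <- synth_config(n_groups = 11, n_individuals = 32, seed = 1)
  ro <- simulate_roster(cfg)
  expect_equal(nrow(ro), 32)
  expect_equal(length(unique(ro$group_id)), 11)
  # exactly one dominant pair (one female + one male) per group
  dom <- ro[ro$rank == "dominant", ]
  expect_equal(nrow(dom), 22)
  tab <- table(dom$group_id, dom$sex)
  expect_true(all(tab == 1))
  # group_size equals the roster count for that group
  counts <- table(ro$group_id)
  expect_equal(unname(ro$group_size), as.integer(counts[ro$group_id]))
  expect_true(all(ro$group_size >= 2 & ro$group_size <= 7))
  expect_true(all(ro$age >= 1))
  expect_true(all(dom$age >= 2))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synth_config(seed = 7)
  expect_identical(simulate_roster(cfg), simulate_roster(cfg))
  ro <- simulate_roster(cfg)
  expect_identical(simulate_trials(ro, cfg), simulate_trials(ro, cfg))
  b1 <- simulate_breeding(ro, config = cfg)
  b2 <- simulate_breeding(ro, config = cfg)
  attr(b1, "truth") <- NULL
  attr(b2, "truth") <- NULL
  expect_identical(b1, b2)
  # and byte-identical CSV output
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic(d1, cfg)
  write_synthetic(d2, cfg)
  for (f in c("roster.csv", "trials.csv", "breeding.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("synth_config rejects infeasible or invalid settings", {
  expect_error(synth_config(n_individuals = 10, n_groups = 6),
               "infeasible dominant pairs")
  expect_error(synth_config(n_individuals = 80, n_groups = 10),
               "max group size")
  expect_error(synth_config(noise_sd = -1), "dispersions")
  expect_error(synth_config(task_loadings = c(0.5, 0.5)), "3 finite")
  expect_error(synth_config(task_loadings = c(0.5, 0.5, 1.5)), "\\[0, 1\\]")
})

test_that("a null female age slope leaves age and the latent factor unrelated", {
  set.seed(71)
  cors <- replicate(30, {
    cfg <- synth_config(female_age_slope = 0, n_individuals = 60,
                        n_groups = 15, seed = sample.int(1e6, 1))
    ro <- simulate_roster(cfg)
    f <- ro$sex == "female"
    cor(ro$age[f], ro$g_true[f])
  })
  expect_lt(abs(mean(cors)), 0.1)
  # and the default negative slope induces a negative correlation in females
  set.seed(72)
  cors_neg <- replicate(15, {
    cfg <- synth_config(n_individuals = 60, n_groups = 15,
                        seed = sample.int(1e6, 1))
    ro <- simulate_roster(cfg)
    f <- ro$sex == "female"
    cor(ro$age[f], ro$g_true[f])
  })
  expect_lt(mean(cors_neg), -0.3)
})

test_that("zero task loadings give uncorrelated task scores", {
  cfg <- synth_config(task_loadings = c(0, 0, 0), n_individuals = 300,
                      n_groups = 75, seed = 8)
  ro <- simulate_roster(cfg)
  sm <- build_score_matrix(simulate_trials(ro, cfg))
  rho <- spearman_pairs(sm)$rho
  expect_true(all(abs(rho) < 0.15))
})

test_that("a near-infinite learning rate yields near-immediate criterion runs", {
  # the success probability is capped at 0.99, so even a perfect learner
  # passes in exactly 6 trials only with probability 0.99^6
  cfg <- synth_config(learning_base_rate = rep(20, 3), noise_sd = 0,
                      n_individuals = 30, n_groups = 10, seed = 9)
  ro <- simulate_roster(cfg)
  sm <- build_score_matrix(simulate_trials(ro, cfg))
  expect_equal(min(sm$scores), 6L)
  expect_gt(mean(sm$scores == 6L), 0.85)
  expect_lt(mean(sm$scores), 7.5)
})

test_that("simulated trial probabilities never exceed the 0.99 ceiling", {
  # the ceiling keeps censoring possible: slow learners must sometimes hit 120
  cfg <- synth_config(seed = 10)
  ro <- simulate_roster(cfg)
  sm <- build_score_matrix(simulate_trials(ro, cfg))
  expect_true(all(sm$scores <= 120L))
  expect_true(all(sm$scores >= 6L))
  expect_equal(unname(sm$scores == 120L & sm$censored), unname(sm$censored))
})

test_that("breeding records respect structure and count ordering", {
  cfg <- synth_config(seed = 11)
  ro <- simulate_roster(cfg)
  br <- simulate_breeding(ro, config = cfg)
  expect_true(all(br$individual_id %in%
                    ro$individual_id[ro$rank == "dominant"]))
  expect_true(all(br$recruits <= br$independents))
  expect_true(all(br$independents <= br$fledglings))
  expect_true(all(br$fledglings >= 0))
  # tenure windows are contiguous seasons
  for (id in unique(br$individual_id)) {
    yrs <- sort(as.integer(sub("S", "", br$year[br$individual_id == id])))
    expect_equal(yrs, seq(min(yrs), max(yrs)))
  }
  expect_error(simulate_breeding(ro, gcp = c(1, 2), config = cfg), "named")
})

test_that("a strongly negative drought effect suppresses independence", {
  cfg <- synth_config(drought_logit_effect = -30, p_drought = 1, seed = 12)
  ro <- simulate_roster(cfg)
  br <- simulate_breeding(ro, config = cfg)
  expect_true(all(br$independents == 0))
})

test_that("the marginal fledgling mean matches the lognormal-Poisson identity", {
  # E[fledglings] = exp(beta0 + (sigma_year^2 + sigma_id^2 + beta_gcp^2)/2)
  cfg <- synth_config(n_individuals = 2000, n_groups = 1000,
                      tenure_years = 99, seed = 13)
  ro <- simulate_roster(cfg)
  br <- simulate_breeding(ro, config = cfg)
  expected <- exp(cfg$beta0_fledge +
                    (cfg$sigma_year^2 + cfg$sigma_id^2 + cfg$beta_gcp^2) / 2)
  expect_equal(mean(br$fledglings), expected, tolerance = 0.1)
})

test_that("a null GCP effect is recovered as centred on zero", {
  set.seed(73)
  est <- replicate(15, {
    cfg <- synth_config(beta_gcp = 0, n_individuals = 60, n_groups = 30,
                        tenure_years = 99, seed = sample.int(1e6, 1))
    ro <- simulate_roster(cfg)
    br <- simulate_breeding(ro, config = cfg)
    fit <- fit_mixed(model_spec("fledglings", "gcp",
                                random = c("year", "individual_id"),
                                family = "poisson"), br)
    fit$coefficients$estimate[fit$coefficients$term == "gcp"]
  })
  expect_lt(abs(mean(est)), 0.05)
})
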