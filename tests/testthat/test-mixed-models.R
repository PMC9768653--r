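test_that("scale_predictors centres and scales with the n-1 denominator", {
  d <- data.frame(x = c(2, 4, 6), y = c(1, 1, 2), lab = c("a", "b", "c"))
  out <- scale_predictors(d, "x")
  expect_equal(out$x, c(-1, 0, 1))
  expect_identical(out$lab, d$lab)
  # idempotent on an already-standardised column
  out2 <- scale_predictors(out, "x")
  expect_equal(out2$x, out$x, tolerance = 1e-12)
  # ages 1..13 end up with unit sd
  ages <- data.frame(age = 1:13)
  expect_equal(sd(scale_predictors(ages, "age")$age), 1)
  expect_error(scale_predictors(d, "lab"), "not numeric")
  expect_error(scale_predictors(data.frame(z = rep(3, 5)), "z"),
               "zero variance")
})

test_that("aicc matches the closed form and guards its domain", {
  expect_equal(aicc(-50, 3, 32), 106 + 24 / 28)
  expect_equal(aicc(-50, 0, 32), 100)
  # converges to AIC as n grows
  expect_equal(aicc(-50, 3, 1e8), -2 * -50 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-50, 3, 4), "n > k \\+ 1")
})

test_that("model_spec validates interactions and labels models", {
  expect_error(model_spec("y", fixed = c("a:b"), random = "g"),
               "main effects")
  expect_error(model_spec("y", fixed = c("a", "b", "a:b", "c", "a:c"),
                          random = "g"), "one interaction")
  expect_error(model_spec("y", fixed = "a", random = character()), "random")
  s <- model_spec("y", fixed = c("a", "b", "a:b"), random = "g")
  expect_equal(s$label, "a + b + a x b")
  expect_equal(model_spec("y", random = "g")$label, "null")
})

test_that("build_candidate_set produces the documented combinatorial counts", {
  pool6 <- letters[1:6]
  set <- build_candidate_set("y", single_terms = pool6,
                             interaction_pool = pool6, random = "g")
  n_inter <- sum(vapply(set, function(s) any(grepl(":", s$fixed)), logical(1)))
  expect_equal(n_inter, choose(6, 2))
  expect_equal(length(set), 1 + 6 + 15)

  tiny <- build_candidate_set("y", single_terms = "age", random = "g")
  expect_equal(vapply(tiny, `[[`, character(1), "label"), c("null", "age"))

  fitness <- build_candidate_set(
    "fledglings", single_terms = c("gcp", "age", "sex", "group_size", "drought"),
    interaction_pool = c("gcp", "sex"), random = c("year", "individual_id"),
    family = "poisson")
  expect_equal(length(fitness), 7)

  full <- build_candidate_set("y", single_terms = pool6,
                              additive_pool = pool6,
                              interaction_pool = pool6, random = "g")
  expect_equal(length(full), 1 + 6 + 15 + 15)
  # no duplicate fixed-term sets
  keys <- vapply(full, function(s) paste(sort(s$fixed), collapse = "|"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("a gaussian fit with zero between-group variance equals OLS", {
  set.seed(51)
  n <- 60
  d <- data.frame(x = rnorm(n), g = rep(letters[1:6], each = 10))
  # residuals centred within groups, so the random-intercept variance
  # estimate collapses to the boundary at 0
  e <- rnorm(n)
  d$y <- 1 + 2 * d$x + (e - ave(e, d$g))
  fit <- fit_mixed(model_spec("y", "x", random = "g"), d)
  expect_true(fit$singular)
  ols <- lm(y ~ x, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("a Laplace Poisson fit with null random variances matches the GLM", {
  set.seed(52)
  n <- 80
  d <- data.frame(x = rnorm(n), g = rep(letters[1:8], each = 10))
  d$y <- rpois(n, exp(0.3 + 0.4 * d$x))
  # responses independent of g, so the variance component collapses to ~0
  fit <- fit_mixed(model_spec("y", "x", random = "g", family = "poisson"), d)
  glm_fit <- glm(y ~ x, data = d, family = poisson())
  expect_lt(fit$variance_components[["g"]], 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(glm_fit)), tolerance = 1e-4)
  expect_equal(fit$coefficients$estimate, unname(coef(glm_fit)),
               tolerance = 1e-4)
})

test_that("fit_mixed reports k, n, AICc and Wald CIs coherently", {
  set.seed(53)
  d <- data.frame(x = rnorm(48), g = rep(letters[1:8], each = 6))
  d$y <- 0.5 * d$x + rnorm(48) + rep(rnorm(8, 0, 0.8), each = 6)
  fit <- fit_mixed(model_spec("y", "x", random = "g"), d)
  expect_equal(fit$k, 2 + 1 + 1)  # intercept + slope, 1 RE variance, residual
  expect_equal(fit$n, 48)
  expect_equal(fit$aicc, aicc(fit$loglik, fit$k, fit$n))
  cf <- fit$coefficients
  expect_equal(cf$ci_lower, cf$estimate - 1.96 * cf$se)
  expect_equal(cf$ci_upper, cf$estimate + 1.96 * cf$se)
  # ML (default) log-likelihood differs from REML
  fit_reml <- fit_mixed(model_spec("y", "x", random = "g"), d,
                        method = "reml")
  expect_false(isTRUE(all.equal(fit$loglik, fit_reml$loglik)))
  expect_error(
    fit_mixed(model_spec("y", c("x", "x2"), random = "g"),
              transform(d, x2 = 2 * x)),
    "rank-deficient")
})

test_that("AICc ordering is invariant to shifting a gaussian response", {
  set.seed(54)
  d <- data.frame(x = rnorm(60), z = rnorm(60),
                  g = rep(letters[1:6], each = 10))
  d$y <- 0.8 * d$x + rnorm(60) + rep(rnorm(6, 0, 0.5), each = 10)
  specs <- build_candidate_set("y", c("x", "z"), random = "g")
  fits1 <- lapply(specs, fit_mixed, data = d)
  d2 <- transform(d, y = y + 100)
  fits2 <- lapply(specs, fit_mixed, data = d2)
  s1 <- select_top_models(fits1)
  s2 <- select_top_models(fits2)
  expect_equal(s1$label, s2$label)
  expect_equal(s1$delta_aicc, s2$delta_aicc, tolerance = 1e-6)
})

test_that("select_top_models applies the delta-AICc and CI rules", {
  make_fit <- function(label, aicc_val, ci_lower, ci_upper, is_null = FALSE) {
    structure(list(
      label = label, k = 4, loglik = -aicc_val / 2, aicc = aicc_val,
      converged = TRUE, singular = FALSE,
      spec = list(fixed = if (is_null) character() else "x"),
      coefficients = data.frame(
        term = c("(Intercept)", if (!is_null) "x"),
        term_label = c("(Intercept)", if (!is_null) "x"),
        estimate = c(0, if (!is_null) mean(c(ci_lower, ci_upper))),
        se = 1,
        ci_lower = c(-1, if (!is_null) ci_lower),
        ci_upper = c(1, if (!is_null) ci_upper))
    ), class = "model_fit")
  }
  fits <- list(
    make_fit("age x sex", 103.53, 0.29, 1.49),
    make_fit("weak", 104.83, -0.2, 0.9),   # within 2 but CI crosses zero
    make_fit("null", 109.46, NA, NA, is_null = TRUE)
  )
  tab <- select_top_models(fits)
  expect_equal(tab$delta_aicc, c(0, 1.30, 5.93), tolerance = 1e-10)
  expect_equal(tab$in_top_set, c(TRUE, FALSE, FALSE))
  expect_true(any(tab$is_null))
  # single model is trivially best
  single <- select_top_models(fits[1])
  expect_equal(single$delta_aicc, 0)
  # exactly one row at delta 0
  expect_equal(sum(tab$delta_aicc == 0), 1)
})

test_that("an age-by-sex latent decline is recovered by ML mixed models", {
  # generator truth: female slope -0.77 per sd age, males flat
  set.seed(55)
  est <- replicate(30, {
    cfg <- synth_config(n_individuals = 500, n_groups = 100,
                        seed = sample.int(1e6, 1))
    ro <- simulate_roster(cfg)
    ro$age_z <- as.numeric(scale(ro$age))
    ro$sex <- factor(ro$sex)  # female = reference
    fit <- fit_mixed(model_spec("g_true", c("age_z", "sex", "age_z:sex"),
                                random = "group_id"), ro)
    fit$coefficients$estimate[fit$coefficients$term == "age_z"]
  })
  expect_lt(abs(mean(est) - (-0.77)), 0.1)
})

test_that("model selection recovers a generating age-by-sex interaction", {
  set.seed(56)
  hits <- replicate(25, {
    cfg <- synth_config(n_individuals = 200, n_groups = 50,
                        seed = sample.int(1e6, 1))
    ro <- simulate_roster(cfg)
    ro$gcp <- ro$g_true
    ro$sex <- factor(ro$sex)
    ro <- scale_predictors(ro, c("age", "group_size"))
    specs <- build_candidate_set(
      "gcp", single_terms = c("age", "sex", "rank", "group_size"),
      additive_pool = c("age", "sex", "rank", "group_size"),
      interaction_pool = c("age", "sex", "rank", "group_size"),
      random = "group_id")
    fits <- lapply(specs, fit_mixed, data = ro)
    tab <- select_top_models(fits)
    top <- tab$label[tab$in_top_set]
    length(top) >= 1 && tab$label[1] == "age + sex + age x sex" &&
      "age + sex + age x sex" %in% top
  })
  expect_gte(mean(hits), 0.8)
})
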