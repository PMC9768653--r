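#' Configuration for the synthetic cognitive-battery generator
#'
#' Parameters of the generative model used throughout the package's
#' calibration and parameter-recovery machinery. Individuals live in groups
#' of 2-7 adults, each with exactly one dominant pair; a latent general
#' factor `g` (dispersion `g_sd`) drives learning speed on all three tasks
#' through `task_loadings`, and declines with standardised age in females
#' only (`female_age_slope`). Per-trial success probability on task `k`
#' follows a saturating curve `0.5 + 0.49 * (1 - exp(-(r * t)^shape))` with
#' `log r = learning_base_rate[k] + task_loadings[k] * g + N(0, noise_sd)`;
#' the 0.99 ceiling keeps censoring at the trial cap possible. Dominant
#' individuals accrue yearly Poisson fledgling counts on a log link with a
#' GCP effect `beta_gcp` and crossed year/individual random intercepts;
#' fledglings survive to independence with a drought-dependent logit
#' probability and recruit with probability `p_recruit`.
#'
#' Defaults are calibrated so that synthetic batteries resemble published
#' field batteries from cooperative-breeding birds: per-task mean scores near
#' 39, 62 and 35 trials with occasional censoring at 120, and a first
#' principal component explaining about 60% of score variance in cohorts of
#' ~38 individuals.
#'
#' @param n_individuals Total adults in the roster.
#' @param n_groups Number of groups (needs `n_individuals >= 2 * n_groups`).
#' @param group_size_range Minimum and maximum adults per group.
#' @param sex_ratio Proportion female among subordinates.
#' @param age_range Minimum and maximum age in years (dominants forced >= 2,
#'   the earliest breeding age).
#' @param g_sd Dispersion of the latent general factor.
#' @param task_loadings Three weights in `[0, 1]` linking the latent factor to
#'   per-task log learning rate.
#' @param female_age_slope Change in the latent factor per s.d. of age, females
#'   only (males 0).
#' @param learning_base_rate Per-task baseline log learning rate.
#' @param learning_shape Shape of the saturating learning curve (1 = simple
#'   exponential; larger values give the abrupt, all-or-none learning curves
#'   seen in individual-level learning data).
#' @param noise_sd Task-specific residual dispersion on the log learning rate.
#' @param beta0_fledge Log baseline fledglings per year.
#' @param beta_gcp Effect of one s.d. of GCP on log fledglings per year.
#' @param sigma_year,sigma_id Dispersions of the year and individual random
#'   intercepts on log fledglings.
#' @param p_drought Yearly probability of a drought season.
#' @param gamma0_indep Baseline logit probability that a fledgling reaches
#'   independence.
#' @param drought_logit_effect Drought effect on the independence logit.
#' @param p_recruit Probability an independent offspring recruits (survives to
#'   one year).
#' @param n_years Number of breeding seasons simulated.
#' @param tenure_years Mean dominant tenure length in years; tenures are
#'   contiguous windows within the study period, and values >= `n_years` give
#'   every dominant the full period.
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 38L,
                         n_groups = 10L,
                         group_size_range = c(2L, 7L),
                         sex_ratio = 0.5,
                         age_range = c(1L, 13L),
                         g_sd = 1,
                         task_loadings = c(0.8, 0.9, 0.6),
                         female_age_slope = -0.77,
                         learning_base_rate = log(c(0.028, 0.0098, 0.032)),
                         learning_shape = 8,
                         noise_sd = 0.3,
                         beta0_fledge = 0.25,
                         beta_gcp = -0.18,
                         sigma_year = 0.3,
                         sigma_id = 0.3,
                         p_drought = 0.3,
                         gamma0_indep = 0.5,
                         drought_logit_effect = -1.0,
                         p_recruit = 0.5,
                         n_years = 10L,
                         tenure_years = 4.7,
                         seed = NULL) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_groups = as.integer(n_groups),
    group_size_range = as.integer(group_size_range),
    sex_ratio = sex_ratio, age_range = as.integer(age_range),
    g_sd = g_sd, task_loadings = task_loadings,
    female_age_slope = female_age_slope,
    learning_base_rate = learning_base_rate,
    learning_shape = learning_shape, noise_sd = noise_sd,
    beta0_fledge = beta0_fledge, beta_gcp = beta_gcp,
    sigma_year = sigma_year, sigma_id = sigma_id,
    p_drought = p_drought, gamma0_indep = gamma0_indep,
    drought_logit_effect = drought_logit_effect, p_recruit = p_recruit,
    n_years = as.integer(n_years), tenure_years = tenure_years,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  disp <- c(g_sd = g_sd, noise_sd = noise_sd, sigma_year = sigma_year,
            sigma_id = sigma_id)
  if (any(disp < 0)) stop("dispersions must be >= 0", call. = FALSE)
  if (length(task_loadings) != 3L || any(!is.finite(task_loadings))) {
    stop("`task_loadings` must be 3 finite weights", call. = FALSE)
  }
  if (any(task_loadings < 0 | task_loadings > 1)) {
    stop("`task_loadings` must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$group_size_range) != 2L ||
      cfg$group_size_range[1L] < 2L ||
      diff(cfg$group_size_range) < 0L) {
    stop("invalid `group_size_range`", call. = FALSE)
  }
  if (cfg$n_individuals < 2L * cfg$n_groups) {
    stop("infeasible dominant pairs: need n_individuals >= 2 * n_groups",
         call. = FALSE)
  }
  if (cfg$n_individuals > cfg$n_groups * cfg$group_size_range[2L]) {
    stop("n_individuals exceeds n_groups * max group size", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

battery_tasks <- c("associative", "reversal", "inhibitory")

# Offset seeds so roster / trials / breeding stages draw from independent,
# individually reproducible streams.
seed_stage <- function(config, stage) {
  if (!is.null(config$seed)) {
    set.seed(config$seed + match(stage, c("roster", "trials", "breeding")) - 1L)
  }
  invisible(NULL)
}

#' Simulate a group-structured roster with a latent general factor
#'
#' Draws group sizes within the configured range (one dominant pair per
#' group), sexes, ages (uniform on `age_range`, dominants at least 2 years),
#' the latent factor `g_true`, and the covariates recorded in field test
#' batteries (body mass, foraging efficiency, latency to approach,
#' inter-trial interval, testing order, time of day, study year). The latent
#' factor is `N(0, g_sd)` shifted by `female_age_slope` times standardised
#' age for females only.
#'
#' @param config A [synth_config()].
#' @return Data frame with one row per individual and attribute
#'   `g_attributes` recording the generating parameters.
#' @export
simulate_roster <- function(config = synth_config()) {
  seed_stage(config, "roster")
  n <- config$n_individuals
  G <- config$n_groups
  lo <- config$group_size_range[1L]
  hi <- config$group_size_range[2L]
  sizes <- rep(max(2L, lo), G)
  spare <- n - sum(sizes)
  while (spare > 0L) {
    open <- which(sizes < hi)
    pick <- open[sample.int(length(open), 1L)]
    sizes[pick] <- sizes[pick] + 1L
    spare <- spare - 1L
  }
  group_id <- rep(sprintf("G%02d", seq_len(G)), sizes)
  rank <- unlist(lapply(sizes, function(s) {
    c("dominant", "dominant", rep("subordinate", s - 2L))
  }))
  sex <- unlist(lapply(sizes, function(s) {
    c("female", "male",
      if (s > 2L) ifelse(stats::runif(s - 2L) < config$sex_ratio,
                         "female", "male"))
  }))
  age <- sample(seq(config$age_range[1L], config$age_range[2L]), n,
                replace = TRUE)
  age[rank == "dominant"] <- pmax(age[rank == "dominant"], 2L)
  g_true <- stats::rnorm(n, 0, config$g_sd)
  age_z <- as.numeric(scale(age))
  g_true <- g_true + config$female_age_slope * age_z * (sex == "female")
  roster <- data.frame(
    individual_id = sprintf("B%03d", seq_len(n)),
    sex = sex,
    age = age,
    rank = rank,
    group_id = group_id,
    group_size = rep(sizes, sizes),
    body_mass = pmin(pmax(stats::rnorm(n, 75, 6), 60), 90),
    foraging_efficiency = stats::rlnorm(n, log(0.25), 0.4),
    latency = stats::rlnorm(n, log(30), 0.6),
    inter_trial_interval = stats::rlnorm(n, log(2), 0.4),
    testing_order = unlist(lapply(sizes, sample.int)),
    time_of_day = sample(c("before-0900", "after-0900"), n, replace = TRUE),
    study_year = sample(c("2018", "2019", "2021"), n, replace = TRUE),
    g_true = g_true,
    stringsAsFactors = FALSE
  )
  attr(roster, "g_attributes") <- list(
    g_sd = config$g_sd, female_age_slope = config$female_age_slope
  )
  roster
}

# Simulate one trial sequence for a given log learning rate. Draws the full
# cap's worth of trials, then truncates at the criterion run.
simulate_sequence <- function(log_rate, shape, spec) {
  t <- seq_len(spec$cap)
  p <- 0.5 + 0.49 * (1 - exp(-(exp(log_rate) * t)^shape))
  outcomes <- as.integer(stats::runif(spec$cap) < p)
  res <- trials_to_criterion(outcomes, spec)
  outcomes[seq_len(if (res$censored) spec$cap else res$score)]
}

#' Simulate trial-level battery outcomes
#'
#' Generates one trial sequence per individual and task. The per-trial
#' success probability follows the saturating learning curve of
#' [synth_config()], and sequences terminate at the passing criterion (run of
#' `spec$run_length` correct) or at the trial cap.
#'
#' @param roster A [simulate_roster()] result (needs `individual_id` and
#'   `g_true`).
#' @param config A [synth_config()].
#' @param spec The [criterion_spec()] used to terminate sequences.
#' @return Long data frame with columns `individual_id`, `task`, `trial`,
#'   `correct`.
#' @export
simulate_trials <- function(roster, config = synth_config(),
                            spec = criterion_spec()) {
  if (nrow(roster) == 0L) stop("empty roster", call. = FALSE)
  seed_stage(config, "trials")
  out <- vector("list", nrow(roster) * 3L)
  idx <- 0L
  for (i in seq_len(nrow(roster))) {
    for (k in seq_len(3L)) {
      log_rate <- config$learning_base_rate[k] +
        config$task_loadings[k] * roster$g_true[i] +
        stats::rnorm(1L, 0, config$noise_sd)
      seq_k <- simulate_sequence(log_rate, config$learning_shape, spec)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        individual_id = roster$individual_id[i],
        task = battery_tasks[k],
        trial = seq_along(seq_k),
        correct = seq_k,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate multi-year breeding records for dominant individuals
#'
#' Yearly fledgling counts for each dominant follow a Poisson log-linear
#' model with intercept `beta0_fledge`, a GCP effect `beta_gcp`, and crossed
#' year and individual random intercepts. Fledglings survive to independence
#' with probability `plogis(gamma0_indep + drought_logit_effect * drought)`
#' and independents recruit with probability `p_recruit`. Each dominant holds
#' tenure for a contiguous window of seasons (mean length `tenure_years`);
#' tenure seasons without success appear as explicit zero rows.
#'
#' @param roster A [simulate_roster()] result.
#' @param gcp Named per-individual GCP values on the standardised scale used
#'   in the fitness models; defaults to the standardised latent factor of the
#'   dominants.
#' @param config A [synth_config()].
#' @return Data frame with one row per dominant individual-year: `
#'   individual_id`, `year` (season label), `sex`, `age`, `group_size`,
#'   `gcp`, `drought`, `fledglings`, `independents`, `recruits`. Ground-truth
#'   effects are attached as attribute `truth`.
#' @export
simulate_breeding <- function(roster, gcp = NULL, config = synth_config()) {
  dom <- roster[roster$rank == "dominant", , drop = FALSE]
  if (nrow(dom) == 0L) stop("roster has no dominant individuals", call. = FALSE)
  seed_stage(config, "breeding")
  if (is.null(gcp)) {
    gcp <- stats::setNames(as.numeric(scale(dom$g_true)), dom$individual_id)
  }
  if (is.null(names(gcp))) {
    stop("`gcp` must be named by individual_id", call. = FALSE)
  }
  missing_gcp <- setdiff(dom$individual_id, names(gcp))
  if (length(missing_gcp)) {
    stop("no gcp value for: ", paste(missing_gcp, collapse = ", "),
         call. = FALSE)
  }
  Y <- config$n_years
  drought <- stats::rbinom(Y, 1L, config$p_drought)
  u_year <- stats::rnorm(Y, 0, config$sigma_year)
  u_id <- stats::setNames(stats::rnorm(nrow(dom), 0, config$sigma_id),
                          dom$individual_id)
  # contiguous tenure windows; tenure_years >= n_years means the full period
  tenure_len <- if (config$tenure_years >= Y) {
    rep(Y, nrow(dom))
  } else {
    1L + stats::rbinom(nrow(dom), Y - 1L,
                       (config$tenure_years - 1) / (Y - 1))
  }
  tenure_start <- vapply(tenure_len, function(l) {
    sample.int(Y - l + 1L, 1L)
  }, integer(1L))
  rows <- vector("list", nrow(dom))
  for (i in seq_len(nrow(dom))) {
    yrs <- seq(tenure_start[i], tenure_start[i] + tenure_len[i] - 1L)
    id <- dom$individual_id[i]
    eta <- config$beta0_fledge + config$beta_gcp * gcp[[id]] +
      u_year[yrs] + u_id[[id]]
    fledglings <- stats::rpois(length(yrs), exp(eta))
    p_ind <- stats::plogis(config$gamma0_indep +
                             config$drought_logit_effect * drought[yrs])
    independents <- stats::rbinom(length(yrs), fledglings, p_ind)
    recruits <- stats::rbinom(length(yrs), independents, config$p_recruit)
    rows[[i]] <- data.frame(
      individual_id = id,
      year = sprintf("S%02d", yrs),
      sex = dom$sex[i],
      age = dom$age[i] + (yrs - yrs[1L]),
      group_size = dom$group_size[i],
      gcp = gcp[[id]],
      drought = drought[yrs],
      fledglings = fledglings,
      independents = independents,
      recruits = recruits,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "truth") <- list(
    beta0_fledge = config$beta0_fledge, beta_gcp = config$beta_gcp,
    u_year = u_year, u_id = u_id, drought = drought, gcp = gcp
  )
  records
}

#' Simulate replicated GCP measurements with a known intraclass correlation
#'
#' Draws `n_individuals` between-individual effects and `n_replicates`
#' within-individual errors with variances chosen so that the intraclass
#' correlation equals `icc` and the total variance is 1. Used to validate the
#' [repeatability()] estimator.
#'
#' @param n_individuals Number of individuals.
#' @param n_replicates Replicates per individual.
#' @param icc True intraclass correlation in `[0, 1)`.
#' @return Long data frame with columns `individual_id`, `replicate`, `gcp`.
#' @export
simulate_gcp_replicates <- function(n_individuals = 18L, n_replicates = 2L,
                                    icc = 0.5) {
  if (icc < 0 || icc >= 1) stop("`icc` must be in [0, 1)", call. = FALSE)
  b <- stats::rnorm(n_individuals, 0, sqrt(icc))
  data.frame(
    individual_id = rep(sprintf("B%03d", seq_len(n_individuals)),
                        each = n_replicates),
    replicate = rep(seq_len(n_replicates), n_individuals),
    gcp = rep(b, each = n_replicates) +
      stats::rnorm(n_individuals * n_replicates, 0, sqrt(1 - icc))
  )
}

#' Split aggregated yearly breeding records into per-attempt rows
#'
#' The inverse of [aggregate_reproduction()] for testing: each individual-year
#' with at least one fledgling is split into one or more breeding attempts
#' whose counts sum to the yearly totals (preserving `recruits <= independents
#' <= fledglings` within every attempt); zero years produce no attempt rows.
#'
#' @param records A [simulate_breeding()] result.
#' @return Data frame of attempts with columns `individual_id`, `year`,
#'   `fledglings`, `independents`, `recruits`.
#' @export
split_into_attempts <- function(records) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    f <- records$fledglings[i]
    if (f == 0L) next
    n_att <- if (f >= 2L) sample(1:2, 1L) else 1L
    # allocate fledglings across attempts, then nest survivors inside them
    alloc <- if (n_att == 1L) f else {
      a <- sample.int(f - 1L, 1L)
      c(a, f - a)
    }
    ind <- records$independents[i]
    rec <- records$recruits[i]
    ind_alloc <- if (n_att == 1L) ind else {
      a <- min(alloc[1L], ind)
      lo <- max(0L, ind - alloc[2L])
      pick <- if (a > lo) sample(lo:a, 1L) else lo
      c(pick, ind - pick)
    }
    rec_alloc <- if (n_att == 1L) rec else {
      a <- min(ind_alloc[1L], rec)
      lo <- max(0L, rec - ind_alloc[2L])
      pick <- if (a > lo) sample(lo:a, 1L) else lo
      c(pick, rec - pick)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = records$individual_id[i],
      year = records$year[i],
      fledglings = alloc,
      independents = ind_alloc,
      recruits = rec_alloc,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(individual_id = character(), year = character(),
                      fledglings = integer(), independents = integer(),
                      recruits = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a full synthetic dataset to disk
#'
#' Generates a roster, trial-level battery data and breeding records under
#' one configuration and writes `roster.csv`, `trials.csv`, `breeding.csv`
#' plus a `truth.json` sidecar with the generating parameters, for use in
#' recovery tests and pipeline runs.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @return Invisibly, the named list of file paths.
#' @export
write_synthetic <- function(dir, config = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roster <- simulate_roster(config)
  trials <- simulate_trials(roster, config)
  breeding <- simulate_breeding(roster, config = config)
  paths <- c(
    roster = file.path(dir, "roster.csv"),
    trials = file.path(dir, "trials.csv"),
    breeding = file.path(dir, "breeding.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(roster, paths[["roster"]], row.names = FALSE)
  utils::write.csv(trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(breeding, paths[["breeding"]], row.names = FALSE)
  truth <- attr(breeding, "truth")
  truth$config <- unclass(config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(as.list(paths))
}
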