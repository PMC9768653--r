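#' Pairwise Spearman rank correlations between task scores
#'
#' Rank correlations (average ranks for ties) between every pair of task
#' score columns, with two-sided p-values from the t-distribution
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. Lower scores mean faster learning, so positive correlations
#' indicate that performance covaries across tasks.
#'
#' @param scores A [build_score_matrix()] result or numeric matrix
#'   (individuals x tasks). Only complete rows are used.
#' @return Data frame with columns `task1`, `task2`, `n`, `rho`, `p`.
#' @export
spearman_pairs <- function(scores) {
  x <- score_values(scores)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 complete individuals", call. = FALSE)
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stop("constant score column: rank correlation undefined", call. = FALSE)
  }
  tasks <- colnames(x)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(x)))
  pairs <- utils::combn(ncol(x), 2L)
  res <- apply(pairs, 2L, function(ij) {
    rho <- stats::cor(rank(x[, ij[1L]]), rank(x[, ij[2L]]))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    c(rho = rho, p = p)
  })
  data.frame(
    task1 = tasks[pairs[1L, ]],
    task2 = tasks[pairs[2L, ]],
    n = n,
    rho = res["rho", ],
    p = res["p", ],
    row.names = NULL
  )
}

# Correlation-matrix PCA returning eigenvalues, the PC1 unit eigenvector
# oriented by `orient`, and loadings (eigenvector * sqrt(eigenvalue)).
pca_pc1 <- function(x, orient = c("loading_sum", "first_element")) {
  orient <- match.arg(orient)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  v1 <- eig$vectors[, 1L]
  flip <- switch(orient,
    loading_sum = sum(v1) < 0,
    first_element = v1[1L] < 0
  )
  if (flip) v1 <- -v1
  loadings <- v1 * sqrt(eig$values[1L])
  list(values = eig$values, vector = v1, loadings = loadings)
}

#' Extract the general cognitive performance (GCP) factor
#'
#' Unrotated principal component analysis on the correlation matrix of
#' trials-to-criterion scores (columns standardised to unit variance). PC1 is
#' oriented so that the sum of its loadings is non-negative; because scores
#' count trials, a positive loading means slow learning, so GCP is defined as
#' the individual's PC1 coordinate with the opposite sign: higher GCP means
#' fewer trials to criterion, i.e. better performance. Loadings are reported
#' as variable-component correlations (eigenvector scaled by the square root
#' of the eigenvalue), so their squares sum to the first eigenvalue.
#'
#' @param scores A [build_score_matrix()] result or numeric matrix. All rows
#'   must be complete; incomplete rows raise an error so that case deletion is
#'   always an explicit, upstream decision.
#' @return An object of class `gcp_result` with elements `eigenvalues`,
#'   `pc1_loadings`, `pct_variance_pc1`, `gcp` (named vector, one value per
#'   individual, computed from the unit eigenvector so `var(gcp)` equals the
#'   first eigenvalue), `loading_mean` and `loading_sd` (n - 1 denominator).
#' @export
extract_gcp <- function(scores) {
  x <- score_values(scores)
  if (anyNA(x)) {
    bad <- rownames(x)[!stats::complete.cases(x)]
    stop("incomplete battery for: ", paste(bad, collapse = ", "),
         "; drop these individuals explicitly before extraction",
         call. = FALSE)
  }
  if (nrow(x) < 4L) stop("need at least 4 complete individuals", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("constant score column", call. = FALSE)
  pc <- pca_pc1(x)
  z <- scale(x)
  gcp <- as.numeric(-(z %*% pc$vector))
  names(gcp) <- rownames(x)
  structure(
    list(
      eigenvalues = pc$values,
      pc1_loadings = stats::setNames(pc$loadings, colnames(x)),
      pct_variance_pc1 = pc$values[1L] / ncol(x) * 100,
      gcp = gcp,
      loading_mean = mean(pc$loadings),
      loading_sd = stats::sd(pc$loadings),
      n = nrow(x)
    ),
    class = "gcp_result"
  )
}

#' @export
print.gcp_result <- function(x, digits = 3, ...) {
  cat("GCP extraction (correlation-matrix PCA,", x$n, "individuals)\n")
  cat("PC1 loadings:\n")
  print(round(x$pc1_loadings, digits))
  cat("eigenvalue:", round(x$eigenvalues[1L], digits),
      " % variance:", round(x$pct_variance_pc1, 2), "\n")
  cat("loading mean:", round(x$loading_mean, digits),
      " sd:", round(x$loading_sd, digits), "\n")
  invisible(x)
}

#' Within-task permutation null for PC1 loadings
#'
#' Tests whether the observed mean and standard deviation of the PC1 loadings
#' deviate from what independent tasks would produce. Each iteration
#' independently permutes the scores within every task column (destroying
#' between-task covariance while preserving marginals), re-runs the
#' correlation PCA, orients PC1 by the same rule as [extract_gcp()], and
#' records the mean and sd (n - 1) of the PC1 loadings. 95% intervals are the
#' 2.5 and 97.5 percentiles with linear interpolation. A shared factor is
#' indicated when the observed mean loading exceeds the upper bound of the
#' simulated-mean interval; similar loadings across tasks push the observed sd
#' toward the lower end of the simulated-sd interval.
#'
#' @param scores A [build_score_matrix()] result or complete numeric matrix.
#' @param n_sims Number of permutation iterations (>= 100; default 10000).
#' @param seed Optional integer seed for reproducible permutations.
#' @param orient PC1 orientation rule applied to every iteration:
#'   `"loading_sum"` (default; sum of loadings made non-negative) or
#'   `"first_element"`. Without an orientation rule the null mean would be 0
#'   by sign symmetry.
#' @return An object of class `gcp_permnull` with observed statistics, the
#'   simulated 95% intervals, verdict flags and the draws themselves.
#' @export
permutation_null <- function(scores, n_sims = 10000L, seed = NULL,
                             orient = c("loading_sum", "first_element")) {
  orient <- match.arg(orient)
  if (n_sims < 100L) {
    stop("`n_sims` must be >= 100 for stable percentile bounds",
         call. = FALSE)
  }
  x <- score_values(scores)
  if (anyNA(x)) stop("scores contain missing cells", call. = FALSE)
  obs <- extract_gcp(x)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  sim_mean <- numeric(n_sims)
  sim_sd <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    perm <- apply(x, 2L, function(col) col[sample.int(n)])
    pc <- pca_pc1(perm, orient = orient)
    sim_mean[s] <- mean(pc$loadings)
    sim_sd[s] <- stats::sd(pc$loadings)
  }
  ci_mean <- stats::quantile(sim_mean, c(0.025, 0.975), names = FALSE, type = 7)
  ci_sd <- stats::quantile(sim_sd, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(
      n_sims = n_sims,
      observed_mean = obs$loading_mean,
      observed_sd = obs$loading_sd,
      ci_mean = ci_mean,
      ci_sd = ci_sd,
      mean_above_ci = obs$loading_mean > ci_mean[2L],
      sd_below_ci = obs$loading_sd < ci_sd[1L],
      sd_within_ci = obs$loading_sd >= ci_sd[1L] && obs$loading_sd <= ci_sd[2L],
      sim_mean = sim_mean,
      sim_sd = sim_sd,
      seed = seed,
      orient = orient
    ),
    class = "gcp_permnull"
  )
}

#' @export
print.gcp_permnull <- function(x, digits = 3, ...) {
  cat("Permutation null for PC1 loadings (", x$n_sims, " within-task shuffles)\n",
      sep = "")
  cat(sprintf("mean loading: observed %.3f, null 95%% CI %.3f-%.3f -> %s\n",
              x$observed_mean, x$ci_mean[1L], x$ci_mean[2L],
              if (x$mean_above_ci) "above CI" else "within/below CI"))
  cat(sprintf("sd loading:   observed %.3f, null 95%% CI %.3f-%.3f -> %s\n",
              x$observed_sd, x$ci_sd[1L], x$ci_sd[2L],
              if (x$sd_below_ci) "below CI"
              else if (x$sd_within_ci) "within CI" else "above CI"))
  invisible(x)
}

#' Repeatability (intraclass correlation) of GCP across battery replicates
#'
#' Fits a one-way random-intercept decomposition `value ~ 1 + (1 |
#' individual)` by restricted maximum likelihood and estimates repeatability
#' as `R = sigma2_between / (sigma2_between + sigma2_within)`. The standard
#' error and 95% CI come from a parametric bootstrap (simulate from the
#' fitted model, refit, percentile interval); the p-value from permuting
#' individual labels (proportion of permuted R at or above the observed,
#' add-one corrected).
#'
#' @param gcp_long Data frame with columns `individual_id` and `gcp`, one row
#'   per individual x replicate.
#' @param nboot Parametric bootstrap draws for se / CI (0 skips).
#' @param nperm Label permutations for the p-value (0 skips).
#' @param seed Optional integer seed.
#' @return An object of class `repeatability_result` with `R`, `se`, `ci`,
#'   `p`, the variance components, and the numbers of individuals and
#'   observations.
#' @export
repeatability <- function(gcp_long, nboot = 1000L, nperm = 1000L, seed = NULL) {
  if (!all(c("individual_id", "gcp") %in% names(gcp_long))) {
    stop("`gcp_long` needs columns `individual_id` and `gcp`", call. = FALSE)
  }
  gcp_long <- gcp_long[!is.na(gcp_long$gcp), ]
  id <- factor(gcp_long$individual_id)
  reps <- table(id)
  if (sum(reps >= 2L) < 5L) {
    stop("insufficient replication: need >= 2 replicates for >= 5 individuals",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(gcp = gcp_long$gcp, individual_id = id)
  point_R <- function(d) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(gcp ~ 1 + (1 | individual_id), data = d, REML = TRUE)
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vb <- vc$vcov[vc$grp == "individual_id"]
    vw <- vc$vcov[vc$grp == "Residual"]
    list(R = vb / (vb + vw), fit = fit, var_between = vb, var_within = vw)
  }
  obs <- point_R(dat)
  boot_R <- se <- ci <- NULL
  if (nboot > 0L) {
    boot_R <- vapply(seq_len(nboot), function(i) {
      sim <- stats::simulate(obs$fit)[[1L]]
      point_R(data.frame(gcp = sim, individual_id = dat$individual_id))$R
    }, numeric(1L))
    se <- stats::sd(boot_R)
    ci <- stats::quantile(boot_R, c(0.025, 0.975), names = FALSE)
  }
  p <- NA_real_
  if (nperm > 0L) {
    perm_R <- vapply(seq_len(nperm), function(i) {
      point_R(data.frame(gcp = dat$gcp,
                         individual_id = sample(dat$individual_id)))$R
    }, numeric(1L))
    p <- (1 + sum(perm_R >= obs$R)) / (nperm + 1)
  }
  structure(
    list(R = obs$R, se = se, ci = ci, p = p,
         var_between = obs$var_between, var_within = obs$var_within,
         n_individuals = nlevels(id), n_obs = nrow(dat),
         nboot = nboot, nperm = nperm),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability: R = %.2f", x$R))
  if (!is.null(x$se)) {
    cat(sprintf("; s.e. = %.2f; 95%% CI = %.2f; %.2f", x$se, x$ci[1L], x$ci[2L]))
  }
  if (!is.na(x$p)) cat(sprintf("; p = %.3g", x$p))
  cat(sprintf("\n(%d individuals, %d observations)\n", x$n_individuals, x$n_obs))
  invisible(x)
}
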