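#' Candidate-model analysis of GCP determinants
#'
#' Ranks linear mixed models of GCP on individual attributes (age, sex, rank,
#' group size), proxies of motivation (latency to approach, inter-trial
#' interval, body mass, foraging efficiency), testing order, time of day and
#' study year - each with group identity as a random intercept - by AICc,
#' and applies the top-model-set rule. The candidate set contains the null
#' model, one model per single term, and all pairwise additive models and
#' pairwise interactions among sex, age, rank, group size, body mass and
#' study year. Individuals of unknown sex are excluded (their number is
#' reported), and continuous predictors are standardised.
#'
#' @param data One row per individual with a `gcp` column, a `group_id`
#'   grouping factor, and the candidate predictor columns; missing columns
#'   are silently omitted from the candidate set.
#' @param method Likelihood used for ranking: `"ml"` (default, comparable
#'   likelihoods across fixed structures) or `"reml"`.
#' @return A list with `selection`, `coefficients` (top-set fixed effects),
#'   `fits`, `n_used` and `n_dropped_unknown_sex`.
#' @export
run_determinant_models <- function(data, method = c("ml", "reml")) {
  method <- match.arg(method)
  if (!all(c("gcp", "group_id") %in% names(data))) {
    stop("`data` needs `gcp` and `group_id` columns", call. = FALSE)
  }
  n_unknown <- if ("sex" %in% names(data)) sum(is.na(data$sex)) else 0L
  if (n_unknown > 0L) data <- data[!is.na(data$sex), , drop = FALSE]
  singles <- c("age", "sex", "rank", "group_size", "latency",
               "inter_trial_interval", "body_mass", "foraging_efficiency",
               "testing_order", "time_of_day", "study_year")
  singles <- intersect(singles, names(data))
  pool <- intersect(c("sex", "age", "rank", "group_size", "body_mass",
                      "study_year"), singles)
  continuous <- intersect(
    c("age", "group_size", "latency", "inter_trial_interval", "body_mass",
      "foraging_efficiency", "testing_order"), singles)
  data <- scale_predictors(data, continuous)
  for (col in c("sex", "rank", "time_of_day", "study_year", "group_id")) {
    if (col %in% names(data)) data[[col]] <- factor(data[[col]])
  }
  specs <- build_candidate_set(
    response = "gcp", single_terms = singles,
    additive_pool = pool, interaction_pool = pool,
    random = "group_id", family = "gaussian"
  )
  fits <- lapply(specs, fit_mixed, data = data, method = method)
  selection <- select_top_models(fits)
  list(
    selection = selection,
    coefficients = top_set_coefficients(selection),
    fits = fits,
    n_used = nrow(data),
    n_dropped_unknown_sex = n_unknown,
    method = method
  )
}
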