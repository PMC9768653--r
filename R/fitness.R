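#' Aggregate breeding attempts into individual-year records
#'
#' Sums counts over all breeding attempts a dominant individual made within a
#' season (cumulative rule), and inserts explicit zero rows for tenure
#' seasons in which a dominant did not breed successfully. Attempts may only
#' reference individuals present in the tenure table (offspring are
#' attributed to the dominant pair at the time of the attempt). A missing
#' recruitment count in any attempt makes the yearly recruit total missing -
#' missing is never collapsed to zero.
#'
#' @param attempts Data frame of breeding attempts with columns
#'   `individual_id`, `year`, `fledglings`, `independents`, `recruits`
#'   (recruits may be `NA`).
#' @param tenure Data frame of dominant individual-years defining when each
#'   individual held a breeding position, with columns `individual_id`,
#'   `year` and any individual/season covariates to carry through (e.g.
#'   `sex`, `age`, `group_size`, `drought`).
#' @return Data frame with one row per tenure individual-year: the tenure
#'   covariates plus cumulative `fledglings`, `independents`, `recruits`.
#' @export
aggregate_reproduction <- function(attempts, tenure) {
  need_a <- c("individual_id", "year", "fledglings", "independents", "recruits")
  if (!all(need_a %in% names(attempts))) {
    stop("`attempts` needs columns: ", paste(need_a, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("individual_id", "year") %in% names(tenure))) {
    stop("`tenure` needs `individual_id` and `year`", call. = FALSE)
  }
  key_t <- paste(tenure$individual_id, tenure$year, sep = "\r")
  if (anyDuplicated(key_t)) {
    stop("duplicate individual-year rows in `tenure`", call. = FALSE)
  }
  key_a <- paste(attempts$individual_id, attempts$year, sep = "\r")
  orphan <- !key_a %in% key_t
  if (any(orphan)) {
    stop("attempt(s) attributed outside dominant tenure: ",
         paste(unique(attempts$individual_id[orphan]), collapse = ", "),
         call. = FALSE)
  }
  with_counts <- function(col) {
    tot <- tapply(attempts[[col]], key_a, function(x) {
      if (anyNA(x)) NA_integer_ else as.integer(sum(x))
    })
    out <- rep(0L, nrow(tenure))
    m <- match(names(tot), key_t)
    out[m] <- unlist(tot)
    out
  }
  records <- tenure
  records$fledglings <- with_counts("fledglings")
  records$independents <- with_counts("independents")
  records$recruits <- with_counts("recruits")
  bad <- stats::na.omit(which(
    records$recruits > records$independents |
      records$independents > records$fledglings
  ))
  if (length(bad)) {
    stop("count ordering violated (recruits <= independents <= fledglings) ",
         "in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

#' Mean fledglings per year from two years of age
#'
#' Averages yearly cumulative fledgling counts over the seasons in which an
#' individual was at least 2 years old - the earliest breeding age - giving
#' one value per individual. Individuals with no eligible seasons get `NA`.
#'
#' @param records Individual-year records with columns `individual_id`, `age`
#'   and `fledglings` (e.g. from [aggregate_reproduction()] or
#'   [simulate_breeding()]).
#' @return Data frame with columns `individual_id`, `n_years`,
#'   `mean_fledglings`, plus `sex` and mean `age` when present in `records`.
#' @export
mean_fledglings_since_age2 <- function(records) {
  need <- c("individual_id", "age", "fledglings")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(records$individual_id)
  out <- lapply(ids, function(id) {
    r <- records[records$individual_id == id & records$age >= 2, ,
                 drop = FALSE]
    data.frame(
      individual_id = id,
      n_years = nrow(r),
      mean_fledglings = if (nrow(r)) mean(r$fledglings) else NA_real_,
      sex = if ("sex" %in% names(records))
        records$sex[records$individual_id == id][1L] else NA_character_,
      age = if (nrow(r)) mean(r$age) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Age-by-sex trend in mean yearly fledgling output
#'
#' Gaussian linear fit of per-individual mean fledglings per year (from age
#' 2) on age, sex and their interaction. This is a deliberately simple
#' cross-sectional check of whether the attributes that structure cognitive
#' performance also structure average reproductive output; it is an
#' approximation, not a longitudinal model.
#'
#' @param means A [mean_fledglings_since_age2()] result with non-missing `sex`
#'   and `age`.
#' @return The `lm` fit.
#' @export
fledgling_age_trend <- function(means) {
  means <- means[!is.na(means$mean_fledglings) & !is.na(means$sex), ]
  means$sex <- factor(means$sex)
  stats::lm(mean_fledglings ~ age * sex, data = means)
}

#' Fitness model set for one reproduction measure
#'
#' Fits the candidate Poisson mixed models relating a yearly reproduction
#' count (fledglings, independents or recruits) to GCP, age, sex, group size
#' and drought, plus the GCP-by-sex interaction, with year and individual
#' identity as crossed random intercepts, and ranks them by AICc with the
#' top-model-set rule. Continuous predictors are standardised before
#' fitting. Rows with a missing value of the chosen measure are dropped from
#' this measure's model set only (listwise per measure, never imputed).
#'
#' @param records Individual-year records with columns `individual_id`,
#'   `year`, `sex`, `age`, `group_size`, `drought` and the measure column.
#' @param gcp Named per-individual GCP vector, or `NULL` if `records` already
#'   contains a `gcp` column.
#' @param measure One of `"fledglings"`, `"independents"`, `"recruits"`.
#' @param random Random-intercept terms; the default crossed year/individual
#'   structure can be swapped for group identity via this argument.
#' @return A list with `selection` (a [select_top_models()] table),
#'   `coefficients` (top-set fixed effects), `fits`, `measure` and `n_used`.
#' @export
run_fitness_models <- function(records, gcp = NULL,
                               measure = c("fledglings", "independents",
                                           "recruits"),
                               random = c("year", "individual_id")) {
  measure <- match.arg(measure)
  if (!measure %in% names(records)) {
    stop("records lack the `", measure, "` column", call. = FALSE)
  }
  if (!is.null(gcp)) {
    if (is.null(names(gcp))) stop("`gcp` must be named", call. = FALSE)
    records$gcp <- as.numeric(gcp[records$individual_id])
  }
  if (!"gcp" %in% names(records)) {
    stop("no GCP values: supply `gcp` or a `gcp` column", call. = FALSE)
  }
  dat <- records[!is.na(records[[measure]]), , drop = FALSE]
  dat$sex <- factor(dat$sex)
  dat$drought <- factor(dat$drought)
  dat <- scale_predictors(dat, c("gcp", "age", "group_size"))
  specs <- build_candidate_set(
    response = measure,
    single_terms = c("gcp", "age", "sex", "group_size", "drought"),
    interaction_pool = c("gcp", "sex"),
    random = random,
    family = "poisson"
  )
  fits <- lapply(specs, fit_mixed, data = dat)
  selection <- select_top_models(fits)
  list(
    selection = selection,
    coefficients = top_set_coefficients(selection),
    fits = fits,
    measure = measure,
    n_used = nrow(dat),
    n_individuals = length(unique(dat$individual_id))
  )
}
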