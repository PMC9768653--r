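#' Centre and scale continuous predictors
#'
#' Centres each named column on its mean and divides by one standard
#' deviation (n - 1 denominator), so coefficient estimates are comparable
#' across predictors. Categorical columns are left untouched.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric column names to standardise.
#' @return `data` with the named columns standardised.
#' @export
scale_predictors <- function(data, columns) {
  for (col in columns) {
    if (!col %in% names(data)) stop("no column `", col, "`", call. = FALSE)
    x <- data[[col]]
    if (!is.numeric(x)) stop("column `", col, "` is not numeric", call. = FALSE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      stop("column `", col, "` has zero variance", call. = FALSE)
    }
    data[[col]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

#' Specify a mixed model for AICc ranking
#'
#' A model is its response, a set of fixed-effect terms (main effects plus at
#' most one interaction written `"a:b"`, whose main effects must also be
#' present), random intercepts, and an error family. An empty `fixed` gives
#' the intercept-only (null) model.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (may be empty).
#' @param random Character vector of grouping factors (random intercepts,
#'   non-empty).
#' @param family `"gaussian"` or `"poisson"` (log link).
#' @param label Optional display label; defaults to the fixed terms, with
#'   `"a:b"` rendered as `"a x b"`, or `"null"` for the intercept-only model.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(), random,
                       family = c("gaussian", "poisson"), label = NULL) {
  family <- match.arg(family)
  if (length(random) == 0L) stop("`random` must be non-empty", call. = FALSE)
  inter <- grep(":", fixed, value = TRUE)
  if (length(inter) > 1L) {
    stop("at most one interaction term is allowed", call. = FALSE)
  }
  for (term in inter) {
    mains <- strsplit(term, ":", fixed = TRUE)[[1L]]
    if (!all(mains %in% fixed)) {
      stop("interaction `", term, "` requires its main effects in `fixed`",
           call. = FALSE)
    }
  }
  if (is.null(label)) {
    label <- if (length(fixed) == 0L) "null" else
      paste(gsub(":", " x ", fixed, fixed = TRUE), collapse = " + ")
  }
  structure(
    list(response = response, fixed = fixed, random = random,
         family = family, label = label),
    class = "model_spec"
  )
}

spec_formula <- function(spec) {
  rhs <- c(if (length(spec$fixed)) spec$fixed else "1",
           paste0("(1 | ", spec$random, ")"))
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`. The correction is
#' undefined when `n <= k + 1`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-50, 3, 32)  # 106 + 24/28
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a mixed model under a `model_spec`
#'
#' Gaussian models are fitted by maximum likelihood by default (`method =
#' "ml"`) so that log-likelihoods, and hence AICc, are comparable across
#' fixed-effect structures; `method = "reml"` is available for variance
#' estimation on a fixed design. Poisson models use the Laplace-approximated
#' marginal likelihood over (possibly crossed) random intercepts with a log
#' link. Wald standard errors and normal 95% CIs (estimate +/- 1.96 se) are
#' reported for every fixed coefficient. The parameter count `k` is the
#' number of fixed coefficients plus one variance per random intercept plus,
#' for gaussian models, the residual variance. Non-convergence and singular
#' variance estimates are reported via flags - fits are never silently
#' dropped.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing all referenced columns; rows with
#'   missing values in those columns are removed (with a count retrievable
#'   from the result).
#' @param method `"ml"` (default) or `"reml"`; gaussian only.
#' @return An object of class `model_fit` with `loglik`, `k`, `n`, `aicc`,
#'   `coefficients` (term, estimate, se, ci_lower, ci_upper),
#'   `variance_components`, `converged`, `singular`, `label` and the
#'   underlying `lme4` fit.
#' @export
fit_mixed <- function(spec, data, method = c("ml", "reml")) {
  method <- match.arg(method)
  vars <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$random))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[keep, , drop = FALSE]
  for (g in spec$random) {
    dat[[g]] <- factor(dat[[g]])
    if (nlevels(dat[[g]]) < 2L) {
      stop("grouping factor `", g, "` has fewer than 2 levels", call. = FALSE)
    }
  }
  if (spec$family == "poisson") {
    y <- dat[[spec$response]]
    if (any(y < 0) || any(y != round(y))) {
      stop("poisson response must be non-negative integers", call. = FALSE)
    }
  }
  form <- spec_formula(spec)
  converged <- TRUE
  fit <- withCallingHandlers(
    if (spec$family == "gaussian") {
      lme4::lmer(form, data = dat, REML = (method == "reml"))
    } else {
      lme4::glmer(form, data = dat, family = stats::poisson())
    },
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  beta <- lme4::fixef(fit)
  if (anyNA(beta) || length(beta) < length(spec$fixed) + 1L) {
    stop("rank-deficient fixed-effect design for model `", spec$label, "`",
         call. = FALSE)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  asgn <- attr(lme4::getME(fit, "X"), "assign")
  term_labels <- attr(stats::terms(lme4::nobars(form)), "term.labels")
  coefs <- data.frame(
    term = names(beta),
    term_label = ifelse(asgn == 0L, "(Intercept)", term_labels[pmax(asgn, 1L)]),
    estimate = as.numeric(beta),
    se = as.numeric(se),
    ci_lower = as.numeric(beta - 1.96 * se),
    ci_upper = as.numeric(beta + 1.96 * se),
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- stats::setNames(vc$vcov, vc$grp)
  n <- stats::nobs(fit)
  k <- length(beta) + length(spec$random) +
    as.integer(spec$family == "gaussian")
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(
      loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
      coefficients = coefs, variance_components = vcomp,
      converged = converged, singular = lme4::isSingular(fit),
      label = spec$label, spec = spec, method = method,
      n_dropped = sum(!keep), fit = fit
    ),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Model `%s` (%s, %s): logLik %.2f, k = %d, n = %d, AICc %.2f%s\n",
              x$label, x$spec$family, x$method, x$loglik, x$k, x$n, x$aicc,
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$singular) " [singular]" else ""))
  print(cbind(x$coefficients[1L],
              round(x$coefficients[-1L], digits)), row.names = FALSE)
  invisible(x)
}

#' Build a candidate model set
#'
#' Constructs the intercept-only (null) model, one model per single term, all
#' pairwise additive models over `additive_pool`, and all pairwise
#' interactions (with their main effects) over `interaction_pool`, without
#' duplicates.
#'
#' @param response Response column name.
#' @param single_terms Terms fitted one at a time.
#' @param additive_pool Terms combined in all pairwise additive models
#'   (default none).
#' @param interaction_pool Terms combined in all pairwise interaction models
#'   (default none).
#' @param random Random-intercept grouping factors, shared by every model.
#' @param family `"gaussian"` or `"poisson"`.
#' @return A list of [model_spec()] objects, the null model first.
#' @export
build_candidate_set <- function(response, single_terms,
                                additive_pool = character(),
                                interaction_pool = character(),
                                random, family = "gaussian") {
  if (length(single_terms) == 0L) {
    stop("`single_terms` must be non-empty", call. = FALSE)
  }
  fixed_sets <- list(character())
  for (term in single_terms) fixed_sets <- c(fixed_sets, list(term))
  if (length(additive_pool) >= 2L) {
    for (ij in utils::combn(additive_pool, 2L, simplify = FALSE)) {
      fixed_sets <- c(fixed_sets, list(ij))
    }
  }
  if (length(interaction_pool) >= 2L) {
    for (ij in utils::combn(interaction_pool, 2L, simplify = FALSE)) {
      fixed_sets <- c(fixed_sets, list(c(ij, paste(ij, collapse = ":"))))
    }
  }
  keys <- vapply(fixed_sets, function(f) paste(sort(f), collapse = "|"),
                 character(1L))
  fixed_sets <- fixed_sets[!duplicated(keys)]
  lapply(fixed_sets, function(f) {
    model_spec(response, fixed = f, random = random, family = family)
  })
}

#' Rank fitted models by AICc and flag the top model set
#'
#' Computes delta AICc relative to the best converged model (AICc ties broken
#' toward fewer parameters) and applies the top-model-set rule: a model is in
#' the top set if its delta AICc is at most 2 and the 95% CI of every focal
#' predictor excludes zero. Focal predictors are a model's highest-order
#' terms: all fixed terms in an additive model, but only the interaction (and
#' any terms outside it) when an interaction is present, since its main
#' effects are retained for marginality and are conditional effects whose CIs
#' do not decide the model's support. The null model row is always present
#' for reference.
#'
#' @param fits List of [fit_mixed()] results.
#' @return An object of class `selection_table`: a data frame with columns
#'   `label`, `k`, `loglik`, `aicc`, `delta_aicc`, `converged`, `singular`,
#'   `is_null`, `ci_excludes_zero`, `in_top_set`, ordered by AICc, with the
#'   fits attached as an attribute.
#' @export
select_top_models <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  conv <- vapply(fits, `[[`, logical(1L), "converged")
  if (!any(conv)) stop("no converged fits", call. = FALSE)
  tab <- data.frame(
    label = vapply(fits, `[[`, character(1L), "label"),
    k = vapply(fits, `[[`, numeric(1L), "k"),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1L), "aicc"),
    converged = conv,
    singular = vapply(fits, `[[`, logical(1L), "singular"),
    is_null = vapply(fits, function(f) length(f$spec$fixed) == 0L, logical(1L)),
    ci_excludes_zero = vapply(fits, function(f) {
      fixed <- f$spec$fixed
      inter <- grep(":", fixed, value = TRUE)
      focal <- if (length(inter)) {
        setdiff(fixed, unlist(strsplit(inter, ":", fixed = TRUE)))
      } else {
        fixed
      }
      cf <- f$coefficients[f$coefficients$term_label %in% focal, , drop = FALSE]
      nrow(cf) == 0L || all(cf$ci_lower > 0 | cf$ci_upper < 0)
    }, logical(1L)),
    row.names = NULL
  )
  best <- min(tab$aicc[tab$converged])
  tab$delta_aicc <- tab$aicc - best
  tab$in_top_set <- tab$converged & tab$delta_aicc <= 2 & tab$ci_excludes_zero
  ord <- order(tab$aicc, tab$k)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("selection_table", "data.frame"))
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  show <- data.frame(
    model = x$label,
    k = x$k,
    AICc = round(x$aicc, digits),
    dAICc = round(x$delta_aicc, digits),
    top_set = ifelse(x$in_top_set, "*", ""),
    note = ifelse(!x$converged, "not converged",
                  ifelse(!x$ci_excludes_zero & x$delta_aicc <= 2 & !x$is_null,
                         "95% CI crosses zero", ""))
  )
  print(show, row.names = FALSE, ...)
  invisible(x)
}

#' Coefficients of the top-model-set members
#'
#' @param selection A [select_top_models()] result.
#' @return Data frame of fixed-effect coefficients (estimate, se, 95% CI) for
#'   each model flagged in the top set, excluding the intercept-only model.
#' @export
top_set_coefficients <- function(selection) {
  fits <- attr(selection, "fits")
  keep <- which(selection$in_top_set & !selection$is_null)
  if (length(keep) == 0L) {
    return(data.frame(model = character(), term = character(),
                      estimate = numeric(), se = numeric(),
                      ci_lower = numeric(), ci_upper = numeric()))
  }
  do.call(rbind, lapply(keep, function(i) {
    cf <- fits[[i]]$coefficients
    cf <- cf[cf$term != "(Intercept)", , drop = FALSE]
    cbind(model = fits[[i]]$label, cf)
  }))
}
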