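#' Passing-criterion specification for run-based scoring
#'
#' Defines the passing criterion used to score a trial sequence: an individual
#' passes a task at the final trial of the first run of `run_length`
#' consecutive correct choices. Tests are stopped at `cap` trials; unpassed
#' tasks are recorded at the cap and flagged as censored. `chance_p` is the
#' per-trial probability of a correct choice for an animal responding at
#' chance (0.5 for a two-choice task), used by [chance_pass_probability()].
#'
#' @param run_length Number of consecutive correct trials required to pass.
#' @param cap Maximum number of trials before the test is stopped.
#' @param chance_p Per-trial probability of success under random choice.
#' @return An object of class `criterion_spec`.
#' @examples
#' criterion_spec()                 # run of 6 within 120 trials, chance 0.5
#' criterion_spec(run_length = 4)   # a laxer criterion
#' @export
criterion_spec <- function(run_length = 6L, cap = 120L, chance_p = 0.5) {
  run_length <- as.integer(run_length)
  cap <- as.integer(cap)
  if (is.na(run_length) || run_length < 1L || run_length > cap) {
    stop("`run_length` must satisfy 1 <= run_length <= cap", call. = FALSE)
  }
  if (!is.numeric(chance_p) || chance_p <= 0 || chance_p >= 1) {
    stop("`chance_p` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(run_length = run_length, cap = cap, chance_p = chance_p),
    class = "criterion_spec"
  )
}

#' Trials to criterion for one trial sequence
#'
#' Scores an ordered binary outcome sequence as the number of trials up to and
#' including the final trial of the first run of `spec$run_length` consecutive
#' correct choices (so the best possible score equals the run length). If no
#' such run occurs, the score is the cap and the result is censored.
#'
#' @param outcomes Integer/logical vector of trial outcomes (1 = correct).
#' @param spec A [criterion_spec()].
#' @return A list with elements `score` (integer) and `censored` (logical).
#' @examples
#' trials_to_criterion(c(1, 1, 1, 1, 1, 1))       # score 6, not censored
#' trials_to_criterion(c(0, 1, 1, 1, 1, 1, 1))    # score 7
#' @export
trials_to_criterion <- function(outcomes, spec = criterion_spec()) {
  if (length(outcomes) == 0L) {
    stop("empty trial sequence", call. = FALSE)
  }
  outcomes <- as.integer(outcomes)
  if (anyNA(outcomes) || any(outcomes != 0L & outcomes != 1L)) {
    stop("trial outcomes must be binary (0/1)", call. = FALSE)
  }
  if (length(outcomes) > spec$cap) {
    stop("trial sequence longer than the cap (", spec$cap, " trials)",
         call. = FALSE)
  }
  run <- 0L
  for (t in seq_along(outcomes)) {
    run <- if (outcomes[t] == 1L) run + 1L else 0L
    if (run == spec$run_length) {
      return(list(score = t, censored = FALSE))
    }
  }
  list(score = spec$cap, censored = TRUE)
}

#' Exact probability that a chance-level chooser passes a run criterion
#'
#' Computes, by dynamic programming over current-run-length states, the exact
#' probability that a Bernoulli(`chance_p`) responder produces a run of
#' `run_length` successes within `n_trials` trials. At `n_trials = run_length`
#' this reduces to `chance_p^run_length`; for the default criterion (six in a
#' row at 0.5) that is 0.015625, i.e. the binomial p = 0.016 reported for
#' two-choice tasks.
#'
#' @param n_trials Number of trials available (vectorised).
#' @param spec A [criterion_spec()].
#' @return Numeric vector of pass probabilities, one per element of `n_trials`.
#' @examples
#' chance_pass_probability(6)                      # 0.5^6 = 0.015625
#' chance_pass_probability(1, criterion_spec(1))   # 0.5
#' @export
chance_pass_probability <- function(n_trials, spec = criterion_spec()) {
  if (any(n_trials < 1)) stop("`n_trials` must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  r <- spec$run_length
  p <- spec$chance_p
  n_max <- max(n_trials)
  # state k in 0..r-1: current run length, not yet passed; state r: absorbed
  state <- c(1, rep(0, r))
  out <- numeric(n_max)
  for (t in seq_len(n_max)) {
    nxt <- numeric(r + 1L)
    nxt[1L] <- sum(state[seq_len(r)]) * (1 - p)
    for (k in seq_len(r)) nxt[k + 1L] <- state[k] * p
    nxt[r + 1L] <- nxt[r + 1L] + state[r + 1L]
    state <- nxt
    out[t] <- state[r + 1L]
  }
  out[n_trials]
}

#' Assemble a score matrix from trial-level data
#'
#' Converts long-format trial outcomes (one row per trial) into an
#' individuals-by-tasks matrix of trials-to-criterion scores with a parallel
#' censoring indicator. At most one sequence per individual and task is
#' allowed; individuals missing any task are flagged rather than dropped.
#'
#' @param trials Data frame with columns `individual_id`, `task`, `trial`
#'   (1-based index ordering trials within a sequence) and `correct` (0/1).
#' @param spec A [criterion_spec()].
#' @return An object of class `score_matrix`: a list with `scores` (integer
#'   matrix, rownames = individuals, colnames = tasks), `censored` (logical
#'   matrix), `complete` (logical per individual), `task_summary` (per-task
#'   mean and range over scored cells) and `spec`.
#' @export
build_score_matrix <- function(trials, spec = criterion_spec()) {
  needed <- c("individual_id", "task", "trial", "correct")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("`trials` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trials$individual_id <- as.character(trials$individual_id)
  trials$task <- as.character(trials$task)
  if (anyDuplicated(trials[, c("individual_id", "task", "trial")])) {
    stop("duplicate individual x task records", call. = FALSE)
  }
  ids <- unique(trials$individual_id)
  tasks <- unique(trials$task)
  scores <- matrix(NA_integer_, length(ids), length(tasks),
                   dimnames = list(ids, tasks))
  censored <- matrix(NA, length(ids), length(tasks),
                     dimnames = list(ids, tasks))
  split_idx <- split(seq_len(nrow(trials)),
                     list(trials$individual_id, trials$task), drop = TRUE)
  for (idx in split_idx) {
    rows <- trials[idx, ]
    rows <- rows[order(rows$trial), ]
    res <- trials_to_criterion(rows$correct, spec)
    scores[rows$individual_id[1L], rows$task[1L]] <- res$score
    censored[rows$individual_id[1L], rows$task[1L]] <- res$censored
  }
  complete <- !apply(is.na(scores), 1L, any)
  task_summary <- data.frame(
    task = tasks,
    mean = apply(scores, 2L, mean, na.rm = TRUE),
    min = apply(scores, 2L, min, na.rm = TRUE),
    max = apply(scores, 2L, max, na.rm = TRUE),
    n = apply(!is.na(scores), 2L, sum),
    row.names = NULL
  )
  structure(
    list(scores = scores, censored = censored, complete = complete,
         task_summary = task_summary, spec = spec),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Score matrix:", nrow(x$scores), "individuals x", ncol(x$scores),
      "tasks (criterion: run of", x$spec$run_length, "within", x$spec$cap,
      "trials)\n")
  cat(sum(!x$complete), "individual(s) with missing tasks;",
      sum(x$censored, na.rm = TRUE), "censored cell(s)\n")
  print(x$task_summary, ...)
  invisible(x)
}

# Extract the numeric score matrix from a score_matrix object or plain matrix.
score_values <- function(scores) {
  if (inherits(scores, "score_matrix")) scores$scores
  else as.matrix(scores)
}
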