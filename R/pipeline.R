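#' Configuration for a full pipeline run
#'
#' Collects input paths, the passing criterion, simulation sizes, seeds and
#' the output directory for [run_full_pipeline()]. Either `trials` (long
#' trial-level CSV) or `scores` (pre-computed score CSV, individuals x tasks
#' with an `individual_id` column) must be given. `roster` supplies
#' individual attributes for the determinant models; `breeding` supplies
#' individual-year reproduction records for the fitness models; both are
#' optional, as is a long-format `replicates` CSV (`individual_id`,
#' `replicate`, `gcp` or task scores per replicate) for repeatability.
#'
#' @param trials,scores,roster,breeding,replicates Input CSV paths (or `NULL`).
#' @param out_dir Output directory.
#' @param criterion A [criterion_spec()].
#' @param n_sims Permutation iterations for the loading null.
#' @param seed Integer seed used for all stochastic stages.
#' @param criterion_fit `"ml"` or `"reml"` likelihood for ranked gaussian fits.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trials = NULL, scores = NULL, roster = NULL,
                       breeding = NULL, replicates = NULL,
                       out_dir = "gcp-output", criterion = criterion_spec(),
                       n_sims = 10000L, seed = 1L,
                       criterion_fit = c("ml", "reml")) {
  criterion_fit <- match.arg(criterion_fit)
  if (is.null(trials) && is.null(scores)) {
    stop("supply `trials` or `scores`", call. = FALSE)
  }
  for (p in c(trials, scores, roster, breeding, replicates)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(
    list(trials = trials, scores = scores, roster = roster,
         breeding = breeding, replicates = replicates, out_dir = out_dir,
         criterion = criterion, n_sims = as.integer(n_sims),
         seed = as.integer(seed), criterion_fit = criterion_fit),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Maps top-level YAML keys onto [run_config()] arguments; `criterion` may be
#' a mapping with `run_length`, `cap` and `chance_p`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the `yaml` package", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$criterion)) {
    y$criterion <- do.call(criterion_spec, y$criterion)
  }
  do.call(run_config, y)
}

pipeline_log <- function(manifest, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  manifest$log <- c(manifest$log, line)
  manifest
}

#' Read a pre-computed score matrix from CSV
#'
#' The file must have an `individual_id` column; every other column is taken
#' to be a task's trials-to-criterion scores.
#'
#' @param path CSV file path.
#' @return Numeric matrix, individuals in rows (rownames), tasks in columns.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df)) {
    stop("scores CSV needs an `individual_id` column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE])
  rownames(m) <- df$individual_id
  m
}

#' Run the full cognitive-battery pipeline
#'
#' Orchestrates every stage on file inputs: trials-to-criterion scoring, GCP
#' extraction with the within-task permutation null, pairwise Spearman
#' correlations, AICc selection of GCP determinants (when a roster is
#' supplied), the three fitness model sets (when breeding records are
#' supplied), and repeatability (when replicate measurements are supplied).
#' Every table is written as CSV alongside a human-readable `summary.txt` and
#' a `manifest.json` recording package version, seeds, configuration and
#' input hashes. A stage failure aborts with the stage name; tables already
#' written are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("gcpbattery")),
    r_version = R.version.string,
    seed = config$seed,
    n_sims = config$n_sims,
    criterion = unclass(config$criterion),
    criterion_fit = config$criterion_fit,
    inputs = list(),
    log = character()
  )
  for (nm in c("trials", "scores", "roster", "breeding", "replicates")) {
    if (!is.null(config[[nm]])) {
      manifest$inputs[[nm]] <- list(
        path = config[[nm]],
        md5 = unname(tools::md5sum(config[[nm]]))
      )
    }
  }
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  # --- scoring ---------------------------------------------------------
  sm <- stage("scoring", {
    if (!is.null(config$trials)) {
      trials <- utils::read.csv(config$trials, stringsAsFactors = FALSE)
      build_score_matrix(trials, config$criterion)
    } else {
      m <- read_scores_csv(config$scores)
      structure(list(scores = m, censored = m == config$criterion$cap,
                     complete = !apply(is.na(m), 1L, any),
                     task_summary = NULL, spec = config$criterion),
                class = "score_matrix")
    }
  })
  manifest <- pipeline_log(manifest, "scoring",
                           sprintf("%d individuals, %d complete",
                                   nrow(sm$scores), sum(sm$complete)))
  scores_df <- data.frame(individual_id = rownames(sm$scores), sm$scores,
                          row.names = NULL, check.names = FALSE)
  utils::write.csv(scores_df, out("scores.csv"), row.names = FALSE)
  results$score_matrix <- sm

  complete_scores <- sm$scores[sm$complete, , drop = FALSE]

  # --- correlations + GCP + permutation null ---------------------------
  results$spearman <- stage("spearman", spearman_pairs(complete_scores))
  utils::write.csv(results$spearman, out("spearman.csv"), row.names = FALSE)
  gcp_res <- stage("gcp", extract_gcp(complete_scores))
  results$gcp <- gcp_res
  utils::write.csv(
    data.frame(individual_id = names(gcp_res$gcp), gcp = gcp_res$gcp,
               row.names = NULL),
    out("gcp.csv"), row.names = FALSE
  )
  null_res <- stage("permutation_null",
                    permutation_null(complete_scores, config$n_sims,
                                     seed = config$seed))
  results$permutation_null <- null_res
  jsonlite::write_json(
    list(
      eigenvalues = gcp_res$eigenvalues,
      pc1_loadings = as.list(gcp_res$pc1_loadings),
      pct_variance_pc1 = gcp_res$pct_variance_pc1,
      loading_mean = gcp_res$loading_mean,
      loading_sd = gcp_res$loading_sd,
      null_ci_mean = null_res$ci_mean,
      null_ci_sd = null_res$ci_sd,
      mean_above_ci = null_res$mean_above_ci,
      sd_below_ci = null_res$sd_below_ci,
      sd_within_ci = null_res$sd_within_ci,
      n_sims = null_res$n_sims
    ),
    out("gcp_report.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- pipeline_log(
    manifest, "gcp",
    sprintf("PC1 %.1f%% variance; mean loading %.2f (null CI %.2f-%.2f)",
            gcp_res$pct_variance_pc1, gcp_res$loading_mean,
            null_res$ci_mean[1L], null_res$ci_mean[2L]))

  # --- determinants (needs roster) -------------------------------------
  if (!is.null(config$roster)) {
    det <- stage("determinants", {
      roster <- utils::read.csv(config$roster, stringsAsFactors = FALSE)
      roster$gcp <- gcp_res$gcp[roster$individual_id]
      roster <- roster[!is.na(roster$gcp), , drop = FALSE]
      run_determinant_models(roster, method = config$criterion_fit)
    })
    results$determinants <- det
    utils::write.csv(as.data.frame(det$selection),
                     out("determinants_selection.csv"), row.names = FALSE)
    utils::write.csv(det$coefficients, out("determinants_coefficients.csv"),
                     row.names = FALSE)
    manifest <- pipeline_log(
      manifest, "determinants",
      sprintf("%d models on %d individuals (%d dropped, unknown sex); best: %s",
              nrow(det$selection), det$n_used, det$n_dropped_unknown_sex,
              det$selection$label[1L]))
  }

  # --- fitness (needs breeding records) --------------------------------
  if (!is.null(config$breeding)) {
    breeding <- stage("fitness",
                      utils::read.csv(config$breeding,
                                      stringsAsFactors = FALSE))
    for (measure in c("fledglings", "independents", "recruits")) {
      res <- stage(paste0("fitness_", measure), {
        gcp_arg <- if ("gcp" %in% names(breeding)) NULL else gcp_res$gcp
        run_fitness_models(breeding, gcp = gcp_arg, measure = measure)
      })
      results[[paste0("fitness_", measure)]] <- res
      utils::write.csv(as.data.frame(res$selection),
                       out(sprintf("fitness_%s_selection.csv", measure)),
                       row.names = FALSE)
      utils::write.csv(res$coefficients,
                       out(sprintf("fitness_%s_coefficients.csv", measure)),
                       row.names = FALSE)
      manifest <- pipeline_log(
        manifest, paste0("fitness_", measure),
        sprintf("%d observations, %d individuals; best: %s",
                res$n_used, res$n_individuals, res$selection$label[1L]))
    }
  }

  # --- repeatability (needs replicate measurements) --------------------
  if (!is.null(config$replicates)) {
    rep_res <- stage("repeatability", {
      reps <- utils::read.csv(config$replicates, stringsAsFactors = FALSE)
      repeatability(reps, seed = config$seed)
    })
    results$repeatability <- rep_res
    jsonlite::write_json(
      list(R = rep_res$R, se = rep_res$se, ci = rep_res$ci, p = rep_res$p,
           n_individuals = rep_res$n_individuals, n_obs = rep_res$n_obs),
      out("repeatability.json"), auto_unbox = TRUE, digits = NA
    )
    manifest <- pipeline_log(
      manifest, "repeatability",
      sprintf("R = %.2f (95%% CI %.2f-%.2f, p = %.3g)",
              rep_res$R, rep_res$ci[1L], rep_res$ci[2L], rep_res$p))
  }

  # --- summary + manifest ----------------------------------------------
  summary_lines <- c("gcpbattery pipeline summary", "", manifest$log)
  writeLines(summary_lines, out("summary.txt"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(results)
}
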