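# Orchestration and file I/O: one reproducible run from simulation (or an
# ingested trial table) through extraction, classification, scaling
# analysis and HMFA.

TRIAL_NUMERIC_COLS <- c("demand_rank", "mu_k", "slope_deg",
                        "target_distance_m", "optimal_speed_mps", "A_mm",
                        "D_s", "IS_mps", "stop_m", "spatial_error_pct")
TRIAL_REQUIRED_COLS <- c("trial_id", "participant_id",
                         TRIAL_NUMERIC_COLS, "ground_truth")

#' Read / write a trial table
#'
#' CSV round trip for the trial-table schema shared by the synthetic
#' generator (ground truth) and the kinematic extractor. Reading validates
#' the schema and reports malformed rows with their line numbers;
#' `write_trial_table` then `read_trial_table` is the identity on valid
#' tables.
#'
#' @param path File path.
#' @return `read_trial_table`: the validated data.frame.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trial table: ", path)
  missing_cols <- setdiff(TRIAL_REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop("trial table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in TRIAL_NUMERIC_COLS) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", cl, "' at line ",
             paste(bad + 1L, collapse = ", "), " of ", path)
      }
      df[[cl]] <- num
    }
  }
  df$ground_truth <- as.logical(df$ground_truth)
  df
}

#' @rdname read_trial_table
#' @param trials Trial table data.frame.
#' @export
write_trial_table <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_REQUIRED_COLS, names(trials))
  if (length(missing_cols)) {
    stop("refusing to write trial table lacking: ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every knob of a full pipeline run so that a run is reproducible
#' from its config alone.
#'
#' @param seed Integer seed for every random stage.
#' @param cohort A [cohort_config()].
#' @param kinematic A [kinematic_config()].
#' @param k_range Cluster counts for the elbow profile.
#' @param n_restarts K-means restarts.
#' @param run_hmfa Logical: fit the HMFA stage.
#' @param output_dir Optional directory; when given, stage outputs are
#'   written there as CSV plus a run-metadata file.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       kinematic = kinematic_config(), k_range = 1:5,
                       n_restarts = 100L, run_hmfa = TRUE,
                       output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(kinematic, "kinematic_config"))
  structure(list(seed = as.integer(seed), cohort = cohort,
                 kinematic = kinematic, k_range = k_range,
                 n_restarts = as.integer(n_restarts),
                 run_hmfa = isTRUE(run_hmfa), output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or ingest) trajectories, extract performance
#' variables, correlate and classify participants, slope scaling with
#' between-cluster ANOVAs and the strategy-by-coordination chi-square, and
#' finally the HMFA. Deterministic: the same config yields identical
#' results.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-generated `strike_cohort` (with
#'   trajectories); by default one is simulated from `config`.
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `extraction`, `classification`, `elbow`, `slopes`, `anova` (one
#'   [oneway_anova()] per slope variable; NULL when a strategy has fewer
#'   than 2 participants), `contingency`, `hmfa`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort, seed = config$seed)
  }
  extraction <- extract_cohort(cohort, config$kinematic)
  trials <- extraction$trials

  classification <- classify_cohort(trials, n_restarts = config$n_restarts,
                                    seed = config$seed)
  z <- classification$z
  elbow <- elbow_profile(z, k_max = max(config$k_range),
                         n_restarts = config$n_restarts, seed = config$seed)

  slopes <- zscore_slopes(cohort_slopes(trials))
  slopes$strategy <- classification$correlations$strategy[
    match(slopes$participant_id,
          classification$correlations$participant_id)]

  anovas <- if (all(table(slopes$strategy) >= 2) &&
                length(unique(slopes$strategy)) >= 2) {
    list(
      z_slope_A = oneway_anova(slopes$z_slope_A, slopes$strategy),
      z_slope_D = oneway_anova(slopes$z_slope_D, slopes$strategy),
      z_slope_IS = oneway_anova(slopes$z_slope_IS, slopes$strategy),
      raw_slope_err = oneway_anova(slopes$raw_slope_err, slopes$strategy)
    )
  } else NULL # too few participants per strategy for between-cluster tests

  counts <- table(slopes$coordination_group, slopes$strategy)
  contingency <- if (all(dim(counts) >= 2) && all(rowSums(counts) > 0) &&
                     all(colSums(counts) > 0)) {
    contingency_stats(unclass(counts))
  } else NULL

  hmfa <- if (config$run_hmfa) {
    hmfa_cohort(trials, factor(slopes$strategy))
  } else NULL

  result <- structure(list(cohort = cohort, extraction = extraction,
                           classification = classification, elbow = elbow,
                           slopes = slopes, anova = anovas,
                           contingency = contingency, hmfa = hmfa,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(result$cohort$trials,
                    file.path(dir, "trials_ground_truth.csv"))
  ex <- result$extraction$trials
  write_trial_table(ex, file.path(dir, "trials_extracted.csv"))
  utils::write.csv(result$extraction$exclusions,
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(result$classification$correlations,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(result$elbow, file.path(dir, "elbow.csv"),
                   row.names = FALSE)
  utils::write.csv(result$slopes, file.path(dir, "slopes.csv"),
                   row.names = FALSE)
  meta <- c(
    sprintf("seed: %d", result$config$seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("strikekin"))),
    sprintf("n_participants: %d", length(result$cohort$profiles)),
    sprintf("n_trials: %d", nrow(result$cohort$trials)),
    sprintf("n_excluded: %d", nrow(result$extraction$exclusions)),
    sprintf("kmeans_restarts: %d", result$config$n_restarts),
    sprintf("onset_speed_fraction: %g",
            result$config$kinematic$onset_speed_fraction),
    sprintf("cube_motion_threshold_mps: %g",
            result$config$kinematic$cube_motion_threshold),
    sprintf("contact_ratio_threshold: %g",
            result$config$kinematic$contact_ratio_threshold)
  )
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  print(x$classification$solution)
  if (!is.null(x$contingency)) {
    cat(sprintf("  strategy x coordination: chi^2(%d) = %.3f, V = %.3f\n",
                x$contingency$df, x$contingency$chi_sq,
                x$contingency$cramers_v))
  }
  if (!is.null(x$hmfa)) print(x$hmfa)
  invisible(x)
}

#' Classification and contingency analysis of the published tables
#'
#' Fixture mode: runs the strategy classification (Fisher-Z + K-means with
#' elbow and Calinski-Harabasz validation) on the published 33 x 3
#' correlation table and the chi-square/Cramer's V analysis on the
#' published strategy-by-coordination counts — no trajectory data involved.
#'
#' @param n_restarts,seed Passed to [kmeans_cluster()].
#' @param k_max Largest cluster count for the elbow profile.
#' @return List with `solution` (k = 3 `cluster_solution` with labels),
#'   `elbow`, `ch_index`, `modes` (regulation-mode factor at the
#'   `critical_r(120)` criterion), `contingency`.
#' @export
analyze_published_tables <- function(n_restarts = 200L, seed = 1L,
                                     k_max = 5L) {
  z <- table1_fisher_z()
  sol <- kmeans_cluster(z, k = 3, n_restarts = n_restarts, seed = seed)
  list(
    solution = sol,
    elbow = elbow_profile(z, k_max = k_max, n_restarts = n_restarts,
                          seed = seed),
    ch_index = calinski_harabasz(sol),
    modes = assign_mode(table1_correlations()$r_D_IS, critical_r(120)),
    contingency = contingency_stats(table2_counts())
  )
}
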