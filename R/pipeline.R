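#' Pipeline configuration
#'
#' Assembles and validates all settings of the end-to-end pipeline. Unknown
#' keys are rejected so that typos in configuration files surface loudly.
#'
#' @param classifier [classifier_config()] settings, as a list of overrides
#'   (e.g. `list(migraine_min_hours = 4)`).
#' @param months Number of 28-day months to aggregate.
#' @param months_required Complete months of daily use required for cohort
#'   inclusion (default 7).
#' @param followup_month Follow-up month compared against baseline (7 or 13
#'   by default naming; any index >= 2 is allowed).
#' @param anova_months Month indices for the repeated-measures comparison.
#' @param alpha Two-tailed significance level.
#' @param diagnosis List of overrides for [assign_diagnosis_group()]
#'   thresholds.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = list(), months = 7L,
                            months_required = 7L, followup_month = 7L,
                            anova_months = NULL, alpha = 0.05,
                            diagnosis = list()) {
  known_cls <- c("mild_max", "moderate_max", "migraine_min_hours",
                 "tth_hours_range", "triptan_names", "attribution_window_hours")
  if (length(bad <- setdiff(names(classifier), known_cls)))
    stop("pipeline_config: unknown classifier key(s): ", paste(bad, collapse = ", "))
  known_dx <- c("chronic_headache_days", "chronic_migraine_days", "episodic_min_attacks")
  if (length(bad <- setdiff(names(diagnosis), known_dx)))
    stop("pipeline_config: unknown diagnosis key(s): ", paste(bad, collapse = ", "))
  stopifnot(months >= 1L, months_required >= 1L, followup_month >= 2L,
            alpha > 0, alpha < 1)
  bands <- intensity_bands(classifier$mild_max %||% 3L,
                           classifier$moderate_max %||% 7L)
  cls <- classifier_config(
    bands = bands,
    migraine_min_hours = classifier$migraine_min_hours %||% 4,
    tth_hours_range = classifier$tth_hours_range %||% c(0.5, 168),
    triptan_names = classifier$triptan_names %||%
      classifier_config()$triptan_names,
    attribution_window_hours = classifier$attribution_window_hours %||% 1
  )
  structure(list(
    classifier = cls,
    months = as.integer(months),
    months_required = as.integer(months_required),
    followup_month = as.integer(followup_month),
    anova_months = anova_months %||% unique(c(1L, as.integer(followup_month))),
    alpha = alpha,
    diagnosis = list(
      chronic_headache_days = diagnosis$chronic_headache_days %||% 45L,
      chronic_migraine_days = diagnosis$chronic_migraine_days %||% 24L,
      episodic_min_attacks = diagnosis$episodic_min_attacks %||% 5L
    )
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may contain any subset of the [pipeline_config()] arguments
#' (`classifier`, `months`, `months_required`, `followup_month`,
#' `anova_months`, `alpha`, `diagnosis`); unknown top-level or nested keys
#' are rejected.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("classifier", "months", "months_required", "followup_month",
             "anova_months", "alpha", "diagnosis")
  if (length(bad <- setdiff(names(raw), known)))
    stop("pipeline config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [headachediary] ", ...)
}

#' Run the full diary-to-outcome pipeline
#'
#' Stages, in order: read (or accept) the diary, classify every attack,
#' aggregate monthly outcomes, assign 90-day diagnosis groups, select the
#' daily-use cohort, and compare baseline with the follow-up month. All
#' stage outputs are written to `out_dir`:
#'
#' * `monthly_outcomes.tsv` -- per user and 28-day month (cohort users only);
#' * `diagnosis_groups.tsv` -- per-user episodic/chronic/other group;
#' * `demographics.json` -- available-data demographic summary per subgroup;
#' * `outcome_table.tsv` / `outcome_table.json` -- paired baseline-vs-
#'   follow-up results per outcome and subgroup;
#' * `anova_table.tsv` -- repeated-measures comparison across the configured
#'   months;
#' * `run_log.json` -- configuration hash, counts and stage timings.
#'
#' If fewer than two users satisfy the daily-use requirement the analysis
#' tables are emitted empty (with a note) rather than erroring, so that e.g.
#' a 13-month requirement on a 7-month cohort reports an empty extended
#' cohort.
#'
#' @param collection A [diary_collection()], or `NULL` to read from `paths`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param paths Named list with `users`, `attacks`, `medications`, `entries`
#'   CSV paths, used when `collection` is `NULL`.
#' @return Invisibly, a list with the in-memory stage results:
#'   `classifications`, `outcomes`, `groups`, `cohort`, `demographics`,
#'   `outcome_table`, `anova_table`.
#' @export
run_pipeline <- function(collection = NULL, config = pipeline_config(),
                         out_dir, paths = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  if (is.null(collection)) {
    log_msg("stage read: ", paths$users)
    collection <- read_diary(paths$users, paths$attacks, paths$medications,
                             paths$entries)
  }

  log_msg("stage classify: ", nrow(collection$attacks), " attacks")
  cls <- classify_attacks(collection, config$classifier)

  log_msg("stage cohort: selecting users with ", config$months_required,
          " complete months")
  cohort <- select_regular_users(collection, config$months_required)
  log_msg("  ", length(cohort), "/", nrow(collection$users), " users retained")

  sub <- diary_collection(
    collection$users[collection$users$user_id %in% cohort, , drop = FALSE],
    collection$attacks[collection$attacks$user_id %in% cohort, , drop = FALSE],
    collection$medications[collection$medications$user_id %in% cohort, , drop = FALSE],
    collection$entries[collection$entries$user_id %in% cohort, , drop = FALSE],
    validate = FALSE
  )

  log_msg("stage aggregate: ", config$months, " months")
  outcomes <- compute_monthly_outcomes(sub, cls, config$months)

  groups <- NULL
  if (length(cohort) && config$months * 28L >= 90L) {
    log_msg("stage diagnosis groups (first 90 days)")
    groups <- assign_diagnosis_group(sub, cls,
                                     config$diagnosis$chronic_headache_days,
                                     config$diagnosis$chronic_migraine_days,
                                     config$diagnosis$episodic_min_attacks)
  }

  demo <- summarize_demographics(sub$users, groups)

  if (length(cohort) >= 2L) {
    log_msg("stage analyze: baseline vs month ", config$followup_month)
    tab <- build_outcome_table(outcomes, groups, 1L, config$followup_month,
                               config$alpha)
    anova_tab <- build_anova_table(outcomes, config$anova_months)
  } else {
    log_msg("stage analyze skipped: fewer than 2 cohort users")
    tab <- build_outcome_table(outcomes[0L, , drop = FALSE], NULL, 1L,
                               config$followup_month, config$alpha)
    tab <- tab[0L, , drop = FALSE]
    anova_tab <- build_anova_table(outcomes[0L, , drop = FALSE],
                                   config$anova_months)[0L, , drop = FALSE]
  }

  write_tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
                quote = FALSE, na = "")
  }
  write_tsv(outcomes, "monthly_outcomes.tsv")
  if (!is.null(groups)) write_tsv(groups, "diagnosis_groups.tsv")
  write_tsv(tab, "outcome_table.tsv")
  write_tsv(anova_tab, "anova_table.tsv")
  jsonlite::write_json(demo, file.path(out_dir, "demographics.json"),
                       dataframe = "rows", na = "null", pretty = TRUE)
  jsonlite::write_json(tab, file.path(out_dir, "outcome_table.json"),
                       dataframe = "rows", na = "null", pretty = TRUE, digits = NA)

  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  log <- list(
    config_hash = unname(tools::md5sum(tmp)),
    n_users_input = nrow(collection$users),
    n_attacks_input = nrow(collection$attacks),
    n_cohort = length(cohort),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  unlink(tmp)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(collection = sub, classifications = cls, outcomes = outcomes,
                 groups = groups, cohort = cohort, demographics = demo,
                 outcome_table = tab, anova_table = anova_tab))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Simulate a cohort and write it as diary CSVs
#'
#' Convenience wrapper around [generate_cohort()] and [write_diary()]: the
#' four diary CSVs plus `ground_truth.tsv` (per-user latent type and base
#' hazard) are written to `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_cohort()] result.
#' @export
simulate_to_dir <- function(config, out_dir) {
  res <- generate_cohort(config)
  write_diary(res$collection, out_dir)
  write.table(res$truth$users, file.path(out_dir, "ground_truth.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(res)
}
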