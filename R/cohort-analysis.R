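#' Paired samples t test
#'
#' Classical paired t test on the differences `d = baseline - followup`, so a
#' decrease over time yields a positive mean difference and a positive
#' confidence interval. Computed from the closed-form sums (not a wrapper
#' around [stats::t.test()], which serves as an independent reference in the
#' test suite).
#'
#' @param baseline,followup Numeric vectors of equal length, pairwise
#'   complete (drop incomplete pairs before calling).
#' @param alpha Two-tailed significance level; the confidence interval has
#'   coverage `1 - alpha` (default 0.05, i.e. a 95% CI).
#' @param outcome_name Label carried into the result.
#' @return An object of class `paired_t_result`: `outcome_name`, `n`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`,
#'   `mean_diff`, `t_stat`, `df`, `p_value`, `ci_low`, `ci_high`.
#' @export
paired_t_test <- function(baseline, followup, alpha = 0.05, outcome_name = "") {
  if (length(baseline) != length(followup))
    stop("paired_t_test: baseline and followup lengths differ")
  if (anyNA(baseline) || anyNA(followup))
    stop("paired_t_test: inputs must be pairwise complete")
  n <- length(baseline)
  if (n < 2L) stop("paired_t_test: need at least 2 pairs")
  d <- baseline - followup
  sd_d <- sqrt(sum((d - mean(d))^2) / (n - 1))
  if (sd_d == 0) stop("degenerate: zero variance")
  se <- sd_d / sqrt(n)
  t_stat <- mean(d) / se
  df <- n - 1L
  p <- 2 * pt(-abs(t_stat), df)
  half <- qt(1 - alpha / 2, df) * se
  structure(list(
    outcome_name = outcome_name, n = n,
    baseline_mean = mean(baseline), baseline_sd = sd(baseline),
    followup_mean = mean(followup), followup_sd = sd(followup),
    mean_diff = mean(d), t_stat = t_stat, df = df, p_value = p,
    ci_low = mean(d) - half, ci_high = mean(d) + half
  ), class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t test%s: n=%d\n",
              if (nzchar(x$outcome_name)) paste0(" [", x$outcome_name, "]") else "",
              x$n))
  cat(sprintf("  baseline %.2f (SD %.2f)  follow-up %.2f (SD %.2f)\n",
              x$baseline_mean, x$baseline_sd, x$followup_mean, x$followup_sd))
  cat(sprintf("  diff %.3f, t(%d)=%.3f, p=%.4g, 95%% CI [%.3f, %.3f]\n",
              x$mean_diff, x$df, x$t_stat, x$p_value, x$ci_low, x$ci_high))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects ANOVA for a complete `subjects x timepoints` matrix: the
#' between-subject variability is removed and the time effect tested with
#' `F = MS_time / MS_error`, `df_time = k - 1`,
#' `df_error = (k - 1)(n - 1)`. No sphericity correction is applied by
#' default; `gg_correction = TRUE` applies the Greenhouse-Geisser epsilon to
#' the degrees of freedom of the p value.
#'
#' @param mat Numeric matrix, one row per subject, one column per timepoint;
#'   must be complete (no `NA`).
#' @param gg_correction Apply the Greenhouse-Geisser correction to the
#'   p value's degrees of freedom.
#' @return An object of class `rm_anova_result`: `n_subjects`,
#'   `k_timepoints`, `f_stat`, `df_time`, `df_error`, `p_value` (and
#'   `gg_epsilon` when corrected).
#' @export
repeated_measures_anova <- function(mat, gg_correction = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("repeated_measures_anova: matrix must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L)
    stop("repeated_measures_anova: need >= 2 subjects and >= 2 timepoints")

  grand <- mean(mat)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_error <- ss_total - ss_time - ss_subj

  df_time <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  ms_error <- ss_error / df_error
  if (ms_error <= .Machine$double.eps * max(1, abs(grand))^2)
    stop("degenerate: zero variance")
  f_stat <- (ss_time / df_time) / ms_error

  eps <- NA_real_
  d1 <- df_time; d2 <- df_error
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the double-centred covariance of columns
    S <- stats::cov(mat)
    Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    d1 <- d1 * eps; d2 <- d2 * eps
  }
  p <- stats::pf(f_stat, d1, d2, lower.tail = FALSE)

  structure(list(n_subjects = n, k_timepoints = k, f_stat = f_stat,
                 df_time = df_time, df_error = df_error, p_value = p,
                 gg_epsilon = eps),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g (n=%d, k=%d)\n",
              x$df_time, x$df_error, x$f_stat, x$p_value,
              x$n_subjects, x$k_timepoints))
  invisible(x)
}

#' Demographic summary with available-data percentages
#'
#' Counts and percentages are computed over the available (non-missing) data
#' only: the female percentage uses `n_total - n_missing_sex` as denominator
#' and mean/SD age use the users with recorded age.
#'
#' @param users User table (see [diary_collection()]); `sex == "unknown"` and
#'   `NA` age count as missing.
#' @param groups Optional data frame `user_id`, `group` (from
#'   [assign_diagnosis_group()]); when given, one summary row per subgroup
#'   (`ALL`, `EPISODIC_MIGRAINE`, `CHRONIC_MIGRAINE`, `OTHER`) is returned.
#' @return A data frame with columns `subgroup`, `n_total`, `n_female`,
#'   `pct_female`, `n_missing_sex`, `mean_age`, `sd_age`, `n_missing_age`.
#' @export
summarize_demographics <- function(users, groups = NULL) {
  one <- function(u, label) {
    n <- nrow(u)
    miss_sex <- sum(u$sex == "unknown")
    n_female <- sum(u$sex == "female")
    avail <- n - miss_sex
    ages <- u$age[!is.na(u$age)]
    data.frame(
      subgroup = label, n_total = n, n_female = n_female,
      pct_female = if (avail > 0) 100 * n_female / avail else NA_real_,
      n_missing_sex = miss_sex,
      mean_age = if (length(ages)) mean(ages) else NA_real_,
      sd_age = if (length(ages) > 1L) sd(ages) else NA_real_,
      n_missing_age = n - length(ages)
    )
  }
  out <- one(users, "ALL")
  if (!is.null(groups)) {
    g <- groups$group[match(users$user_id, groups$user_id)]
    for (lab in c("EPISODIC_MIGRAINE", "CHRONIC_MIGRAINE", "OTHER"))
      out <- rbind(out, one(users[!is.na(g) & g == lab, , drop = FALSE], lab))
  }
  out
}

outcome_columns <- function() {
  c(mhd = "Monthly headache days",
    mmd = "Monthly migraine days",
    amd = "Monthly days with acute medication use",
    mean_headache_intensity = "Mean monthly headache intensity",
    mean_migraine_intensity = "Mean monthly migraine intensity")
}

#' Baseline versus follow-up outcome table
#'
#' One paired t test per outcome (MHD, MMD, AMD, mean headache intensity,
#' mean migraine intensity) and subgroup (`ALL`, `EPISODIC_MIGRAINE`,
#' `CHRONIC_MIGRAINE`). Frequency outcomes use every user with both months
#' present; the intensity outcomes use the pairwise-complete users for that
#' outcome (both months' intensity defined, i.e. at least one qualifying day
#' in each). Rows that cannot be computed (subgroup with fewer than 2 usable
#' pairs, or zero variance of the differences) are kept with `NA` statistics
#' and a `note`.
#'
#' @param outcomes Result of [compute_monthly_outcomes()].
#' @param groups Result of [assign_diagnosis_group()], or `NULL` for the
#'   all-users analysis only.
#' @param baseline_month,followup_month 28-day month indices to compare
#'   (defaults 1 and 7: baseline and the sixth month after baseline).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A data frame with one row per subgroup and outcome: subgroup,
#'   outcome, n, baseline/follow-up mean and SD, mean_diff, t_stat, df,
#'   p_value, ci_low, ci_high, note.
#' @export
build_outcome_table <- function(outcomes, groups = NULL, baseline_month = 1L,
                                followup_month = 7L, alpha = 0.05) {
  oc <- outcome_columns()
  base <- outcomes[outcomes$month_index == baseline_month, , drop = FALSE]
  fup <- outcomes[outcomes$month_index == followup_month, , drop = FALSE]
  common <- intersect(base$user_id, fup$user_id)
  base <- base[match(common, base$user_id), , drop = FALSE]
  fup <- fup[match(common, fup$user_id), , drop = FALSE]

  subgroups <- "ALL"
  if (!is.null(groups))
    subgroups <- c("ALL", "EPISODIC_MIGRAINE", "CHRONIC_MIGRAINE")

  rows <- list()
  for (sg in subgroups) {
    keep <- rep(TRUE, length(common))
    if (sg != "ALL")
      keep <- groups$group[match(common, groups$user_id)] == sg
    for (col in names(oc)) {
      b <- base[[col]][keep]; f <- fup[[col]][keep]
      ok <- !is.na(b) & !is.na(f)
      row <- data.frame(subgroup = sg, outcome = oc[[col]], n = sum(ok),
                        baseline_mean = NA_real_, baseline_sd = NA_real_,
                        followup_mean = NA_real_, followup_sd = NA_real_,
                        mean_diff = NA_real_, t_stat = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, note = "")
      res <- if (sum(ok) >= 2L)
        tryCatch(paired_t_test(b[ok], f[ok], alpha, oc[[col]]),
                 error = function(e) conditionMessage(e))
      else "not computable: fewer than 2 complete pairs"
      if (inherits(res, "paired_t_result")) {
        row[c("baseline_mean", "baseline_sd", "followup_mean", "followup_sd",
              "mean_diff", "t_stat", "p_value", "ci_low", "ci_high")] <-
          res[c("baseline_mean", "baseline_sd", "followup_mean", "followup_sd",
                "mean_diff", "t_stat", "p_value", "ci_low", "ci_high")]
        row$df <- res$df
      } else {
        row$note <- if (is.character(res)) res else "not computable"
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Repeated-measures comparison across several months
#'
#' Runs [repeated_measures_anova()] per outcome on the users with complete
#' data at every requested month (listwise completeness).
#'
#' @param outcomes Result of [compute_monthly_outcomes()].
#' @param months Month indices to compare (default baseline, month 7,
#'   month 13).
#' @param gg_correction See [repeated_measures_anova()].
#' @return A data frame: outcome, n_subjects, k_timepoints, f_stat, df_time,
#'   df_error, p_value, note.
#' @export
build_anova_table <- function(outcomes, months = c(1L, 7L, 13L),
                              gg_correction = FALSE) {
  oc <- outcome_columns()
  rows <- list()
  for (col in names(oc)) {
    wide <- lapply(months, function(m) {
      x <- outcomes[outcomes$month_index == m, c("user_id", col)]
      names(x)[2L] <- paste0("m", m)
      x
    })
    merged <- Reduce(function(a, b) merge(a, b, by = "user_id"), wide)
    mat <- as.matrix(merged[, -1L, drop = FALSE])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    res <- if (nrow(mat) >= 2L)
      tryCatch(repeated_measures_anova(mat, gg_correction),
               error = function(e) conditionMessage(e))
    else "not computable: fewer than 2 complete subjects"
    row <- data.frame(outcome = oc[[col]], n_subjects = nrow(mat),
                      k_timepoints = length(months), f_stat = NA_real_,
                      df_time = NA_integer_, df_error = NA_integer_,
                      p_value = NA_real_, note = "")
    if (inherits(res, "rm_anova_result")) {
      row$f_stat <- res$f_stat; row$df_time <- res$df_time
      row$df_error <- res$df_error; row$p_value <- res$p_value
    } else row$note <- if (is.character(res)) res else "not computable"
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
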