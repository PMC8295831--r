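# Independent oracles, deliberately written in a different style from the
# package (scalar, loop-based, explicit counters). These encode the
# diagnostic rules and numeric decompositions directly and are frozen: they
# must never call into the vectorized implementation they check.

# --- attack classification oracle -------------------------------------------
# x: a one-row list/data.frame with the attack fields; has_triptan: was a
# migraine-specific intake attributable to this attack; prior: prior
# headache diagnosis string.
oracle_classify_one <- function(x, has_triptan, prior) {
  dur <- as.numeric(difftime(x$end, x$start, units = "mins")) / 60

  a_count <- 0L
  if (isTRUE(x$unilateral)) a_count <- a_count + 1L
  if (isTRUE(x$throbbing)) a_count <- a_count + 1L
  if (x$max_intensity >= 4) a_count <- a_count + 1L
  if (isTRUE(x$worse_with_activity)) a_count <- a_count + 1L
  feat_a <- a_count >= 2L

  feat_b <- FALSE
  if (isTRUE(x$nausea)) feat_b <- TRUE
  if (isTRUE(x$vomitus)) feat_b <- TRUE
  if (isTRUE(x$photophobia) && isTRUE(x$phonophobia)) feat_b <- TRUE

  qualified <- (dur >= 4) && feat_a && feat_b
  override <- isTRUE(x$aura) || isTRUE(has_triptan)

  neg_count <- 0L
  if (!isTRUE(x$unilateral)) neg_count <- neg_count + 1L
  if (!isTRUE(x$throbbing)) neg_count <- neg_count + 1L
  if (x$max_intensity <= 7) neg_count <- neg_count + 1L
  if (!isTRUE(x$worse_with_activity)) neg_count <- neg_count + 1L
  photo_phono <- sum(c(isTRUE(x$photophobia), isTRUE(x$phonophobia)))
  tth <- (dur >= 0.5) && (dur <= 168) && neg_count >= 2L &&
    !isTRUE(x$nausea) && !isTRUE(x$vomitus) && photo_phono <= 1L

  n_failed <- 0L
  if (dur < 4) n_failed <- n_failed + 1L
  if (!feat_a) n_failed <- n_failed + 1L
  if (!feat_b) n_failed <- n_failed + 1L
  probable <- n_failed == 1L

  prior_mig <- identical(prior, "migraine")
  if (override || qualified) return("MIGRAINE")
  if (tth && probable) return(if (prior_mig) "MIGRAINE" else "TTH")
  if (tth) return("TTH")
  if (probable) return(if (prior_mig) "MIGRAINE" else "OTHER")
  "OTHER"
}

# --- calendar-day oracle ----------------------------------------------------
# Step through [start, end] in 1-hour increments (plus the endpoint) and
# collect the distinct calendar dates.
oracle_hour_stepping_days <- function(start, end) {
  t <- as.numeric(start)
  stop_t <- as.numeric(end)
  seen <- character()
  while (t < stop_t) {
    seen <- union(seen, format(as.POSIXct(t, tz = "UTC", origin = "1970-01-01"), "%Y-%m-%d"))
    t <- t + 3600
  }
  seen <- union(seen, format(as.POSIXct(stop_t, tz = "UTC", origin = "1970-01-01"), "%Y-%m-%d"))
  sort(as.Date(seen))
}

# --- repeated-measures ANOVA oracle -----------------------------------------
# Brute-force sums-of-squares decomposition with explicit double loops.
oracle_rm_anova_f <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_time <- 0
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(mat[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(mat[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (mat[i, j] - grand)^2
  ss_err <- ss_tot - ss_time - ss_subj
  (ss_time / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}
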