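# Long table of (user_id, date, max intensity) for every calendar day
# intersected by an attack; one row per attack x day.
attack_day_table <- function(attacks, attack_id = FALSE) {
  if (!nrow(attacks)) {
    out <- data.table(user_id = character(), date = as.Date(character()),
                      max_intensity = integer())
    if (attack_id) out[, attack_id := character()]
    return(out)
  }
  d0 <- as.Date(attacks$start, tz = "UTC")
  d1 <- as.Date(attacks$end, tz = "UTC")
  nd <- as.integer(d1 - d0) + 1L
  idx <- rep(seq_len(nrow(attacks)), nd)
  out <- data.table(
    user_id = attacks$user_id[idx],
    date = d0[idx] + (sequence(nd) - 1L),
    max_intensity = attacks$max_intensity[idx]
  )
  if (attack_id) out[, attack_id := attacks$attack_id[idx]]
  out
}

#' Calendar days covered by an attack
#'
#' Every calendar date intersected by the closed interval `[start, end]`;
#' headache-day and migraine-day outcomes are defined on calendar days, so a
#' multi-day attack contributes each intersected day.
#'
#' @param start,end `POSIXct` attack bounds with `end > start`.
#' @return A `Date` vector (for one attack) in increasing order.
#' @export
attack_calendar_days <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, end > start)
  seq(as.Date(start, tz = "UTC"), as.Date(end, tz = "UTC"), by = "day")
}

#' 28-day month index of a date
#'
#' A month is 4 weeks (28 days) beginning with the first day of app use:
#' month 1 (the baseline) covers days 0-27 after `first_use_date`.
#'
#' @param date,first_use_date `Date` vectors (recycled).
#' @return Integer month index, 1-based.
#' @export
month_index <- function(date, first_use_date) {
  delta <- as.integer(as.Date(date) - as.Date(first_use_date))
  if (any(delta < 0))
    stop("month_index: date before first_use_date")
  delta %/% 28L + 1L
}

#' Monthly outcomes per user and 28-day month
#'
#' For each user and each month `1..months` (month 1 = baseline):
#' * `mhd` -- monthly headache days: days with any attack;
#' * `mmd` -- monthly migraine days: days with at least one MIGRAINE-labelled
#'   attack;
#' * `amd` -- days with at least one acute-medication intake of any kind
#'   (triptan or not, regardless of attack linkage);
#' * `mean_headache_intensity` -- mean over headache days of the day's
#'   maximal attack intensity (`NA` when `mhd` is 0);
#' * `mean_migraine_intensity` -- the same over migraine days (`NA` when
#'   `mmd` is 0).
#'
#' Days falling after month `months` are ignored. Multi-day attacks count
#' every intersected day; an attack spanning a month boundary contributes a
#' day to each month.
#'
#' @param collection A [diary_collection()].
#' @param classifications Result of [classify_attacks()] covering all attacks.
#' @param months Number of 28-day months to aggregate.
#' @return A data frame with one row per user and month, ordered by
#'   `user_id`, `month_index`.
#' @export
compute_monthly_outcomes <- function(collection, classifications, months) {
  stopifnot(inherits(collection, "diary_collection"), months >= 1L)
  months <- as.integer(months)
  users <- collection$users
  if (!all(collection$attacks$attack_id %in% classifications$attack_id))
    stop("classifications must cover all attacks")

  grid <- data.table(user_id = rep(users$user_id, each = months),
                     month_index = rep(seq_len(months), nrow(users)))

  days <- attack_day_table(collection$attacks, attack_id = TRUE)
  if (nrow(days)) {
    days[, label := classifications$label[match(attack_id, classifications$attack_id)]]
    days[, first_use := users$first_use_date[match(user_id, users$user_id)]]
    # per user x day: any attack, any migraine attack, day's max intensities
    byday <- days[, .(
      intensity = max(max_intensity),
      mig = any(label == "MIGRAINE"),
      mig_intensity = if (any(label == "MIGRAINE"))
        max(max_intensity[label == "MIGRAINE"]) else NA_integer_
    ), by = .(user_id, date, first_use)]
    byday[, month_index := as.integer(date - first_use) %/% 28L + 1L]
    byday <- byday[month_index >= 1L & month_index <= months]
    agg <- byday[, .(
      mhd = .N,
      mmd = sum(mig),
      mean_headache_intensity = mean(intensity),
      mean_migraine_intensity = if (any(mig)) mean(mig_intensity[mig]) else NA_real_
    ), by = .(user_id, month_index)]
    grid <- merge(grid, agg, by = c("user_id", "month_index"), all.x = TRUE)
  } else {
    grid[, `:=`(mhd = NA_integer_, mmd = NA_integer_,
                mean_headache_intensity = NA_real_,
                mean_migraine_intensity = NA_real_)]
  }

  med <- collection$medications
  if (nrow(med)) {
    md <- data.table(user_id = med$user_id,
                     date = as.Date(med$intake_time, tz = "UTC"))
    md <- unique(md)
    md[, first_use := users$first_use_date[match(user_id, users$user_id)]]
    md[, month_index := as.integer(date - first_use) %/% 28L + 1L]
    md <- md[month_index >= 1L & month_index <= months]
    amd <- md[, .(amd = .N), by = .(user_id, month_index)]
    grid <- merge(grid, amd, by = c("user_id", "month_index"), all.x = TRUE)
  } else {
    grid[, amd := NA_integer_]
  }

  grid[is.na(mhd), `:=`(mhd = 0L)]
  grid[is.na(mmd), mmd := 0L]
  grid[is.na(amd), amd := 0L]
  data.table::setorder(grid, user_id, month_index)
  data.table::setcolorder(grid, c("user_id", "month_index", "mhd", "mmd", "amd",
                                  "mean_headache_intensity", "mean_migraine_intensity"))
  as.data.frame(grid)
}

#' Episodic/chronic migraine grouping from the first 90 days
#'
#' Over days 1-90 of app use (from `first_use_date`):
#' * `CHRONIC_MIGRAINE` if headache days >= `chronic_headache_days` (default
#'   45, i.e. 15 per 30-day month) and migraine days >= `chronic_migraine_days`
#'   (default 24, i.e. 8 per 30-day month);
#' * else `EPISODIC_MIGRAINE` if at least `episodic_min_attacks` (default 5)
#'   MIGRAINE-labelled attacks started in the window;
#' * else `OTHER`.
#'
#' @param collection A [diary_collection()]; every user must have at least 90
#'   observed days (daily entries and/or attack-covered days through day 90).
#' @param classifications Result of [classify_attacks()].
#' @param chronic_headache_days,chronic_migraine_days,episodic_min_attacks
#'   Thresholds applied to 90-day totals.
#' @return A data frame `user_id`, `group`.
#' @export
assign_diagnosis_group <- function(collection, classifications,
                                   chronic_headache_days = 45L,
                                   chronic_migraine_days = 24L,
                                   episodic_min_attacks = 5L) {
  stopifnot(inherits(collection, "diary_collection"))
  users <- collection$users

  covered <- covered_day_table(collection)
  last_obs <- covered[, .(last = max(date)), by = user_id]
  fu <- users$first_use_date
  last <- last_obs$last[match(users$user_id, last_obs$user_id)]
  obs_days <- as.integer(last - fu) + 1L
  obs_days[is.na(obs_days)] <- 0L
  if (any(obs_days < 90L))
    stop("assign_diagnosis_group: fewer than 90 days observed for user(s) ",
         paste(utils::head(users$user_id[obs_days < 90L], 3L), collapse = ", "))

  days <- attack_day_table(collection$attacks, attack_id = TRUE)
  a <- collection$attacks
  lab <- classifications$label[match(a$attack_id, classifications$attack_id)]

  hd <- md <- na <- integer(nrow(users))
  if (nrow(days)) {
    days[, label := classifications$label[match(attack_id, classifications$attack_id)]]
    days[, offset := as.integer(date - users$first_use_date[match(user_id, users$user_id)])]
    win <- days[offset >= 0L & offset <= 89L]
    counts <- win[, .(hd = data.table::uniqueN(date),
                      md = data.table::uniqueN(date[label == "MIGRAINE"])),
                  by = user_id]
    hd <- counts$hd[match(users$user_id, counts$user_id)]
    md <- counts$md[match(users$user_id, counts$user_id)]
    hd[is.na(hd)] <- 0L; md[is.na(md)] <- 0L

    start_off <- as.integer(as.Date(a$start, tz = "UTC") -
                              users$first_use_date[match(a$user_id, users$user_id)])
    in_win <- lab == "MIGRAINE" & start_off >= 0L & start_off <= 89L
    tab <- table(a$user_id[in_win])
    na <- as.integer(tab[match(users$user_id, names(tab))])
    na[is.na(na)] <- 0L
  }

  group <- ifelse(hd >= chronic_headache_days & md >= chronic_migraine_days,
                  "CHRONIC_MIGRAINE",
                  ifelse(na >= episodic_min_attacks, "EPISODIC_MIGRAINE", "OTHER"))
  data.frame(user_id = users$user_id, group = group)
}

# Days on which a user demonstrably interacted with the diary: any daily
# entry, or any attack-covered calendar day.
covered_day_table <- function(collection) {
  e <- collection$entries
  ed <- data.table(user_id = e$user_id, date = as.Date(e$entry_date))
  ad <- attack_day_table(collection$attacks)[, .(user_id, date)]
  unique(rbindlist(list(ed, ad)))
}

#' Select users with complete daily app use
#'
#' A user qualifies when every calendar day from `first_use_date` through day
#' `28 * months_required` is covered by a daily entry or an attack.
#'
#' @param collection A [diary_collection()].
#' @param months_required Number of complete 28-day months required.
#' @return Character vector of qualifying `user_id`s.
#' @export
select_regular_users <- function(collection, months_required) {
  stopifnot(inherits(collection, "diary_collection"), months_required >= 1L)
  need <- 28L * as.integer(months_required)
  users <- collection$users
  covered <- covered_day_table(collection)
  covered[, first_use := users$first_use_date[match(user_id, users$user_id)]]
  covered[, offset := as.integer(date - first_use)]
  ok <- covered[offset >= 0L & offset < need,
                .(n = data.table::uniqueN(offset)), by = user_id]
  ok$user_id[ok$n == need]
}
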