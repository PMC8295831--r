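test_that("attack calendar days match the hour-stepping oracle", {
  cases <- list(
    c("2020-01-05 10:00:00", "2020-01-05 14:00:00"),
    c("2020-01-05 23:00:00", "2020-01-06 02:00:00"),
    c("2020-01-05 22:00:00", "2020-01-07 01:00:00"),
    c("2020-02-28 12:00:00", "2020-03-01 00:30:00")   # leap day span
  )
  for (cs in cases) {
    expect_equal(attack_calendar_days(ts(cs[1]), ts(cs[2])),
                 oracle_hour_stepping_days(ts(cs[1]), ts(cs[2])))
  }
  expect_equal(attack_calendar_days(ts("2020-01-05 10:00:00"), ts("2020-01-05 14:00:00")),
               as.Date("2020-01-05"))
})

test_that("month_index is exact at the 28-day boundaries", {
  fu <- as.Date("2020-03-01")
  expect_equal(month_index(fu, fu), 1L)
  expect_equal(month_index(fu + 27, fu), 1L)
  expect_equal(month_index(fu + 28, fu), 2L)
  expect_equal(month_index(fu + 28 * 6, fu), 7L)
  expect_error(month_index(fu - 1, fu), "before first_use_date")
})

test_that("monthly outcomes for the hand-counted toy diary are exact", {
  col <- read_diary(path_toy("users.csv"), path_toy("attacks.csv"),
                    path_toy("medications.csv"), path_toy("entries.csv"))
  cls <- classify_attacks(col)
  expect_equal(cls$label[match(c("a1", "a2", "a3", "a4", "a5", "a6"), cls$attack_id)],
               c("MIGRAINE", "TTH", "MIGRAINE", "MIGRAINE", "MIGRAINE", "MIGRAINE"))
  expect_equal(cls$label[match(c("b1", "b2", "b3"), cls$attack_id)],
               c("TTH", "TTH", "MIGRAINE"))

  out <- compute_monthly_outcomes(col, cls, months = 4)
  g <- function(u, m) out[out$user_id == u & out$month_index == m, ]

  expect_equal(unlist(g("u1", 1)[, c("mhd", "mmd", "amd")]), c(mhd = 4, mmd = 2, amd = 2))
  expect_equal(g("u1", 1)$mean_headache_intensity, 6.25)
  expect_equal(g("u1", 1)$mean_migraine_intensity, 7.5)
  expect_equal(unlist(g("u1", 2)[, c("mhd", "mmd", "amd")]), c(mhd = 2, mmd = 2, amd = 1))
  expect_equal(g("u1", 2)$mean_headache_intensity, 6)
  expect_equal(unlist(g("u2", 1)[, c("mhd", "mmd", "amd")]), c(mhd = 2, mmd = 0, amd = 1))
  expect_equal(g("u2", 1)$mean_headache_intensity, 4.5)
  expect_true(is.na(g("u2", 1)$mean_migraine_intensity))
  expect_equal(unlist(g("u3", 1)[, c("mhd", "mmd", "amd")]), c(mhd = 0, mmd = 0, amd = 0))
  expect_true(is.na(g("u3", 1)$mean_headache_intensity))
})

test_that("a user with no attacks yields zero counts and undefined intensities", {
  col <- diary_collection(make_user("lonely"),
                          entries = make_entries("lonely", as.Date("2020-01-01") + 0:27))
  out <- compute_monthly_outcomes(col, classify_attacks(col), months = 1)
  expect_equal(out$mhd, 0L)
  expect_equal(out$mmd, 0L)
  expect_equal(out$amd, 0L)
  expect_true(is.na(out$mean_headache_intensity))
})

test_that("an attack spanning the month boundary contributes a day to each month", {
  a <- make_attack(start = "2020-01-28 22:00:00", end = "2020-01-29 03:00:00",
                   nausea = TRUE, unilateral = TRUE, throbbing = TRUE)
  col <- diary_collection(make_user(), a)
  out <- compute_monthly_outcomes(col, classify_attacks(col), months = 2)
  expect_equal(out$mhd, c(1L, 1L))   # Jan 28 is day 28 (month 1), Jan 29 month 2
  expect_equal(out$mmd, c(1L, 1L))
})

test_that("diagnosis groups: chronic, episodic and other thresholds", {
  fu <- as.Date("2020-01-01")
  # chronic: 50 attack days in the first 90, all migraine-qualifying
  mk_run <- function(uid, dates, intensity = 7L) {
    do.call(rbind, lapply(seq_along(dates), function(i)
      make_attack(paste0(uid, "_", i), uid,
                  start = paste(dates[i], "09:00:00"),
                  end = paste(dates[i], "15:00:00"),
                  max_intensity = intensity,
                  unilateral = TRUE, throbbing = TRUE, nausea = TRUE)))
  }
  chronic_attacks <- mk_run("cu", fu + seq(0, 89, length.out = 50))
  # episodic: 6 migraine days well under chronic thresholds
  epi_attacks <- mk_run("eu", fu + c(3, 10, 25, 40, 61, 80))
  # other: TTH only
  oth_attacks <- do.call(rbind, lapply(1:4, function(i)
    make_attack(paste0("ou_", i), "ou",
                start = paste(fu + 10 * i, "10:00:00"),
                end = paste(fu + 10 * i, "16:00:00"), max_intensity = 4L)))
  users <- rbind(make_user("cu"), make_user("eu"), make_user("ou"))
  users$first_use_date <- fu
  attacks <- rbind(chronic_attacks, epi_attacks, oth_attacks)
  col <- diary_collection(users, attacks,
                          entries = full_coverage_entries(users, attacks, 90))
  grp <- assign_diagnosis_group(col, classify_attacks(col))
  expect_equal(grp$group[match(c("cu", "eu", "ou"), grp$user_id)],
               c("CHRONIC_MIGRAINE", "EPISODIC_MIGRAINE", "OTHER"))
})

test_that("diagnosis grouping refuses users with under 90 observed days", {
  col <- diary_collection(make_user(),
                          entries = make_entries("u1", as.Date("2020-01-01") + 0:59))
  expect_error(assign_diagnosis_group(col, classify_attacks(col)),
               "fewer than 90 days")
})

test_that("regular-user selection requires every single day", {
  fu <- as.Date("2020-01-01")
  users <- rbind(make_user("full"), make_user("hole"), make_user("short"))
  n <- 28 * 7
  entries <- rbind(
    make_entries("full", fu + 0:(n - 1)),
    make_entries("hole", (fu + 0:(n - 1))[-100]),   # one missing day
    make_entries("short", fu + 0:(n - 30))
  )
  col <- diary_collection(users, entries = entries)
  expect_equal(select_regular_users(col, 7), "full")
  # an attack-covered day substitutes for an entry
  a <- make_attack("ha", "hole", start = paste(fu + 99, "10:00:00"),
                   end = paste(fu + 99, "12:00:00"))
  col2 <- diary_collection(users, a, entries = entries)
  expect_setequal(select_regular_users(col2, 7), c("full", "hole"))
})

test_that("fuzzed diaries: MMD <= MHD <= 28, AMD <= 28, months nest", {
  set.seed(2024)
  for (r in 1:40) {
    cfg <- simulation_config(
      n_users = sample(2:5, 1), months = sample(2:4, 1),
      frac_migraineur = runif(1), baseline_daily_hazard = runif(1, 0.05, 0.9),
      monthly_decline = runif(1, 0.7, 1), allow_multiday = r %% 2 == 0,
      seed = 5000 + r)
    coh <- generate_cohort(cfg)
    out <- compute_monthly_outcomes(coh$collection, classify_attacks(coh$collection),
                                    cfg$months)
    expect_true(all(out$mmd <= out$mhd))
    expect_true(all(out$mhd <= 28))
    expect_true(all(out$amd <= 28))
    # total MHD equals the user's distinct headache days in the window
    tot <- tapply(out$mhd, out$user_id, sum)
    a <- coh$collection$attacks
    for (u in names(tot)) {
      au <- a[a$user_id == u, ]
      days <- as.Date(character())
      for (i in seq_len(nrow(au)))
        days <- union(days, oracle_hour_stepping_days(au$start[i], au$end[i]))
      fu <- coh$collection$users$first_use_date[coh$collection$users$user_id == u]
      days <- days[days <= fu + 28 * cfg$months - 1]
      expect_equal(unname(tot[u]), length(unique(days)))
    }
    expect_true(all(select_regular_users(coh$collection, cfg$months) %in%
                      select_regular_users(coh$collection, 1)))
  }
})
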