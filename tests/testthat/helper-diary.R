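# Builders for compact in-code fixtures.

ts <- function(x) as.POSIXct(x, tz = "UTC")

make_user <- function(user_id = "u1", sex = "female", age = 35L,
                      prior_diagnosis = "none",
                      first_use_date = as.Date("2020-01-01")) {
  data.frame(user_id = user_id, sex = sex, age = age,
             prior_diagnosis = prior_diagnosis, first_use_date = first_use_date)
}

make_attack <- function(attack_id = "a1", user_id = "u1",
                        start = "2020-01-02 10:00:00", end = "2020-01-02 15:00:00",
                        max_intensity = 6L, unilateral = FALSE, throbbing = FALSE,
                        worse_with_activity = FALSE, nausea = FALSE,
                        vomitus = FALSE, photophobia = FALSE,
                        phonophobia = FALSE, aura = FALSE) {
  data.frame(attack_id = attack_id, user_id = user_id,
             start = ts(start), end = ts(end), max_intensity = max_intensity,
             unilateral = unilateral, throbbing = throbbing,
             worse_with_activity = worse_with_activity, nausea = nausea,
             vomitus = vomitus, photophobia = photophobia,
             phonophobia = phonophobia, aura = aura)
}

make_med <- function(user_id = "u1", drug_name = "Ibuprofen", dose = "400 mg",
                     intake_time = "2020-01-02 10:30:00",
                     migraine_specific = NA) {
  data.frame(user_id = user_id, drug_name = drug_name, dose = dose,
             intake_time = ts(intake_time), migraine_specific = migraine_specific)
}

make_entries <- function(user_id, dates, kind = "no_headache") {
  data.frame(user_id = user_id, entry_date = as.Date(dates), entry_kind = kind)
}

# Full daily-entry coverage for each user over n_days from first use; attack
# days omitted (they are covered by the attacks themselves).
full_coverage_entries <- function(users, attacks, n_days) {
  out <- list()
  for (i in seq_len(nrow(users))) {
    uid <- users$user_id[i]
    days <- users$first_use_date[i] + 0:(n_days - 1L)
    a <- attacks[attacks$user_id == uid, , drop = FALSE]
    cov <- as.Date(character())
    for (j in seq_len(nrow(a)))
      cov <- c(cov, seq(as.Date(a$start[j], tz = "UTC"),
                        as.Date(a$end[j], tz = "UTC"), by = "day"))
    out[[i]] <- make_entries(uid, days[!days %in% cov])
  }
  do.call(rbind, out)
}

path_toy <- function(file) {
  system.file("extdata", "toy_diary", file, package = "headachediary")
}
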