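test_that("attack duration is exact to the minute, across midnight too", {
  a <- rbind(
    make_attack("a1", start = "2020-01-05 10:00:00", end = "2020-01-05 14:00:00"),
    make_attack("a2", start = "2020-01-05 23:00:00", end = "2020-01-06 03:30:00"),
    make_attack("a3", start = "2020-01-05 10:00:00", end = "2020-01-05 10:30:00")
  )
  expect_equal(attack_duration_hours(a), c(4, 4.5, 0.5))
})

test_that("feature A counts >= 2 of the four indicators", {
  expect_true(meets_feature_a(make_attack(unilateral = TRUE, throbbing = TRUE,
                                          max_intensity = 3L)))
  expect_false(meets_feature_a(make_attack(max_intensity = 2L)))
  # single indicators never suffice; intensity>=4 plus activity do
  expect_true(meets_feature_a(make_attack(max_intensity = 9L,
                                          worse_with_activity = TRUE)))
  # exhaustive 2^4 grid against an explicit counter
  grid <- expand.grid(u = c(F, T), t = c(F, T), i = c(2L, 6L), w = c(F, T))
  for (r in seq_len(nrow(grid))) {
    a <- make_attack(unilateral = grid$u[r], throbbing = grid$t[r],
                     max_intensity = grid$i[r], worse_with_activity = grid$w[r])
    expect_equal(meets_feature_a(a),
                 (grid$u[r] + grid$t[r] + (grid$i[r] >= 4) + grid$w[r]) >= 2)
  }
})

test_that("feature B: nausea/vomiting disjunctive, photo+phonophobia conjunctive", {
  expect_true(meets_feature_b(make_attack(nausea = TRUE)))
  expect_true(meets_feature_b(make_attack(vomitus = TRUE)))
  expect_false(meets_feature_b(make_attack(photophobia = TRUE)))
  expect_true(meets_feature_b(make_attack(photophobia = TRUE, phonophobia = TRUE)))
  expect_false(meets_feature_b(make_attack()))
})

test_that("qualified migraine needs duration >= 4 h plus A plus B", {
  qm <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 15:00:00",
                    unilateral = TRUE, throbbing = TRUE, nausea = TRUE)
  expect_true(is_qualified_migraine(qm))
  short <- qm; short$end <- ts("2020-01-02 13:54:00")   # 3.9 h
  expect_false(is_qualified_migraine(short))
  a_only <- qm; a_only$nausea <- FALSE
  expect_false(is_qualified_migraine(a_only))
})

test_that("aura and attributable triptan intake override everything", {
  brief <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 11:00:00",
                       max_intensity = 2L, aura = TRUE)
  expect_true(has_migraine_override(brief))
  plain <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 14:00:00")
  expect_true(has_migraine_override(plain, make_med(drug_name = "Sumatriptan 50mg",
                                                    intake_time = "2020-01-02 11:00:00")))
  expect_false(has_migraine_override(plain, make_med(drug_name = "Ibuprofen",
                                                     intake_time = "2020-01-02 11:00:00")))
  # attribution window: one hour before start through end
  before <- make_med(drug_name = "Sumatriptan", intake_time = "2020-01-02 09:10:00")
  expect_true(has_migraine_override(plain, before))
  too_early <- make_med(drug_name = "Sumatriptan", intake_time = "2020-01-02 08:30:00")
  expect_false(has_migraine_override(plain, too_early))
  after_end <- make_med(drug_name = "Sumatriptan", intake_time = "2020-01-02 15:00:00")
  expect_false(has_migraine_override(plain, after_end))
})

test_that("TTH criteria: window, negated pain features, symptom limits", {
  tth <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 16:00:00",
                     max_intensity = 4L)
  expect_true(meets_tth_criteria(tth))
  expect_equal(oracle_classify_one(tth, FALSE, "none"), "TTH")
  nau <- tth; nau$nausea <- TRUE
  expect_false(meets_tth_criteria(nau))
  both <- tth; both$photophobia <- TRUE; both$phonophobia <- TRUE
  expect_false(meets_tth_criteria(both))
  shortest <- tth; shortest$end <- ts("2020-01-02 10:20:00")  # 20 min
  expect_false(meets_tth_criteria(shortest))
  week_plus <- tth; week_plus$end <- ts("2020-01-09 11:00:00")  # 169 h
  expect_false(meets_tth_criteria(week_plus))
})

test_that("probable migraine = exactly one failed migraine conjunct", {
  a_and_dur <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 15:00:00",
                           unilateral = TRUE, throbbing = TRUE)
  expect_true(meets_probable_migraine(a_and_dur))           # B fails
  full <- a_and_dur; full$nausea <- TRUE
  expect_false(meets_probable_migraine(full))               # zero failures
  two_fail <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 12:00:00")
  expect_false(meets_probable_migraine(two_fail))           # duration + A (+B)
})

test_that("classification follows the hierarchy and the prior-diagnosis rule", {
  qm <- make_attack(start = "2020-01-02 10:00:00", end = "2020-01-02 15:00:00",
                    unilateral = TRUE, throbbing = TRUE, nausea = TRUE)
  expect_equal(classify_attacks(qm, prior_diagnosis = "none")$label, "MIGRAINE")

  # TTH-and-probable tie: broken by prior diagnosis ("general rule of hierarchy")
  tie <- make_attack(start = "2020-01-02 09:00:00", end = "2020-01-02 14:00:00",
                     unilateral = TRUE, throbbing = TRUE, max_intensity = 5L)
  expect_equal(classify_attacks(tie, prior_diagnosis = "none")$label, "TTH")
  expect_equal(classify_attacks(tie, prior_diagnosis = "migraine")$label, "MIGRAINE")

  # probable-only (not TTH): OTHER without a prior migraine diagnosis
  prob <- make_attack(start = "2020-01-02 08:00:00", end = "2020-01-02 10:00:00",
                      max_intensity = 8L, unilateral = TRUE, throbbing = TRUE,
                      worse_with_activity = TRUE, nausea = TRUE)
  expect_equal(classify_attacks(prob, prior_diagnosis = "none")$label, "OTHER")
  expect_equal(classify_attacks(prob, prior_diagnosis = "migraine")$label, "MIGRAINE")

  tr <- classify_attacks(qm, prior_diagnosis = "none")$rule_trace
  expect_match(tr, "qualified_migraine")
})

test_that("drug-name lookup is case-insensitive substring with flag precedence", {
  expect_true(is_migraine_specific("Sumatriptan 50mg"))
  expect_true(is_migraine_specific("RIZATRIPTAN odt"))
  expect_false(is_migraine_specific("ibuprofen"))
  expect_true(is_migraine_specific("unknown", explicit_flag = TRUE))
  expect_false(is_migraine_specific("sumatriptan", explicit_flag = FALSE))
})

test_that("override dominance and qualified-migraine monotonicity (fuzzed)", {
  set.seed(7)
  for (r in 1:60) {
    dur_h <- sample(c(1, 3, 5, 30), 1)
    a <- make_attack(start = "2020-01-02 08:00:00",
                     end = format(ts("2020-01-02 08:00:00") + dur_h * 3600),
                     max_intensity = sample(0:10, 1),
                     unilateral = runif(1) < .5, throbbing = runif(1) < .5,
                     worse_with_activity = runif(1) < .5, nausea = runif(1) < .5,
                     vomitus = runif(1) < .5, photophobia = runif(1) < .5,
                     phonophobia = runif(1) < .5, aura = runif(1) < .5)
    prior <- sample(c("migraine", "none"), 1)

    with_aura <- a; with_aura$aura <- TRUE
    expect_equal(classify_attacks(with_aura, prior_diagnosis = prior)$label, "MIGRAINE")
    med <- make_med(drug_name = "zolmitriptan",
                    intake_time = format(a$start + 600))
    expect_equal(classify_attacks(a, medications = med,
                                  prior_diagnosis = prior)$label[1], "MIGRAINE")

    # adding indicators / lengthening never turns qualified off
    if (is_qualified_migraine(a)) {
      more <- a
      more$nausea <- TRUE; more$unilateral <- TRUE
      more$end <- more$end + 3600
      expect_true(is_qualified_migraine(more))
    }
  }
})

test_that("determinism: identical input gives identical labels and traces", {
  coh <- generate_cohort(simulation_config(n_users = 10, months = 2, seed = 5))$collection
  c1 <- classify_attacks(coh)
  c2 <- classify_attacks(coh)
  expect_identical(c1, c2)
})

test_that("prior diagnosis only matters where probable migraine holds without qualification", {
  coh <- generate_cohort(simulation_config(n_users = 15, months = 2, seed = 31))$collection
  a <- coh$attacks
  lab_mig <- classify_attacks(a, medications = coh$medications,
                              prior_diagnosis = "migraine")$label
  lab_none <- classify_attacks(a, medications = coh$medications,
                               prior_diagnosis = "none")$label
  differs <- lab_mig != lab_none
  cfg <- classifier_config()
  expect_true(all(meets_probable_migraine(a[differs, ], cfg)))
  expect_true(!any(is_qualified_migraine(a[differs, ], cfg)))
})
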