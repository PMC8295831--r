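#' Default symptom profiles for the synthetic generator
#'
#' Per-attack probabilities of the eight boolean flags, a discretised-normal
#' intensity distribution and a lognormal duration distribution, for the two
#' latent attack types. The migraineur profile is chosen so that the large
#' majority of migraineur-type attacks classify as MIGRAINE (unilateral 0.7,
#' throbbing 0.8, intensity mean 6, nausea 0.6, photophobia 0.7, phonophobia
#' 0.6, aura 0.2, median duration 12 h); the TTH profile is complementary
#' (bilateral, pressing, mild-moderate, median 4 h, no aura).
#'
#' @return A named list with elements `migraineur` and `tth_type`.
#' @export
default_symptom_profiles <- function() {
  list(
    migraineur = list(
      unilateral = 0.7, throbbing = 0.8, worse_with_activity = 0.6,
      nausea = 0.6, vomitus = 0.2, photophobia = 0.7, phonophobia = 0.6,
      aura = 0.2,
      intensity_mean = 6, intensity_sd = 1.5, intensity_min = 1, intensity_max = 10,
      duration_median_hours = 12, duration_sdlog = 0.5
    ),
    tth_type = list(
      unilateral = 0.1, throbbing = 0.1, worse_with_activity = 0.15,
      nausea = 0, vomitus = 0, photophobia = 0.15, phonophobia = 0.15,
      aura = 0,
      intensity_mean = 4, intensity_sd = 1.5, intensity_min = 1, intensity_max = 7,
      duration_median_hours = 4, duration_sdlog = 0.6
    )
  )
}

#' Configuration of the synthetic diary generator
#'
#' The generated world: each user is latently a migraineur or a TTH-type
#' headache sufferer; on each day of month `m` an attack occurs with hazard
#' `baseline_daily_hazard * monthly_decline^(m - 1)`; symptom flags,
#' intensity and duration are drawn from the latent type's profile; every
#' attack-free day gets a `no_headache` entry, so every generated user is a
#' complete daily user.
#'
#' The frequency defaults are calibrated to the reference cohort: a baseline
#' expectation of 9.42 headache days per 28-day month (hazard 9.42/28) that
#' declines to 6.39 by month 7 (`monthly_decline = (6.39/9.42)^(1/6)`), 72%
#' migraineurs, sex missing for 32% of users and 87.9% female among the
#' remainder, age missing for 25% and N(37.2, 11.1) among the remainder.
#'
#' @param n_users Number of users.
#' @param months Number of complete 28-day months each user is observed.
#' @param frac_migraineur Probability a user is a latent migraineur.
#' @param baseline_daily_hazard Per-day attack probability in month 1.
#' @param monthly_decline Multiplicative per-month hazard factor (1 = no
#'   change over time).
#' @param symptom_profiles See [default_symptom_profiles()].
#' @param p_acute_medication Probability an attack is treated with acute
#'   medication.
#' @param p_triptan_given_migraineur Probability a treated migraineur attack
#'   uses a triptan rather than a plain analgesic.
#' @param p_missing_sex,p_missing_age Demographic missingness.
#' @param p_female Probability of female sex among users with recorded sex.
#' @param prior_dx_rule `"from_latent"` (migraineurs report a prior migraine
#'   diagnosis with probability 0.8), `"none"` or `"all_migraine"`.
#' @param chronic_frac Fraction of migraineurs drawn from a high-hazard
#'   chronic stratum (0 disables it and keeps expectations closed-form).
#' @param chronic_daily_hazard Baseline daily hazard of the chronic stratum.
#' @param hazard_dispersion Optional Beta overdispersion of the per-user
#'   hazard: `NULL` for none, otherwise the Beta "sample size" `s` so that a
#'   user's hazard is `Beta(h*s, (1-h)*s)` with mean `h`.
#' @param allow_multiday Allow attack durations to spill across midnight
#'   (default `FALSE`: attacks are truncated to their calendar day so day
#'   counts equal attack counts and expectations stay closed-form).
#' @param start_date First possible first-use date.
#' @param stagger_days First-use dates are spread uniformly over this many
#'   days.
#' @param seed Integer RNG seed; the whole collection is reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_users = 100L,
                              months = 7L,
                              frac_migraineur = 0.72,
                              baseline_daily_hazard = 9.42 / 28,
                              monthly_decline = (6.39 / 9.42)^(1 / 6),
                              symptom_profiles = default_symptom_profiles(),
                              p_acute_medication = 0.6,
                              p_triptan_given_migraineur = 0.5,
                              p_missing_sex = 498 / 1545,
                              p_missing_age = 393 / 1545,
                              p_female = 0.879,
                              prior_dx_rule = c("from_latent", "none", "all_migraine"),
                              chronic_frac = 0,
                              chronic_daily_hazard = 18 / 28,
                              hazard_dispersion = NULL,
                              allow_multiday = FALSE,
                              start_date = as.Date("2019-01-01"),
                              stagger_days = 60L,
                              seed = 1L) {
  prior_dx_rule <- match.arg(prior_dx_rule)
  probs <- c(frac_migraineur, baseline_daily_hazard, monthly_decline,
             p_acute_medication, p_triptan_given_migraineur,
             p_missing_sex, p_missing_age, p_female, chronic_frac,
             chronic_daily_hazard)
  if (any(probs < 0 | probs > 1))
    stop("simulation_config: all probabilities must lie in [0, 1]")
  if (months < 1L || n_users < 1L)
    stop("simulation_config: n_users and months must be >= 1")
  if (baseline_daily_hazard > 0.95 || chronic_daily_hazard > 0.95)
    stop("infeasible config: daily hazard too high to avoid overlapping attacks")
  structure(list(
    n_users = as.integer(n_users), months = as.integer(months),
    frac_migraineur = frac_migraineur,
    baseline_daily_hazard = baseline_daily_hazard,
    monthly_decline = monthly_decline,
    symptom_profiles = symptom_profiles,
    p_acute_medication = p_acute_medication,
    p_triptan_given_migraineur = p_triptan_given_migraineur,
    p_missing_sex = p_missing_sex, p_missing_age = p_missing_age,
    p_female = p_female, prior_dx_rule = prior_dx_rule,
    chronic_frac = chronic_frac, chronic_daily_hazard = chronic_daily_hazard,
    hazard_dispersion = hazard_dispersion,
    allow_multiday = allow_multiday,
    start_date = as.Date(start_date), stagger_days = as.integer(stagger_days),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Expected monthly headache days under a generator configuration
#'
#' Closed form for the default single-day-attack world: the number of attack
#' days in a 28-day month is Binomial(28, h_m) with
#' `h_m = baseline_daily_hazard * monthly_decline^(m - 1)`, so the expected
#' MHD is `28 * h_m`.
#'
#' @param config A [simulation_config()].
#' @param month 28-day month index (1 = baseline).
#' @return Expected monthly headache days (real).
#' @export
expected_mhd <- function(config, month) {
  stopifnot(inherits(config, "simulation_config"), month >= 1)
  28 * config$baseline_daily_hazard * config$monthly_decline^(month - 1)
}

#' Generate a synthetic diary cohort
#'
#' Simulates the world described by [simulation_config()] and returns the
#' resulting validated [diary_collection()] together with the latent ground
#' truth (per-user type and monthly hazards, per-attack type) for
#' parameter-recovery tests. Identical seeds give identical collections.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `collection` (a [diary_collection()]) and
#'   `truth` (list of `users` and `attacks` data frames, plus the per-user
#'   by month hazard matrix `hazards`).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_users
  n_days <- config$months * 28L

  user_id <- sprintf("u%05d", seq_len(n))
  migraineur <- runif(n) < config$frac_migraineur
  chronic <- migraineur & (runif(n) < config$chronic_frac)
  base_h <- ifelse(chronic, config$chronic_daily_hazard, config$baseline_daily_hazard)
  if (!is.null(config$hazard_dispersion)) {
    s <- config$hazard_dispersion
    base_h <- stats::rbeta(n, base_h * s, (1 - base_h) * s)
  }
  first_use <- config$start_date +
    sample.int(config$stagger_days, n, replace = TRUE) - 1L

  # per-user x day hazards, user-major
  month_of_day <- rep(seq_len(config$months), each = 28L)
  decline <- config$monthly_decline^(month_of_day - 1)
  hazards_mat <- outer(base_h, config$monthly_decline^(seq_len(config$months) - 1))
  h <- rep(base_h, each = n_days) * rep(decline, times = n)
  hit <- rbinom(n * n_days, 1L, h) == 1L

  uidx <- rep(seq_len(n), each = n_days)[hit]
  off <- rep(seq_len(n_days) - 1L, times = n)[hit]
  n_att <- sum(hit)
  prof <- config$symptom_profiles
  type <- ifelse(migraineur[uidx], "migraineur", "tth_type")

  draw <- function(field) {
    p <- ifelse(type == "migraineur", prof$migraineur[[field]], prof$tth_type[[field]])
    runif(n_att) < p
  }
  pick <- function(field) {
    ifelse(type == "migraineur", prof$migraineur[[field]], prof$tth_type[[field]])
  }

  date <- first_use[uidx] + off
  start_min <- floor(runif(n_att, 8 * 60, 16 * 60))
  dur_min <- round(60 * rlnorm(n_att, log(pick("duration_median_hours")),
                               pick("duration_sdlog")))
  dur_min <- pmax(dur_min, 30)
  if (!config$allow_multiday) {
    dur_min <- pmin(dur_min, (24L * 60L - 1L) - start_min)
  } else {
    dur_min <- pmin(dur_min, 72 * 60)
  }
  start <- as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + 60 * start_min,
                      tz = "UTC", origin = "1970-01-01")
  end <- start + 60 * dur_min

  intensity <- as.integer(pmin(pmax(round(rnorm(n_att, pick("intensity_mean"),
                                                pick("intensity_sd"))),
                                    pick("intensity_min")), pick("intensity_max")))

  attacks <- data.frame(
    attack_id = sprintf("a%07d", seq_len(n_att)),
    user_id = user_id[uidx], start = start, end = end,
    max_intensity = intensity,
    unilateral = draw("unilateral"), throbbing = draw("throbbing"),
    worse_with_activity = draw("worse_with_activity"),
    nausea = draw("nausea"), vomitus = draw("vomitus"),
    photophobia = draw("photophobia"), phonophobia = draw("phonophobia"),
    aura = draw("aura")
  )

  if (config$allow_multiday && n_att > 1L) {
    # truncate an attack at the next attack of the same user (minus 1 minute)
    o <- order(attacks$user_id, attacks$start)
    same <- attacks$user_id[o][-1L] == attacks$user_id[o][-n_att]
    nxt <- c(as.numeric(attacks$start[o][-1L]), NA)
    endv <- as.numeric(attacks$end[o])
    cap <- ifelse(c(same, FALSE), nxt - 60, Inf)
    attacks$end[o] <- as.POSIXct(pmin(endv, cap), tz = "UTC", origin = "1970-01-01")
  }

  treated <- runif(n_att) < config$p_acute_medication
  triptan <- treated & migraineur[uidx] &
    (runif(n_att) < config$p_triptan_given_migraineur)
  medications <- data.frame(
    user_id = attacks$user_id[treated],
    drug_name = ifelse(triptan[treated], "Sumatriptan", "Ibuprofen"),
    dose = ifelse(triptan[treated], "50 mg", "400 mg"),
    intake_time = attacks$start[treated] + 30 * 60,
    migraine_specific = rep(NA, sum(treated))
  )

  covered <- attack_day_table(attacks)
  all_days <- data.table(user_id = rep(user_id, each = n_days),
                         entry_date = rep(first_use, each = n_days) +
                           rep(seq_len(n_days) - 1L, times = n))
  free <- all_days[!covered, on = c(user_id = "user_id", entry_date = "date")]
  entries <- data.frame(user_id = free$user_id, entry_date = free$entry_date,
                        entry_kind = "no_headache")

  sex <- ifelse(runif(n) < config$p_missing_sex, "unknown",
                ifelse(runif(n) < config$p_female, "female", "male"))
  age <- ifelse(runif(n) < config$p_missing_age, NA_integer_,
                as.integer(pmin(pmax(round(rnorm(n, 37.2, 11.1)), 18L), 80L)))
  prior <- switch(config$prior_dx_rule,
    from_latent = ifelse(migraineur & runif(n) < 0.8, "migraine",
                         ifelse(runif(n) < 0.5, "none", "unknown")),
    none = rep("none", n),
    all_migraine = rep("migraine", n))

  users <- data.frame(user_id = user_id, sex = sex, age = age,
                      prior_diagnosis = prior, first_use_date = first_use)

  collection <- diary_collection(users, attacks, medications, entries)
  truth <- list(
    users = data.frame(user_id = user_id,
                       latent_type = ifelse(migraineur, "migraineur", "tth_type"),
                       chronic_stratum = chronic,
                       base_daily_hazard = base_h),
    hazards = hazards_mat,
    attacks = data.frame(attack_id = attacks$attack_id,
                         latent_type = type)
  )
  list(collection = collection, truth = truth)
}
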