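#' Intensity bands on the 0-10 numeric rating scale
#'
#' Partitions intensities 1-10 into mild, moderate and severe; 0 means no
#' pain. The defaults are the conventional NRS tertiles: mild 1-3, moderate
#' 4-7, severe 8-10, so "moderate or severe" means an intensity of at least
#' `mild_max + 1` and "mild or moderate" at most `moderate_max`.
#'
#' @param mild_max Upper bound of the mild band (default 3).
#' @param moderate_max Upper bound of the moderate band (default 7).
#' @return An object of class `intensity_bands`.
#' @export
intensity_bands <- function(mild_max = 3L, moderate_max = 7L) {
  mild_max <- as.integer(mild_max); moderate_max <- as.integer(moderate_max)
  if (!(mild_max >= 1L && mild_max < moderate_max && moderate_max <= 9L))
    stop("intensity bands must satisfy 1 <= mild_max < moderate_max <= 9")
  structure(list(mild = c(1L, mild_max),
                 moderate = c(mild_max + 1L, moderate_max),
                 severe = c(moderate_max + 1L, 10L)),
            class = "intensity_bands")
}

#' Classifier configuration
#'
#' All tunable parameters of the attack classifier.
#'
#' @param bands [intensity_bands()] used for "moderate or severe" (migraine
#'   feature A) and "mild or moderate" (TTH).
#' @param migraine_min_hours Minimum duration of a qualified migraine attack
#'   (hours, default 4; no upper bound is imposed).
#' @param tth_hours_range Admissible TTH duration window in hours (default
#'   0.5 to 168, i.e. 30 minutes to 7 days).
#' @param triptan_names Lower-case substrings identifying migraine-specific
#'   acute medication by drug name when no explicit flag is recorded.
#' @param attribution_window_hours An intake is attributed to an attack if it
#'   falls within `[start - attribution_window_hours, end]` (default 1).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(bands = intensity_bands(),
                              migraine_min_hours = 4,
                              tth_hours_range = c(0.5, 168),
                              triptan_names = c("sumatriptan", "zolmitriptan",
                                                "rizatriptan", "eletriptan",
                                                "almotriptan", "naratriptan",
                                                "frovatriptan"),
                              attribution_window_hours = 1) {
  stopifnot(inherits(bands, "intensity_bands"),
            migraine_min_hours > 0,
            length(tth_hours_range) == 2L,
            tth_hours_range[1L] < tth_hours_range[2L],
            attribution_window_hours >= 0)
  structure(list(bands = bands,
                 migraine_min_hours = migraine_min_hours,
                 tth_hours_range = as.numeric(tth_hours_range),
                 triptan_names = tolower(triptan_names),
                 attribution_window_hours = attribution_window_hours),
            class = "classifier_config")
}

#' Attack duration in hours
#'
#' @param attacks Attack table (or any data frame with `start`/`end`
#'   `POSIXct` columns).
#' @return Numeric vector of durations in hours, exact to the second.
#' @export
attack_duration_hours <- function(attacks) {
  as.numeric(difftime(attacks$end, attacks$start, units = "hours"))
}

#' Migraine pain-characteristic criterion (feature A)
#'
#' At least two of: unilateral location, pulsatile (throbbing) quality,
#' moderate or severe pain intensity, aggravation by physical activity.
#'
#' @param attacks Attack table.
#' @param bands [intensity_bands()].
#' @return Logical vector, one element per attack.
#' @export
meets_feature_a <- function(attacks, bands = intensity_bands()) {
  modsev <- attacks$max_intensity >= bands$moderate[1L]
  (attacks$unilateral + attacks$throbbing + modsev +
      attacks$worse_with_activity) >= 2L
}

#' Migraine associated-symptom criterion (feature B)
#'
#' Nausea and/or vomiting, or photophobia *and* phonophobia (conjunctive).
#'
#' @param attacks Attack table.
#' @return Logical vector, one element per attack.
#' @export
meets_feature_b <- function(attacks) {
  attacks$nausea | attacks$vomitus | (attacks$photophobia & attacks$phonophobia)
}

#' Qualified migraine attack
#'
#' A headache (with or without aura) lasting at least the configured minimum
#' (default 4 hours) that meets both feature A and feature B.
#'
#' @param attacks Attack table.
#' @param config [classifier_config()].
#' @return Logical vector.
#' @export
is_qualified_migraine <- function(attacks, config = classifier_config()) {
  attack_duration_hours(attacks) >= config$migraine_min_hours &
    meets_feature_a(attacks, config$bands) &
    meets_feature_b(attacks)
}

#' Migraine-specific medication lookup
#'
#' An explicit recorded flag wins; otherwise the drug name is matched
#' case-insensitively against the configured migraine-specific substrings
#' (triptans by default).
#'
#' @param drug_name Character vector of drug names.
#' @param explicit_flag Logical vector (`NA` = not recorded).
#' @param config [classifier_config()].
#' @return Logical vector.
#' @export
is_migraine_specific <- function(drug_name, explicit_flag = NA,
                                 config = classifier_config()) {
  explicit_flag <- rep_len(explicit_flag, length(drug_name))
  pat <- paste(config$triptan_names, collapse = "|")
  by_name <- grepl(pat, tolower(drug_name))
  ifelse(is.na(explicit_flag), by_name, explicit_flag)
}

# Per-attack flag: does any migraine-specific intake of the same user fall in
# [start - window, end]? data.table non-equi join over potentially large
# tables.
attacks_with_specific_intake <- function(attacks, medications,
                                         config = classifier_config()) {
  if (!nrow(attacks)) return(logical())
  if (!nrow(medications)) return(rep(FALSE, nrow(attacks)))
  med <- medications[is_migraine_specific(medications$drug_name,
                                          medications$migraine_specific,
                                          config), , drop = FALSE]
  if (!nrow(med)) return(rep(FALSE, nrow(attacks)))
  a <- data.table(row = seq_len(nrow(attacks)), user_id = attacks$user_id,
                  lo = as.numeric(attacks$start) - 3600 * config$attribution_window_hours,
                  hi = as.numeric(attacks$end))
  m <- data.table(user_id = med$user_id, lo = as.numeric(med$intake_time),
                  hi = as.numeric(med$intake_time))
  data.table::setkey(m, user_id, lo, hi)
  ov <- data.table::foverlaps(a, m, type = "any", nomatch = NULL, which = TRUE)
  out <- rep(FALSE, nrow(attacks))
  out[a$row[ov$xid]] <- TRUE
  out
}

#' Migraine override: aura or migraine-specific medication
#'
#' Attacks accompanied by aura, or by an attributable intake of a
#' migraine-specific medication (e.g. a triptan), are migraine regardless of
#' duration and pain features.
#'
#' @param attacks Attack table.
#' @param medications Medication table; only intakes within the attribution
#'   window of an attack count for that attack.
#' @param config [classifier_config()].
#' @return Logical vector.
#' @export
has_migraine_override <- function(attacks, medications = empty_medications(),
                                  config = classifier_config()) {
  attacks$aura | attacks_with_specific_intake(attacks, medications, config)
}

#' Tension-type headache criteria
#'
#' Duration within the TTH window (default 30 minutes to 7 days); at least
#' two of the four negated migraine pain features (bilateral, non-pulsatile,
#' intensity at most moderate, no aggravation by activity); no nausea and no
#' vomiting; at most one of photophobia and phonophobia.
#'
#' @param attacks Attack table.
#' @param config [classifier_config()].
#' @return Logical vector.
#' @export
meets_tth_criteria <- function(attacks, config = classifier_config()) {
  dur <- attack_duration_hours(attacks)
  mild_or_mod <- attacks$max_intensity <= config$bands$moderate[2L]
  neg2 <- (!attacks$unilateral) + (!attacks$throbbing) + mild_or_mod +
    (!attacks$worse_with_activity) >= 2L
  dur >= config$tth_hours_range[1L] & dur <= config$tth_hours_range[2L] &
    neg2 & !attacks$nausea & !attacks$vomitus &
    (attacks$photophobia + attacks$phonophobia) <= 1L
}

#' Probable migraine
#'
#' Exactly one of the three qualified-migraine conjuncts (duration at least 4
#' hours, feature A, feature B) fails.
#'
#' @param attacks Attack table.
#' @param config [classifier_config()].
#' @return Logical vector.
#' @export
meets_probable_migraine <- function(attacks, config = classifier_config()) {
  fails <- (attack_duration_hours(attacks) < config$migraine_min_hours) +
    (!meets_feature_a(attacks, config$bands)) +
    (!meets_feature_b(attacks))
  fails == 1L
}

#' Classify headache attacks as migraine, TTH or other
#'
#' Implements the attack-level decision rule:
#'
#' 1. Aura or an attributable migraine-specific intake, or a qualified
#'    migraine attack, is `MIGRAINE`.
#' 2. An attack meeting both TTH and probable-migraine criteria is `MIGRAINE`
#'    for users with a previous migraine diagnosis and `TTH` otherwise (the
#'    ICHD-3 "general rule of hierarchy").
#' 3. Otherwise TTH alone gives `TTH`; probable migraine alone gives
#'    `MIGRAINE` with a prior migraine diagnosis and `OTHER` without.
#' 4. Anything else is `OTHER`.
#'
#' @param collection A [diary_collection()] (attacks, medications and user
#'   prior diagnoses are taken from it), or an attack table if `medications`
#'   and `prior_diagnosis` are supplied explicitly.
#' @param config [classifier_config()].
#' @param medications,prior_diagnosis Only used when `collection` is a bare
#'   attack table: the medication table and a per-attack character vector
#'   (recycled) of prior diagnoses.
#' @return A data frame with one row per attack: `attack_id`, `label`
#'   (`"MIGRAINE"`, `"TTH"`, `"OTHER"`) and `rule_trace` (the `;`-separated
#'   names of the rules on the decision path).
#' @export
classify_attacks <- function(collection, config = classifier_config(),
                             medications = NULL, prior_diagnosis = NULL) {
  if (inherits(collection, "diary_collection")) {
    attacks <- collection$attacks
    medications <- collection$medications
    prior_diagnosis <- collection$users$prior_diagnosis[
      match(attacks$user_id, collection$users$user_id)]
  } else {
    attacks <- collection
    medications <- medications %||% empty_medications()
    prior_diagnosis <- rep_len(prior_diagnosis %||% "unknown", nrow(attacks))
  }
  n <- nrow(attacks)
  if (!n)
    return(data.frame(attack_id = character(), label = character(),
                      rule_trace = character()))

  med_override <- attacks_with_specific_intake(attacks, medications, config)
  aura <- attacks$aura
  qualified <- is_qualified_migraine(attacks, config)
  tth <- meets_tth_criteria(attacks, config)
  probable <- meets_probable_migraine(attacks, config)
  prior_mig <- prior_diagnosis == "migraine"

  label <- rep("OTHER", n)
  trace <- character(n)

  ov <- aura | med_override
  label[ov | qualified] <- "MIGRAINE"
  trace[ov | qualified] <- paste0(
    ifelse(aura[ov | qualified], "aura_override;", ""),
    ifelse(med_override[ov | qualified], "triptan_override;", ""),
    ifelse(qualified[ov | qualified], "qualified_migraine;", ""))

  rest <- !(ov | qualified)

  i <- rest & tth & probable
  label[i] <- ifelse(prior_mig[i], "MIGRAINE", "TTH")
  trace[i] <- ifelse(prior_mig[i],
                     "tth_and_probable;prior_migraine_counts_as_migraine;",
                     "tth_and_probable;hierarchy_tth;")

  i <- rest & tth & !probable
  label[i] <- "TTH"
  trace[i] <- "tth;"

  i <- rest & !tth & probable
  label[i] <- ifelse(prior_mig[i], "MIGRAINE", "OTHER")
  trace[i] <- ifelse(prior_mig[i],
                     "probable_migraine;prior_migraine_counts_as_migraine;",
                     "probable_migraine;no_prior_migraine_other;")

  i <- rest & !tth & !probable
  trace[i] <- "no_criteria_met;"

  data.frame(attack_id = attacks$attack_id, label = label,
             rule_trace = sub(";$", "", trace))
}
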