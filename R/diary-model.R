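#' Diary collection: users, attacks, medications, daily entries
#'
#' A `diary_collection` bundles the four tables of a headache e-diary export
#' and enforces the domain invariants on construction:
#'
#' * `users`: `user_id` (unique), `sex` (`"female"`, `"male"`, `"unknown"`),
#'   `age` (integer years, `NA` allowed), `prior_diagnosis` (`"migraine"`,
#'   `"other"`, `"none"`, `"unknown"`), `first_use_date` (`Date`).
#' * `attacks`: `attack_id` (unique), `user_id`, `start`/`end` (`POSIXct`,
#'   `end > start`, attacks of one user must not overlap), `max_intensity`
#'   (integer 0-10) and the eight boolean symptom flags `unilateral`,
#'   `throbbing`, `worse_with_activity`, `nausea`, `vomitus`, `photophobia`,
#'   `phonophobia`, `aura`.
#' * `medications`: `user_id`, `drug_name`, `dose` (free text), `intake_time`
#'   (`POSIXct`), `migraine_specific` (logical, `NA` = resolve by drug name).
#' * `entries`: `user_id`, `entry_date` (`Date`), `entry_kind` (`"headache"`
#'   or `"no_headache"`); at most one `no_headache` entry per user and day,
#'   and a `headache` entry date must be covered by some attack of that user.
#'
#' Every `user_id` referenced by the other three tables must exist in `users`,
#' and a user's `first_use_date` must not postdate their earliest attack.
#'
#' @param users,attacks,medications,entries Data frames as described above.
#'   Missing optional columns are not tolerated; zero-row tables are.
#' @param validate Run full validation (default). Skipping is only safe for
#'   data that has already been validated, e.g. inside the package itself.
#' @return An object of class `diary_collection`, a list with the four tables.
#' @seealso [read_diary()], [write_diary()], [validate_diary()]
#' @export
diary_collection <- function(users, attacks = empty_attacks(),
                             medications = empty_medications(),
                             entries = empty_entries(),
                             validate = TRUE) {
  x <- structure(
    list(users = as.data.frame(users),
         attacks = as.data.frame(attacks),
         medications = as.data.frame(medications),
         entries = as.data.frame(entries)),
    class = "diary_collection"
  )
  if (validate) validate_diary(x)
  x
}

attack_flag_cols <- function() {
  c("unilateral", "throbbing", "worse_with_activity", "nausea",
    "vomitus", "photophobia", "phonophobia", "aura")
}

#' Empty diary tables with the correct column types
#'
#' Useful as building blocks for tests and for users constructing collections
#' programmatically.
#' @return A zero-row data frame of the respective schema.
#' @export
empty_users <- function() {
  data.frame(user_id = character(), sex = character(), age = integer(),
             prior_diagnosis = character(),
             first_use_date = as.Date(character()))
}

#' @rdname empty_users
#' @export
empty_attacks <- function() {
  out <- data.frame(attack_id = character(), user_id = character(),
                    start = as.POSIXct(character(), tz = "UTC"),
                    end = as.POSIXct(character(), tz = "UTC"),
                    max_intensity = integer())
  for (f in attack_flag_cols()) out[[f]] <- logical()
  out
}

#' @rdname empty_users
#' @export
empty_medications <- function() {
  data.frame(user_id = character(), drug_name = character(),
             dose = character(),
             intake_time = as.POSIXct(character(), tz = "UTC"),
             migraine_specific = logical())
}

#' @rdname empty_users
#' @export
empty_entries <- function() {
  data.frame(user_id = character(), entry_date = as.Date(character()),
             entry_kind = character())
}

require_cols <- function(df, cols, where) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    diary_error(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                where = where)
}

#' Validate a diary collection
#'
#' Checks every structural invariant of the diary model and raises a
#' `diary_validation_error` naming the violated rule and the offending row.
#' Validation is total: a collection either passes all rules or an error
#' identifies the first violation.
#'
#' @param x A [diary_collection()].
#' @return `x`, invisibly, if valid.
#' @export
validate_diary <- function(x) {
  stopifnot(inherits(x, "diary_collection"))
  u <- x$users; a <- x$attacks; m <- x$medications; e <- x$entries

  require_cols(u, c("user_id", "sex", "age", "prior_diagnosis", "first_use_date"), "users")
  require_cols(a, c("attack_id", "user_id", "start", "end", "max_intensity",
                    attack_flag_cols()), "attacks")
  require_cols(m, c("user_id", "drug_name", "dose", "intake_time", "migraine_specific"), "medications")
  require_cols(e, c("user_id", "entry_date", "entry_kind"), "entries")

  if (anyDuplicated(u$user_id))
    diary_error("duplicate user_id",
                where = paste0("users row ", which(duplicated(u$user_id))[1L]))
  bad <- !(u$sex %in% c("female", "male", "unknown"))
  if (any(bad))
    diary_error("sex must be female/male/unknown",
                where = paste0("users row ", which(bad)[1L]))
  bad <- !is.na(u$age) & (u$age < 0 | u$age != floor(u$age))
  if (any(bad))
    diary_error("age must be a nonnegative integer or missing",
                where = paste0("users row ", which(bad)[1L]))
  bad <- !(u$prior_diagnosis %in% c("migraine", "other", "none", "unknown"))
  if (any(bad))
    diary_error("prior_diagnosis must be migraine/other/none/unknown",
                where = paste0("users row ", which(bad)[1L]))
  if (anyNA(u$first_use_date))
    diary_error("first_use_date required",
                where = paste0("users row ", which(is.na(u$first_use_date))[1L]))

  if (nrow(a)) {
    if (anyDuplicated(a$attack_id))
      diary_error("duplicate attack_id",
                  where = paste0("attacks row ", which(duplicated(a$attack_id))[1L]))
    if (anyNA(a$start) || anyNA(a$end))
      diary_error("malformed timestamp",
                  where = paste0("attacks row ", which(is.na(a$start) | is.na(a$end))[1L]))
    bad <- a$end <= a$start
    if (any(bad))
      diary_error("end > start violated", where = paste0("attacks row ", which(bad)[1L]))
    bad <- is.na(a$max_intensity) | a$max_intensity < 0 | a$max_intensity > 10 |
      a$max_intensity != floor(a$max_intensity)
    if (any(bad))
      diary_error("max_intensity must be an integer in 0-10",
                  where = paste0("attacks row ", which(bad)[1L]))
    for (f in attack_flag_cols()) {
      if (anyNA(a[[f]]))
        diary_error(paste0("missing value in required boolean '", f, "'"),
                    where = paste0("attacks row ", which(is.na(a[[f]]))[1L]))
    }
    bad <- !(a$user_id %in% u$user_id)
    if (any(bad))
      diary_error("unknown user_id reference",
                  where = paste0("attacks row ", which(bad)[1L]),
                  detail = a$user_id[which(bad)[1L]])

    # per-user interval overlap: after sorting by start, an attack may not
    # begin before the previous one ends
    o <- order(a$user_id, a$start)
    same <- a$user_id[o][-1L] == a$user_id[o][-length(o)]
    olap <- same & (as.numeric(a$start[o][-1L]) < as.numeric(a$end[o][-length(o)]))
    if (any(olap))
      diary_error("overlapping attacks for a user",
                  where = paste0("attacks row ", o[-1L][which(olap)[1L]]))

    # first_use_date must not postdate a user's earliest attack
    first_attack <- tapply(as.Date(a$start, tz = "UTC"), a$user_id, min)
    fu <- u$first_use_date[match(names(first_attack), u$user_id)]
    bad <- fu > as.Date(first_attack, origin = "1970-01-01")
    if (any(bad))
      diary_error("first_use_date after earliest attack",
                  detail = names(first_attack)[which(bad)[1L]])
  }

  if (nrow(m)) {
    if (anyNA(m$intake_time))
      diary_error("malformed timestamp",
                  where = paste0("medications row ", which(is.na(m$intake_time))[1L]))
    bad <- !(m$user_id %in% u$user_id)
    if (any(bad))
      diary_error("unknown user_id reference",
                  where = paste0("medications row ", which(bad)[1L]))
  }

  if (nrow(e)) {
    bad <- !(e$entry_kind %in% c("headache", "no_headache"))
    if (any(bad))
      diary_error("entry_kind must be headache/no_headache",
                  where = paste0("entries row ", which(bad)[1L]))
    bad <- !(e$user_id %in% u$user_id)
    if (any(bad))
      diary_error("unknown user_id reference",
                  where = paste0("entries row ", which(bad)[1L]))
    nh <- e[e$entry_kind == "no_headache", , drop = FALSE]
    key <- paste(nh$user_id, nh$entry_date)
    if (anyDuplicated(key))
      diary_error("at most one no_headache entry per user and day",
                  where = paste0("entries row ",
                                 which(e$entry_kind == "no_headache")[which(duplicated(key))[1L]]))
    hh <- e[e$entry_kind == "headache", , drop = FALSE]
    if (nrow(hh)) {
      covered <- attack_day_table(x$attacks)
      key_h <- paste(hh$user_id, hh$entry_date)
      key_c <- paste(covered$user_id, covered$date)
      bad <- !(key_h %in% key_c)
      if (any(bad))
        diary_error("headache entry not covered by any attack",
                    where = paste0("entries row ",
                                   which(e$entry_kind == "headache")[which(bad)[1L]]))
    }
  }
  invisible(x)
}

#' @export
print.diary_collection <- function(x, ...) {
  cat("<diary_collection>\n")
  cat("  users:      ", nrow(x$users), "\n")
  cat("  attacks:    ", nrow(x$attacks), "\n")
  cat("  medications:", nrow(x$medications), "\n")
  cat("  entries:    ", nrow(x$entries), "\n")
  invisible(x)
}

#' Read a diary collection from four CSV files
#'
#' Files are UTF-8, comma-separated with a header row. Timestamps are ISO 8601
#' wall-clock (`YYYY-MM-DD HH:MM[:SS]`, a `T` separator is accepted), booleans
#' are `"true"`/`"false"`, and missing values are empty cells. Missing
#' `sex`/`prior_diagnosis` map to `"unknown"` and missing `age` to `NA`; the
#' attack symptom flags and all timestamps are required. The returned
#' collection has passed [validate_diary()].
#'
#' @param users_path,attacks_path,medications_path,entries_path CSV paths.
#'   `entries_path` may be `NULL` for collections without daily entries.
#' @return A validated [diary_collection()].
#' @export
read_diary <- function(users_path, attacks_path, medications_path = NULL,
                       entries_path = NULL) {
  read1 <- function(p) {
    read.csv(p, colClasses = "character", na.strings = NULL,
             check.names = TRUE, fileEncoding = "UTF-8")
  }

  u <- read1(users_path)
  require_cols(u, c("user_id", "sex", "age", "prior_diagnosis", "first_use_date"), "users.csv")
  age <- suppressWarnings(as.integer(u$age))
  bad <- trimws(u$age) != "" & is.na(age)
  if (any(bad))
    diary_error("age must be a nonnegative integer or missing",
                where = paste0("users.csv row ", which(bad)[1L]), detail = u$age[which(bad)[1L]])
  users <- data.frame(
    user_id = u$user_id,
    sex = ifelse(trimws(u$sex) == "", "unknown", trimws(u$sex)),
    age = age,
    prior_diagnosis = ifelse(trimws(u$prior_diagnosis) == "", "unknown",
                             trimws(u$prior_diagnosis)),
    first_use_date = parse_date(u$first_use_date, where = "users.csv")
  )

  a <- read1(attacks_path)
  require_cols(a, c("attack_id", "user_id", "start", "end", "max_intensity",
                    attack_flag_cols()), "attacks.csv")
  mi <- suppressWarnings(as.integer(a$max_intensity))
  bad <- is.na(mi) | mi < 0 | mi > 10
  if (any(bad))
    diary_error("max_intensity must be an integer in 0-10",
                where = paste0("attacks.csv row ", which(bad)[1L]),
                detail = a$max_intensity[which(bad)[1L]])
  attacks <- data.frame(
    attack_id = a$attack_id, user_id = a$user_id,
    start = parse_timestamp(a$start, where = "attacks.csv"),
    end = parse_timestamp(a$end, where = "attacks.csv"),
    max_intensity = mi
  )
  for (f in attack_flag_cols())
    attacks[[f]] <- parse_boolean(a[[f]], allow_missing = FALSE, field = f,
                                  where = "attacks.csv")

  if (!is.null(medications_path)) {
    m <- read1(medications_path)
    require_cols(m, c("user_id", "drug_name", "dose", "intake_time",
                      "migraine_specific"), "medications.csv")
    medications <- data.frame(
      user_id = m$user_id, drug_name = m$drug_name, dose = m$dose,
      intake_time = parse_timestamp(m$intake_time, where = "medications.csv"),
      migraine_specific = parse_boolean(m$migraine_specific, allow_missing = TRUE,
                                        field = "migraine_specific",
                                        where = "medications.csv")
    )
  } else medications <- empty_medications()

  if (!is.null(entries_path)) {
    e <- read1(entries_path)
    require_cols(e, c("user_id", "entry_date", "entry_kind"), "entries.csv")
    entries <- data.frame(
      user_id = e$user_id,
      entry_date = parse_date(e$entry_date, where = "entries.csv"),
      entry_kind = e$entry_kind
    )
  } else entries <- empty_entries()

  diary_collection(users, attacks, medications, entries)
}

#' Write a diary collection to four CSV files
#'
#' Inverse of [read_diary()]: `read_diary()` applied to the written files
#' reproduces every field and every missing value of the collection.
#'
#' @param collection A [diary_collection()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths of the four written files.
#' @export
write_diary <- function(collection, dir) {
  stopifnot(inherits(collection, "diary_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("users.csv", "attacks.csv", "medications.csv", "entries.csv"))

  u <- collection$users
  write.csv(data.frame(user_id = u$user_id, sex = u$sex,
                       age = ifelse(is.na(u$age), "", u$age),
                       prior_diagnosis = u$prior_diagnosis,
                       first_use_date = format(u$first_use_date, "%Y-%m-%d")),
            paths[1L], row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")

  a <- collection$attacks
  out <- data.frame(attack_id = a$attack_id, user_id = a$user_id,
                    start = format_timestamp(a$start),
                    end = format_timestamp(a$end),
                    max_intensity = a$max_intensity)
  for (f in attack_flag_cols()) out[[f]] <- format_boolean(a[[f]])
  write.csv(out, paths[2L], row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")

  m <- collection$medications
  write.csv(data.frame(user_id = m$user_id, drug_name = m$drug_name, dose = m$dose,
                       intake_time = format_timestamp(m$intake_time),
                       migraine_specific = format_boolean(m$migraine_specific)),
            paths[3L], row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")

  e <- collection$entries
  write.csv(data.frame(user_id = e$user_id,
                       entry_date = format(e$entry_date, "%Y-%m-%d"),
                       entry_kind = e$entry_kind),
            paths[4L], row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")

  invisible(paths)
}
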