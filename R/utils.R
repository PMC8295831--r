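#' @importFrom data.table := .N .SD data.table as.data.table setDT setkey rbindlist fifelse
#' @importFrom stats pt qt rbinom rlnorm rnorm runif sd var aggregate
#' @importFrom utils read.csv write.csv write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signal a diary validation failure. `rule` is the short name of the violated
# rule; `where` locates the offending row ("attacks.csv row 12").
diary_error <- function(rule, where = NULL, detail = NULL) {
  msg <- paste0(
    "diary validation failed",
    if (!is.null(where)) paste0(" [", where, "]"),
    ": ", rule,
    if (!is.null(detail)) paste0(" (", detail, ")")
  )
  stop(errorCondition(msg, rule = rule, class = c("diary_validation_error", "error")))
}

# ISO 8601 wall-clock timestamps; no timezone arithmetic (stored as UTC so
# arithmetic is pure calendar/clock arithmetic, immune to DST).
parse_timestamp <- function(x, where = NULL) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}(:\\d{2})?$", x)
  out <- rep(as.POSIXct(NA), length(x))
  x[!bad & nchar(x) == 16L] <- paste0(x[!bad & nchar(x) == 16L], ":00")
  out[!bad] <- as.POSIXct(x[!bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  bad <- bad | (is.na(out) & !is.na(x) & x != "")
  if (any(bad)) {
    i <- which(bad)[1L]
    diary_error("malformed timestamp",
                where = if (is.null(where)) NULL else paste0(where, " row ", i),
                detail = x[i])
  }
  out
}

parse_date <- function(x, where = NULL) {
  x <- trimws(as.character(x))
  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[!bad] <- as.Date(x[!bad], format = "%Y-%m-%d")
  bad <- bad | is.na(out)
  if (any(bad)) {
    i <- which(bad)[1L]
    diary_error("malformed date",
                where = if (is.null(where)) NULL else paste0(where, " row ", i),
                detail = x[i])
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

parse_boolean <- function(x, allow_missing = FALSE, field = "", where = NULL) {
  if (is.logical(x)) return(x)
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  miss <- is.na(x) | x0 == "" | x0 == "na"
  bad <- is.na(out) & !miss
  if (any(bad)) {
    i <- which(bad)[1L]
    diary_error(paste0("malformed boolean in '", field, "'"),
                where = if (is.null(where)) NULL else paste0(where, " row ", i),
                detail = as.character(x)[i])
  }
  if (!allow_missing && any(miss)) {
    i <- which(miss)[1L]
    diary_error(paste0("missing value in required boolean '", field, "'"),
                where = if (is.null(where)) NULL else paste0(where, " row ", i))
  }
  out
}

format_boolean <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
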