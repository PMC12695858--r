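#' Parse partial dates as reported to spontaneous reporting systems
#'
#' SRS date fields come at three precisions: year only (`"2023"`), year and
#' month (`"202304"` or `"2023-04"`), or a full calendar date (`"20230410"`
#' or `"2023-04-10"`). The parser records the precision so downstream
#' time-to-onset rules can impute or exclude accordingly.
#'
#' @param x character vector of raw date strings; `NA`, `""` and `"unknown"`
#'   markers yield a missing row.
#' @return data.frame with columns `year`, `month`, `day` (integer, `NA`
#'   where absent) and `precision` (`"year"`, `"year_month"`, `"full"`, or
#'   `NA` for unparseable/missing input).
#' @examples
#' parse_partial_date(c("20230410", "202304", "2023", "2023-06-15", ""))
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x <- gsub("[-/.]", "", trimws(x))
  n <- length(x)
  out <- data.frame(year = rep(NA_integer_, n), month = NA_integer_,
                    day = NA_integer_, precision = NA_character_,
                    stringsAsFactors = FALSE)
  bad <- is.na(x) | x == "" | !grepl("^[0-9]+$", x)
  digits <- nchar(x)
  full <- !bad & digits == 8L
  ym   <- !bad & digits == 6L
  yo   <- !bad & digits == 4L
  out$year[yo | ym | full] <- as.integer(substr(x[yo | ym | full], 1, 4))
  out$month[ym | full] <- as.integer(substr(x[ym | full], 5, 6))
  out$day[full] <- as.integer(substr(x[full], 7, 8))
  out$precision[yo] <- "year"
  out$precision[ym] <- "year_month"
  out$precision[full] <- "full"
  # invalidate impossible calendar values
  badm <- !is.na(out$month) & (out$month < 1L | out$month > 12L)
  out[badm, c("year", "month", "day", "precision")] <- NA
  chk <- which(!is.na(out$day))
  if (length(chk)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", out$year[chk], out$month[chk],
                         out$day[chk]), format = "%Y-%m-%d")
    badd <- chk[is.na(d)]
    out[badd, c("year", "month", "day", "precision")] <- NA
  }
  out
}

# Proleptic day number after imputation: year-month dates take day 15,
# year-only dates are not resolvable (NA). Vectorised.
partial_date_to_day <- function(pd) {
  n <- nrow(pd)
  day <- ifelse(pd$precision == "year_month", 15L, pd$day)
  res <- rep(NA_real_, n)
  ok <- !is.na(pd$precision) & pd$precision %in% c("year_month", "full")
  if (any(ok)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", pd$year[ok], pd$month[ok],
                         day[ok]), format = "%Y-%m-%d")
    res[ok] <- as.numeric(d)
  }
  res
}

#' Time from drug start to event onset under SRS date-handling rules
#'
#' Applies the four rules used for time-to-onset analysis of spontaneous
#' reports: (1) a start or onset date known only to the year excludes the
#' record; (2) year-month dates are resolved to day 15; (3) an onset date
#' before the start date excludes the record; (4) onset on the same
#' calendar day as the start counts as half a day.
#'
#' @param start,onset character vectors of raw date strings (see
#'   [parse_partial_date()]).
#' @return data.frame with `time_to_onset_days` (NA where excluded) and
#'   `rule` describing the outcome: `"ok"`, `"same_day"` (rule 4),
#'   `"excluded_year_only"` (rule 1), `"excluded_onset_before_start"`
#'   (rule 3), or `"excluded_missing_date"`.
#' @examples
#' onset_interval_days("20230410", "20230410")  # same day -> 0.5
#' onset_interval_days("202304", "202306")      # both to day 15 -> 61
#' onset_interval_days("20230501", "20230401")  # onset precedes start
#' @export
onset_interval_days <- function(start, onset) {
  ps <- parse_partial_date(start)
  po <- parse_partial_date(onset)
  n <- nrow(ps)
  rule <- rep("ok", n)
  tto <- rep(NA_real_, n)

  missing_any <- is.na(ps$precision) | is.na(po$precision)
  year_only <- !missing_any & (ps$precision == "year" | po$precision == "year")
  rule[missing_any] <- "excluded_missing_date"
  rule[year_only] <- "excluded_year_only"

  usable <- !missing_any & !year_only
  ds <- partial_date_to_day(ps)
  do <- partial_date_to_day(po)
  diff <- do - ds
  before <- usable & diff < 0
  same <- usable & diff == 0
  after <- usable & diff > 0
  rule[before] <- "excluded_onset_before_start"
  rule[same] <- "same_day"
  tto[same] <- 0.5
  tto[after] <- diff[after]
  data.frame(time_to_onset_days = tto, rule = rule, stringsAsFactors = FALSE)
}
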