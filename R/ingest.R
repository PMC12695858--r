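# Reading, normalising and cleaning SRS tables into a common case-level
# model. The object flowing through this module is a list of class
# `srs_data` holding three data.frames keyed by (case_id, version):
#   demo   one row per case submission
#   drugs  one row per reported drug on a submission
#   events one row per reported adverse event on a submission
# Case versioning exists only in FAERS; JADER rows carry version 0.

# Delimited reader that rejects lines whose field count disagrees with the
# header (a real failure mode of the quarterly ASCII files). Returns the
# well-formed rows as character data plus the rejected-line count.
read_delimited_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty table file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad to header width
  nf <- lengths(parts)
  header <- parts[[1]]
  width <- length(header)
  body <- parts[-1]
  ok <- lengths(body) == width |
    (lengths(body) == width - 1L & endsWith(lines[-1], sep))
  body[ok & lengths(body) == width - 1L] <-
    lapply(body[ok & lengths(body) == width - 1L], function(p) c(p, ""))
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("%s: rejected %d malformed line(s)", basename(path),
                    n_bad), call. = FALSE)
  body <- body[ok]
  df <- as.data.frame(do.call(rbind, c(body, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (!length(body)) {
    df <- as.data.frame(matrix(character(0), ncol = width),
                        stringsAsFactors = FALSE)
  }
  names(df) <- header
  attr(df, "rejected_lines") <- n_bad
  df
}

pick_columns <- function(df, colmap, table_name) {
  missing <- setdiff(unname(colmap), names(df))
  if (length(missing))
    stop(sprintf("table %s is missing required column(s): %s", table_name,
                 paste(missing, collapse = ", ")))
  out <- df[, unname(colmap), drop = FALSE]
  names(out) <- names(colmap)
  out
}

blank_to_na <- function(x, markers) {
  x <- trimws(as.character(x))
  x[x %in% markers] <- NA_character_
  x
}

#' Read FAERS-dialect quarterly tables into the common case model
#'
#' Joins the DEMO, DRUG and REAC tables on (case id, case version); the
#' THER table supplies therapy start dates, joined to DRUG on the drug
#' sequence number. Drug names are normalized with
#' [normalize_drug_name()], role codes mapped to the common enum and ages
#' converted to years via the dialect's unit table.
#'
#' @param demo_path,drug_path,reac_path,ther_path paths to the four
#'   dollar-delimited tables.
#' @param dialect dialect configuration, see [faers_dialect()].
#' @return an `srs_data` list with elements `demo`, `drugs`, `events`,
#'   `source`, `accepted_roles` and `rejected_lines`.
#' @export
read_faers_tables <- function(demo_path, drug_path, reac_path,
                              ther_path = NULL, dialect = faers_dialect()) {
  mk <- dialect$missing_markers
  demo_raw <- read_delimited_checked(demo_path, dialect$sep)
  drug_raw <- read_delimited_checked(drug_path, dialect$sep)
  reac_raw <- read_delimited_checked(reac_path, dialect$sep)
  rejected <- attr(demo_raw, "rejected_lines") +
    attr(drug_raw, "rejected_lines") + attr(reac_raw, "rejected_lines")

  demo <- pick_columns(demo_raw, dialect$demo, "DEMO")
  demo$case_id <- trimws(demo$case_id)
  demo$version <- suppressWarnings(as.integer(demo$version))
  demo$version[is.na(demo$version)] <- 0L
  age_val <- suppressWarnings(as.numeric(blank_to_na(demo$age, mk)))
  unit <- toupper(blank_to_na(demo$age_unit, mk))
  per_year <- unname(dialect$age_units[unit])
  demo$age_years <- age_val * per_year
  demo$sex <- unname(dialect$sex_map[blank_to_na(demo$sex, mk)])
  demo$occupation <- blank_to_na(demo$occupation, mk)
  demo$event_date <- blank_to_na(demo$event_date, mk)

  drugs <- pick_columns(drug_raw, dialect$drug, "DRUG")
  drugs$case_id <- trimws(drugs$case_id)
  drugs$version <- suppressWarnings(as.integer(drugs$version))
  drugs$version[is.na(drugs$version)] <- 0L
  drugs$drug_name <- normalize_drug_name(drugs$drug_name)
  drugs$role <- unname(dialect$role_map[trimws(drugs$role)])
  drugs$start_date <- NA_character_

  if (!is.null(ther_path)) {
    ther_raw <- read_delimited_checked(ther_path, dialect$sep)
    rejected <- rejected + attr(ther_raw, "rejected_lines")
    ther <- pick_columns(ther_raw, dialect$ther, "THER")
    ther$case_id <- trimws(ther$case_id)
    key_d <- paste(drugs$case_id, drugs$version, drugs$drug_seq, sep = "\r")
    key_t <- paste(trimws(ther$case_id),
                   suppressWarnings(as.integer(ther$version)),
                   ther$drug_seq, sep = "\r")
    idx <- match(key_d, key_t)
    drugs$start_date <- blank_to_na(ther$start_date[idx], mk)
  }

  events <- pick_columns(reac_raw, dialect$reac, "REAC")
  events$case_id <- trimws(events$case_id)
  events$version <- suppressWarnings(as.integer(events$version))
  events$version[is.na(events$version)] <- 0L
  events$pt_code <- suppressWarnings(as.integer(events$pt_code))
  events$pt_name <- blank_to_na(events$pt_name, mk)
  # FAERS carries the AE onset date on DEMO (event_dt); apply it per case
  key_e <- paste(events$case_id, events$version, sep = "\r")
  key_m <- paste(demo$case_id, demo$version, sep = "\r")
  events$onset_date <- demo$event_date[match(key_e, key_m)]

  structure(list(
    demo = demo[, c("case_id", "version", "age_years", "sex", "occupation")],
    drugs = drugs[, c("case_id", "version", "drug_name", "role",
                      "start_date")],
    events = events[, c("case_id", "version", "pt_code", "pt_name",
                        "onset_date")],
    source = "FAERS", accepted_roles = dialect$accepted_roles,
    rejected_lines = rejected
  ), class = "srs_data")
}

#' Read JADER-dialect CSV tables into the common case model
#'
#' Links the DEMO table to DRUG and REAC on the report identification
#' number. Decade-bucket ages are mapped to midpoint years, Japanese sex
#' and role labels to the common enums, "unknown" markers to missing, and
#' full-width/half-width variants of drug names to a single normalized
#' key. Rows that are exact duplicates after normalization are collapsed
#' (JADER has no case versioning).
#'
#' @param demo_path,drug_path,reac_path,hist_path paths to the CSV tables
#'   (`hist_path` optional, content passed through unused).
#' @param dialect dialect configuration, see [jader_dialect()].
#' @return an `srs_data` list, version fixed at 0.
#' @export
read_jader_tables <- function(demo_path, drug_path, reac_path,
                              hist_path = NULL, dialect = jader_dialect()) {
  mk <- dialect$missing_markers
  demo_raw <- read_delimited_checked(demo_path, dialect$sep)
  drug_raw <- read_delimited_checked(drug_path, dialect$sep)
  reac_raw <- read_delimited_checked(reac_path, dialect$sep)
  rejected <- attr(demo_raw, "rejected_lines") +
    attr(drug_raw, "rejected_lines") + attr(reac_raw, "rejected_lines")

  demo <- pick_columns(demo_raw, dialect$demo, "DEMO")
  demo$case_id <- trimws(demo$case_id)
  demo$version <- 0L
  age_txt <- zenkaku_to_hankaku(blank_to_na(demo$age, mk))
  demo$age_years <- unname(dialect$age_decades[age_txt])
  demo$sex <- unname(dialect$sex_map[blank_to_na(demo$sex, mk)])
  demo$occupation <- blank_to_na(demo$occupation, mk)
  demo <- demo[!duplicated(demo), ]

  drugs <- pick_columns(drug_raw, dialect$drug, "DRUG")
  drugs$case_id <- trimws(drugs$case_id)
  drugs$version <- 0L
  drugs$drug_name <- normalize_drug_name(drugs$drug_name)
  drugs$role <- unname(dialect$role_map[trimws(drugs$role)])
  drugs$start_date <- zenkaku_to_hankaku(blank_to_na(drugs$start_date, mk))
  drugs <- drugs[!duplicated(drugs), ]

  events <- pick_columns(reac_raw, dialect$reac, "REAC")
  events$case_id <- trimws(events$case_id)
  events$version <- 0L
  events$pt_code <- suppressWarnings(
    as.integer(zenkaku_to_hankaku(blank_to_na(events$pt_code, mk))))
  events$pt_name <- blank_to_na(events$pt_name, mk)
  events$onset_date <- zenkaku_to_hankaku(blank_to_na(events$onset_date, mk))
  events <- events[!duplicated(events), ]

  structure(list(
    demo = demo[, c("case_id", "version", "age_years", "sex", "occupation")],
    drugs = drugs[, c("case_id", "version", "drug_name", "role",
                      "start_date")],
    events = events[, c("case_id", "version", "pt_code", "pt_name",
                        "onset_date")],
    source = "JADER", accepted_roles = dialect$accepted_roles,
    rejected_lines = rejected
  ), class = "srs_data")
}

#' Keep only the latest version of each case
#'
#' FAERS assigns a new version number to each follow-up submission of a
#' case; only the latest version is analysed so that follow-ups do not
#' count as new reports. Ties on (case id, version) keep the last-read
#' row. Drug and event rows belonging to superseded versions are dropped
#' with their case submission. Idempotent.
#'
#' @param x an `srs_data` object.
#' @return the `srs_data` object with one demo row per case id.
#' @export
dedup_latest_version <- function(x) {
  stopifnot(inherits(x, "srs_data"))
  demo <- x$demo
  if (nrow(demo)) {
    ord <- order(demo$case_id, demo$version, seq_len(nrow(demo)))
    demo <- demo[ord, ]
    keep <- !duplicated(demo$case_id, fromLast = TRUE)
    demo <- demo[keep, ]
    key <- paste(demo$case_id, demo$version, sep = "\r")
    x$drugs <- x$drugs[paste(x$drugs$case_id, x$drugs$version,
                             sep = "\r") %in% key, ]
    x$events <- x$events[paste(x$events$case_id, x$events$version,
                               sep = "\r") %in% key, ]
    rownames(demo) <- rownames(x$drugs) <- rownames(x$events) <- NULL
  }
  x$demo <- demo
  x
}

#' Exclude reports with blank or anomalous age or sex
#'
#' Reports lacking a usable age in years or a known sex are removed, the
#' standard cleaning step before disproportionality analysis. Each
#' exclusion is tallied by reason so an attrition flowchart can be
#' reported; survivors + exclusions always equals the input count.
#'
#' @param x a deduplicated `srs_data` object.
#' @param age_range allowed age interval in years; values outside it are
#'   "anomalous".
#' @return an object of class `srs_reports`: the cleaned `srs_data` plus
#'   an `exclusions` named count vector.
#' @export
apply_exclusions <- function(x, age_range = c(0, 120)) {
  stopifnot(inherits(x, "srs_data"))
  demo <- x$demo
  missing_age <- is.na(demo$age_years)
  anomalous_age <- !missing_age &
    (demo$age_years < age_range[1] | demo$age_years > age_range[2])
  missing_sex <- !missing_age & !anomalous_age &
    (is.na(demo$sex) | !demo$sex %in% c("male", "female"))
  drop <- missing_age | anomalous_age | missing_sex
  exclusions <- c(missing_age = sum(missing_age),
                  anomalous_age = sum(anomalous_age),
                  missing_sex = sum(missing_sex))
  demo <- demo[!drop, ]
  key <- paste(demo$case_id, demo$version, sep = "\r")
  drugs <- x$drugs[paste(x$drugs$case_id, x$drugs$version,
                         sep = "\r") %in% key, ]
  events <- x$events[paste(x$events$case_id, x$events$version,
                           sep = "\r") %in% key, ]
  rownames(demo) <- rownames(drugs) <- rownames(events) <- NULL
  structure(list(demo = demo, drugs = drugs, events = events,
                 source = x$source, accepted_roles = x$accepted_roles,
                 exclusions = exclusions),
            class = "srs_reports")
}

#' Label reports as cases of the target adverse event
#'
#' A report is a case when any of its events carries a preferred-term
#' code in the target set. No report is dropped here; the flag feeds the
#' 2x2 tables downstream.
#'
#' @param x an `srs_reports` object.
#' @param target_pt_codes non-empty integer vector of MedDRA PT codes.
#' @return the `srs_reports` object with logical column `is_case` on
#'   `demo`.
#' @export
label_cases <- function(x, target_pt_codes = taste_disorder_pts()) {
  stopifnot(inherits(x, "srs_reports"))
  if (!length(target_pt_codes)) stop("target PT code set must be non-empty")
  hit <- x$events$case_id[x$events$pt_code %in% as.integer(target_pt_codes)]
  x$demo$is_case <- x$demo$case_id %in% hit
  x
}

# Drug rows of x restricted to roles accepted for analysis (primary
# suspect in FAERS, suspected drug in JADER).
accepted_drugs <- function(x) {
  d <- x$drugs
  d[!is.na(d$role) & d$role %in% x$accepted_roles, , drop = FALSE]
}

#' Time-to-onset records for one drug
#'
#' For each case report exposed to `drug_name` (accepted role) and
#' labelled a case of the target event, computes days from the drug's
#' start date to the onset of the first-listed target event, under the
#' partial-date rules of [onset_interval_days()]. Exclusions are tallied
#' by rule.
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param drug_name drug name (normalized internally).
#' @param target_pt_codes PT codes defining the event.
#' @return data.frame of `case_id`, `drug_name`, `time_to_onset_days`
#'   with attribute `onset_exclusions`, a named tally of rule outcomes.
#' @export
compute_onset <- function(x, drug_name,
                          target_pt_codes = taste_disorder_pts()) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(x$demo$is_case))
    stop("run label_cases() before compute_onset()")
  drug_name <- normalize_drug_name(drug_name)
  d <- accepted_drugs(x)
  d <- d[d$drug_name == drug_name, , drop = FALSE]
  d <- d[!duplicated(d$case_id), , drop = FALSE]   # first-listed entry
  e <- x$events[x$events$pt_code %in% as.integer(target_pt_codes), ,
                drop = FALSE]
  e <- e[!duplicated(e$case_id), , drop = FALSE]
  cases <- x$demo$case_id[x$demo$is_case]
  ids <- intersect(intersect(d$case_id, e$case_id), cases)
  if (!length(ids)) {
    out <- data.frame(case_id = character(0), drug_name = character(0),
                      time_to_onset_days = numeric(0))
    attr(out, "onset_exclusions") <- integer(0)
    return(out)
  }
  start <- d$start_date[match(ids, d$case_id)]
  onset <- e$onset_date[match(ids, e$case_id)]
  iv <- onset_interval_days(start, onset)
  keep <- !is.na(iv$time_to_onset_days)
  out <- data.frame(case_id = ids[keep], drug_name = drug_name,
                    time_to_onset_days = iv$time_to_onset_days[keep],
                    stringsAsFactors = FALSE)
  attr(out, "onset_exclusions") <-
    table(factor(iv$rule[!keep],
                 levels = c("excluded_missing_date", "excluded_year_only",
                            "excluded_onset_before_start")))
  out
}

#' @export
print.srs_data <- function(x, ...) {
  cat(sprintf("<srs_data: %s> %d case rows, %d drug rows, %d event rows\n",
              x$source, nrow(x$demo), nrow(x$drugs), nrow(x$events)))
  invisible(x)
}

#' @export
print.srs_reports <- function(x, ...) {
  cat(sprintf("<srs_reports: %s> %d cleaned reports", x$source,
              nrow(x$demo)))
  if (!is.null(x$demo$is_case))
    cat(sprintf(" (%d target-event cases)", sum(x$demo$is_case)))
  cat("\n excluded:", paste(names(x$exclusions), x$exclusions,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
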