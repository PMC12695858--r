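# In-memory constructors mirroring the reader output, so unit tests can
# exercise the cleaning stages without touching files.

mk_srs_data <- function(demo, drugs = NULL, events = NULL,
                        source = "FAERS",
                        accepted_roles = "primary_suspect") {
  blank_drugs <- data.frame(case_id = character(0), version = integer(0),
                            drug_name = character(0), role = character(0),
                            start_date = character(0),
                            stringsAsFactors = FALSE)
  blank_events <- data.frame(case_id = character(0), version = integer(0),
                             pt_code = integer(0), pt_name = character(0),
                             onset_date = character(0),
                             stringsAsFactors = FALSE)
  structure(list(demo = demo, drugs = drugs %||% blank_drugs,
                 events = events %||% blank_events, source = source,
                 accepted_roles = accepted_roles, rejected_lines = 0L),
            class = "srs_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_demo <- function(case_id, version = 1L, age_years = 50,
                    sex = "female", occupation = "CN") {
  n <- length(case_id)
  data.frame(case_id = as.character(case_id),
             version = rep(version, length.out = n),
             age_years = rep(age_years, length.out = n),
             sex = rep(sex, length.out = n),
             occupation = rep(occupation, length.out = n),
             stringsAsFactors = FALSE)
}

mk_drugs <- function(case_id, drug_name, role = "primary_suspect",
                     version = 1L, start_date = NA_character_) {
  data.frame(case_id = as.character(case_id), version = version,
             drug_name = drug_name, role = role, start_date = start_date,
             stringsAsFactors = FALSE)
}

mk_events <- function(case_id, pt_code, pt_name = "x", version = 1L,
                      onset_date = NA_character_) {
  data.frame(case_id = as.character(case_id), version = version,
             pt_code = as.integer(pt_code), pt_name = pt_name,
             onset_date = onset_date, stringsAsFactors = FALSE)
}

# Cleaned-and-labelled reports straight from a scenario, via the FAERS
# dialect round trip.
reports_from_scenario <- function(scenario, dialect = "faers") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  out <- simulate_reports(scenario, dir)
  raw <- if (dialect == "faers") {
    read_faers_tables(out$faers_paths[1], out$faers_paths[2],
                      out$faers_paths[3], out$faers_paths[4])
  } else {
    read_jader_tables(out$jader_paths[1], out$jader_paths[2],
                      out$jader_paths[3], out$jader_paths[4])
  }
  label_cases(apply_exclusions(dedup_latest_version(raw)))
}

# dollar-delimited writer for hand-built FAERS table fixtures
write_faers_file <- function(df, path) {
  utils::write.table(df, path, sep = "$", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}
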