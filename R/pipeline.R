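# End-to-end orchestration: raw dialect files in, publication-style
# tables out, with attrition bookkeeping at every step.

#' Demographic summary of target-event cases
#'
#' Tallies the labelled cases by adverse-event term, sex, age decade
#' and reporter occupation — the layout of a demographic
#' characteristics table. Age decades use half-open bins: under 20
#' (printed "<19"), then [20, 30) ... [80, 90), and 90 and over
#' (printed ">90"); each case counts once per panel, by its
#' first-listed target event.
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param target_pt_codes named PT code vector (names label the AE
#'   rows).
#' @return data.frame `panel`, `level`, `count`.
#' @export
demographics_table <- function(x,
                               target_pt_codes = taste_disorder_pts()) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(x$demo$is_case))
    stop("run label_cases() before demographics_table()")
  cases <- x$demo[x$demo$is_case, , drop = FALSE]
  ev <- x$events[x$events$pt_code %in% as.integer(target_pt_codes), ,
                 drop = FALSE]
  ev <- ev[!duplicated(ev$case_id), ]
  first_pt <- ev$pt_code[match(cases$case_id, ev$case_id)]
  pt_labels <- names(target_pt_codes)
  if (is.null(pt_labels)) pt_labels <- as.character(target_pt_codes)
  ae <- table(factor(pt_labels[match(first_pt, target_pt_codes)],
                     levels = pt_labels))
  sex <- table(factor(cases$sex, levels = c("male", "female")))
  breaks <- c(-Inf, 20, 30, 40, 50, 60, 70, 80, 90, Inf)
  labs <- c("<19", "20-29", "30-39", "40-49", "50-59", "60-69",
            "70-79", "80-89", ">90")
  agebin <- table(cut(cases$age_years, breaks = breaks, labels = labs,
                      right = FALSE))
  occ <- cases$occupation
  occ[is.na(occ)] <- "missing"
  occ <- table(occ)
  rbind(
    data.frame(panel = "adverse_event", level = names(ae),
               count = as.integer(ae)),
    data.frame(panel = "sex", level = names(sex),
               count = as.integer(sex)),
    data.frame(panel = "age_decade", level = names(agebin),
               count = as.integer(agebin)),
    data.frame(panel = "reporter_occupation", level = names(occ),
               count = as.integer(occ)))
}

#' Run the full analysis pipeline on raw dialect files
#'
#' Reads the FAERS-dialect tables (and optionally JADER-dialect
#' tables), deduplicates case versions, applies the age/sex
#' exclusions, labels target-event cases, and produces the four
#' publication-style outputs: the attrition counts, the demographics
#' table, the disproportionality signal table, the time-to-onset
#' table and the adjusted-ROR table, plus a machine-readable run log.
#' All results are computed first and written together, so a failing
#' stage leaves no partial output.
#'
#' @param config list with elements `faers` (named paths `demo`,
#'   `drug`, `reac`, `ther`), optional `jader` (named paths `demo`,
#'   `drug`, `reac`, `hist`), optional `faers_dialect` /
#'   `jader_dialect` overrides, `pt_codes` (default
#'   [taste_disorder_pts()]), optional `drug_list`, and `thresholds`
#'   (defaults: signal 5, tto 20, adjusted 30).
#' @param out_dir output directory for the delimited tables; created
#'   if absent.
#' @return invisibly, a list with every computed artifact
#'   (`reports`, `screen`, `signal_table`, `onset_table`,
#'   `adjusted_table`, `demographics`, `attrition`, and when JADER
#'   input is given `jader_screen` and `intersection`).
#' @export
run_pipeline <- function(config, out_dir) {
  th <- utils::modifyList(list(signal = 5, tto = 20, adjusted = 30),
                          config$thresholds %||% list())
  pt <- config$pt_codes %||% taste_disorder_pts()

  fd <- config$faers_dialect %||% faers_dialect()
  raw <- read_faers_tables(config$faers$demo, config$faers$drug,
                           config$faers$reac, config$faers$ther,
                           dialect = fd)
  n_raw <- nrow(raw$demo)
  dd <- dedup_latest_version(raw)
  n_dedup <- nrow(dd$demo)
  rep_ <- apply_exclusions(dd)
  rep_ <- label_cases(rep_, pt)
  attrition <- data.frame(
    step = c("raw_case_rows", "after_dedup",
             paste0("excluded_", names(rep_$exclusions)),
             "analyzed"),
    count = c(n_raw, n_dedup, as.integer(rep_$exclusions),
              nrow(rep_$demo)))

  drugs <- config$drug_list %||% NULL
  screen <- screen_signals(rep_, drugs, min_cases = th$signal)
  sig_tab <- signal_table(screen, atc = config$atc %||% NULL)

  tto_drugs <- if (length(sig_tab$drug)) sig_tab$drug else character(0)
  onset_list <- lapply(tto_drugs, function(dn)
    compute_onset(rep_, dn, pt))
  onset <- if (length(onset_list)) do.call(rbind, onset_list)
           else data.frame(case_id = character(0),
                           drug_name = character(0),
                           time_to_onset_days = numeric(0))
  onset_tab <- onset_summary_table(onset, min_cases = th$tto)

  adj_tab <- if (length(tto_drugs))
    adjusted_summary_table(rep_, tto_drugs, min_cases = th$adjusted)
  else
    adjusted_summary_table(rep_, "none-listed", min_cases = th$adjusted)

  demo_tab <- demographics_table(rep_, pt)

  out <- list(reports = rep_, screen = screen, signal_table = sig_tab,
              onset_table = onset_tab, adjusted_table = adj_tab,
              demographics = demo_tab, attrition = attrition)

  if (!is.null(config$jader)) {
    jd <- config$jader_dialect %||% jader_dialect()
    jraw <- read_jader_tables(config$jader$demo, config$jader$drug,
                              config$jader$reac, config$jader$hist,
                              dialect = jd)
    jrep <- label_cases(apply_exclusions(dedup_latest_version(jraw)),
                        pt)
    jscreen <- screen_signals(jrep, drugs, min_cases = th$signal)
    out$jader_screen <- jscreen
    out$intersection <- cross_database_intersection(screen, jscreen)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  wt(attrition, "attrition.tsv")
  wt(demo_tab, "demographics.tsv")
  wt(sig_tab, "signal_table.tsv")
  wt(onset_tab, "time_to_onset.tsv")
  wt(adj_tab, "adjusted_ror.tsv")
  if (!is.null(out$intersection))
    writeLines(out$intersection,
               file.path(out_dir, "cross_database_signals.txt"))
  log_lines <- c(
    paste0("package_version=",
           as.character(utils::packageVersion("srssignal"))),
    paste0("r_version=", R.version.string),
    paste0("threshold_signal=", th$signal),
    paste0("threshold_tto=", th$tto),
    paste0("threshold_adjusted=", th$adjusted),
    paste0("n_raw=", n_raw), paste0("n_analyzed=", nrow(rep_$demo)),
    paste0("n_cases=", sum(rep_$demo$is_case)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check published signal-table values against recomputation
#'
#' Reads a margins file (drug, target-event cases n11, other-event
#' cases n10, database totals) together with the published ROR, CI, IC
#' and IC025 values, recomputes each statistic from the margins alone
#' and compares at 2 decimal places (half-up). The packaged default
#' fixture carries the margins of a published taste-disorder signal
#' table.
#'
#' @param margins_file CSV with columns `drug`, `n11`, `n10`,
#'   `nplus1`, `nplusplus`, `ror`, `ror_ci_low`, `ror_ci_high`, `ic`,
#'   `ic025`.
#' @return data.frame of class `printed_table_check`: one row per
#'   drug and quantity with `computed`, `printed`, `pass`; attribute
#'   `all_pass`.
#' @export
verify_printed_tables <- function(margins_file = table3_margins_file()) {
  if (!file.exists(margins_file))
    stop("margins fixture not found: ", margins_file)
  m <- utils::read.csv(margins_file, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    ct <- contingency_from_margins(r$n11, r$n10, r$nplus1, r$nplusplus)
    rr <- ror(ct)
    ic <- information_component(ct)
    computed <- c(ror = rr$ror, ror_ci_low = rr$ci_low,
                  ror_ci_high = rr$ci_high, ic = ic$ic,
                  ic025 = ic$ic025)
    printed <- c(r$ror, r$ror_ci_low, r$ror_ci_high, r$ic, r$ic025)
    data.frame(drug = r$drug, quantity = names(computed),
               computed = round_half_up(unname(computed), 2),
               printed = printed,
               pass = round_half_up(unname(computed), 2) == printed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  class(out) <- c("printed_table_check", "data.frame")
  out
}

#' Path of the packaged published-margins fixture
#'
#' @return path to the CSV of published 2x2 margins and statistics.
#' @export
table3_margins_file <- function() {
  system.file("extdata", "table3_margins.csv", package = "srssignal",
              mustWork = TRUE)
}

#' @export
print.printed_table_check <- function(x, ...) {
  cat(sprintf("printed-table check: %d/%d comparisons pass\n",
              sum(x$pass), nrow(x)))
  if (!all(x$pass)) print(as.data.frame(x)[!x$pass, ])
  invisible(x)
}
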