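#' Screen a drug list for disproportionality signals
#'
#' For each drug, builds the 2x2 table against the labelled reports and
#' computes the reporting odds ratio and the BCPNN information
#' component. A drug is signal-positive when it is eligible (at least
#' `min_cases` target-event reports), its ROR confidence interval lies
#' above 1 and its IC025 exceeds 0 — both criteria must fire. Drugs
#' whose expected joint count n1+ n+1 / n++ falls below 5 are flagged,
#' not filtered.
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param drug_list character vector of drug names to screen; `NULL`
#'   screens every accepted-role drug in the data.
#' @param min_cases minimum n11 for eligibility (default 5).
#' @return data.frame of class `srs_signal_screen`, one row per drug,
#'   sorted by n11 descending, with the table cells, both statistics,
#'   `eligible`, `ror_signal`, `ic_signal`, `signal` and
#'   `expected_lt5`.
#' @export
screen_signals <- function(x, drug_list = NULL, min_cases = 5) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(drug_list)) {
    drug_list <- sort(unique(accepted_drugs(x)$drug_name))
  }
  if (!length(drug_list)) stop("drug list must be non-empty")
  drug_list <- unique(normalize_drug_name(drug_list))
  rows <- lapply(drug_list, function(dn) {
    ct <- build_contingency(x, dn)
    rr <- ror(ct)
    ic <- information_component(ct)
    eligible <- ct$n11 >= min_cases
    data.frame(
      drug_name = dn, n11 = ct$n11, n10 = ct$n10, n1plus = ct$n1plus,
      ror = rr$ror, ror_ci_low = rr$ci_low, ror_ci_high = rr$ci_high,
      ic = ic$ic, ic025 = ic$ic025, eligible = eligible,
      ror_signal = rr$signal, ic_signal = ic$signal,
      signal = eligible && rr$signal && ic$signal,
      expected_lt5 = ct$n1plus * ct$nplus1 / ct$nplusplus < 5,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n11, out$drug_name), ]
  rownames(out) <- NULL
  class(out) <- c("srs_signal_screen", "data.frame")
  out
}

#' Drugs signalling in two databases
#'
#' Intersects two signal screens (e.g. FAERS and JADER) on normalized
#' drug name, keeping drugs signal-positive in both, ordered by the
#' first screen's case count descending.
#'
#' @param a,b `srs_signal_screen` data.frames.
#' @return character vector of drug names.
#' @export
cross_database_intersection <- function(a, b) {
  sa <- a$drug_name[a$signal]
  sb <- b$drug_name[b$signal]
  keep <- sa[sa %in% sb]
  keep[order(-a$n11[match(keep, a$drug_name)])]
}

#' Format a signal screen as a publication-style table
#'
#' One row per eligible drug with counts, "ROR (low-high)" and
#' "IC (IC025)" columns rounded half-up to 2 decimals, plus optional ATC
#' code annotation — the layout of a printed SRS signal table.
#'
#' @param screen an `srs_signal_screen`.
#' @param atc optional named character vector mapping drug name to ATC
#'   code (annotation only).
#' @param signals_only keep only signal-positive rows.
#' @return data.frame with character columns ready to write as text.
#' @export
signal_table <- function(screen, atc = NULL, signals_only = TRUE) {
  s <- screen[screen$eligible & (!signals_only | screen$signal), ,
              drop = FALSE]
  data.frame(
    drug = s$drug_name,
    atc_code = if (is.null(atc)) rep(NA_character_, nrow(s))
               else unname(atc[s$drug_name]),
    cases = s$n11, non_cases = s$n10, total = s$n1plus,
    ror_ci = sprintf("%s (%s-%s)", format_half_up(s$ror),
                     format_half_up(s$ror_ci_low),
                     format_half_up(s$ror_ci_high)),
    ic_ic025 = sprintf("%s (%s)", format_half_up(s$ic),
                       format_half_up(s$ic025)),
    stringsAsFactors = FALSE)
}
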