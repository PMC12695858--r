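#' Construct a 2x2 drug-event contingency table
#'
#' The unit of observation is one report: `n11` reports name the target
#' drug and the target event, `n10` the drug with any other event, `n01`
#' the event with any other drug, `n00` neither. Margins are derived and
#' checked for consistency.
#'
#' @param n11,n10,n01,n00 non-negative cell counts.
#' @return object of class `contingency_table` with cells and margins
#'   (`n1plus`, `n0plus`, `nplus1`, `nplus0`, `nplusplus`).
#' @examples
#' contingency_table(3968, 72107, 24485 - 3968,
#'                   10177264 - 76075 - (24485 - 3968))
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative counts")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n1plus = n11 + n10, n0plus = n01 + n00,
                 nplus1 = n11 + n01, nplus0 = n10 + n00,
                 nplusplus = n11 + n10 + n01 + n00),
            class = "contingency_table")
}

#' Contingency table from marginal totals
#'
#' Rebuilds the full 2x2 table from the counts a published signal table
#' prints: cases and non-cases for the drug plus the database totals of
#' target-event reports and all reports.
#'
#' @param n11 reports with target drug and target event.
#' @param n10 reports with target drug, other events.
#' @param nplus1 total target-event reports in the database.
#' @param nplusplus total reports in the database.
#' @return a `contingency_table`.
#' @export
contingency_from_margins <- function(n11, n10, nplus1, nplusplus) {
  n01 <- nplus1 - n11
  n00 <- nplusplus - (n11 + n10) - n01
  contingency_table(n11, n10, n01, n00)
}

#' Build the 2x2 table for one drug from cleaned reports
#'
#' Each surviving report contributes to exactly one cell: exposure is
#' whether the report names `drug_name` among its accepted-role drugs
#' (a report naming it twice counts once), outcome is the `is_case`
#' label. Cells always sum to the number of reports.
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param drug_name drug name (normalized internally).
#' @return a `contingency_table`.
#' @export
build_contingency <- function(x, drug_name) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(x$demo$is_case))
    stop("run label_cases() before build_contingency()")
  drug_name <- normalize_drug_name(drug_name)
  d <- accepted_drugs(x)
  exposed_ids <- unique(d$case_id[d$drug_name == drug_name])
  exposed <- x$demo$case_id %in% exposed_ids
  case <- x$demo$is_case
  contingency_table(sum(exposed & case), sum(exposed & !case),
                    sum(!exposed & case), sum(!exposed & !case))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n01, x$nplus1, x$n10, x$n00, x$nplus0,
                x$n1plus, x$n0plus, x$nplusplus), nrow = 3,
              dimnames = list(c("target drug", "other drugs", "total"),
                              c("target AE", "other AEs", "total")))
  print(m)
  invisible(x)
}
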