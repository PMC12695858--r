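# Age- and sex-adjusted reporting odds ratios. The model is
#   log odds(case) = b0 + bD * drug + bA * age + bG * sex
# fitted by maximum-likelihood logistic regression; the adjusted ROR is
# exp(bD) with a Wald interval. Eligibility follows the
# events-per-variable rule of thumb (EPV 10, three explanatory
# variables, hence at least 30 target-event reports for the drug), and
# collinearity is checked with variance inflation factors.

#' Observation matrix for the adjusted-ROR model
#'
#' One row per cleaned report: outcome `y` (target-event case), drug
#' indicator `D` (exposure to `drug_name` with an accepted role), age
#' `A` in years (continuous) and sex indicator `G` (female = 1,
#' male = 0).
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param drug_name drug name (normalized internally).
#' @return data.frame with columns `y`, `D`, `A`, `G`.
#' @export
build_design <- function(x, drug_name) {
  stopifnot(inherits(x, "srs_reports"))
  if (is.null(x$demo$is_case))
    stop("run label_cases() before build_design()")
  drug_name <- normalize_drug_name(drug_name)
  d <- accepted_drugs(x)
  exposed_ids <- unique(d$case_id[d$drug_name == drug_name])
  des <- data.frame(y = as.integer(x$demo$is_case),
                    D = as.integer(x$demo$case_id %in% exposed_ids),
                    A = x$demo$age_years,
                    G = as.integer(x$demo$sex == "female"))
  if (sum(des$D) == 0)
    stop(sprintf("no reports exposed to '%s'; fit refused", drug_name))
  if (sum(des$y) == 0)
    stop("no target-event cases in the data; fit refused")
  des
}

# Variance inflation factors via the auxiliary-regression closed form:
# VIF_j = [ (R^-1)_jj ] for R the correlation matrix of the columns.
vif_from_design <- function(X) {
  R <- stats::cor(X)
  v <- diag(solve(R))
  names(v) <- colnames(X)
  v
}

#' Fit the age- and sex-adjusted reporting odds ratio for one drug
#'
#' Maximum-likelihood logistic regression of case status on drug
#' exposure, age and sex. Reports the crude ROR from the 2x2 table and
#' the adjusted ROR exp(bD), both with 95% Wald intervals, plus VIFs
#' for the three explanatory columns (values of 2 or more raise a
#' warning, not an error). The fit is refused when the drug has fewer
#' target-event cases than `min_cases` (EPV rule) or when a cell of the
#' drug-by-outcome table is empty (separation).
#'
#' @param design data.frame from [build_design()], or an `srs_reports`
#'   object (then `drug_name` must be given and the design is built
#'   internally).
#' @param drug_name drug name when `design` is an `srs_reports` object.
#' @param min_cases minimum exposed target-event cases (default 30 =
#'   EPV 10 x 3 variables).
#' @return object of class `adjusted_ror` with elements `drug_name`,
#'   `n11`, `crude` (estimate, ci), `adjusted` (estimate, ci),
#'   `coefficients`, `vif`, `glm_fit`.
#' @export
fit_adjusted <- function(design, drug_name = NULL, min_cases = 30) {
  if (inherits(design, "srs_reports")) {
    if (is.null(drug_name))
      stop("drug_name is required when passing reports")
    design <- build_design(design, drug_name)
  }
  stopifnot(all(c("y", "D", "A", "G") %in% names(design)))
  n11 <- sum(design$y == 1 & design$D == 1)
  if (n11 < min_cases)
    stop(sprintf(paste0("drug has %d target-event cases, below the ",
                        "events-per-variable minimum of %d"),
                 n11, min_cases))
  tab <- table(factor(design$D, levels = 0:1),
               factor(design$y, levels = 0:1))
  if (any(tab == 0))
    stop("empty drug-by-outcome cell (separation); fit refused")
  fit <- stats::glm(y ~ D + A + G, family = stats::binomial(),
                    data = design,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged)
    stop(sprintf("logistic fit did not converge%s",
                 if (is.null(drug_name)) "" else paste0(" for ",
                                                        drug_name)))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  adj <- exp(co["D"] + c(0, -1.96, 1.96) * c(0, se["D"], se["D"]))
  crude_ror <- ror(contingency_table(
    n11, sum(design$D == 1) - n11,
    sum(design$y == 1) - n11,
    sum(design$D == 0 & design$y == 0)))
  vifs <- vif_from_design(as.matrix(design[, c("D", "A", "G")]))
  if (any(vifs >= 2))
    warning("variance inflation factor >= 2; collinear covariates",
            call. = FALSE)
  structure(list(
    drug_name = drug_name, n11 = n11,
    crude = c(ror = crude_ror$ror, ci_low = crude_ror$ci_low,
              ci_high = crude_ror$ci_high),
    adjusted = c(ror = unname(adj[1]), ci_low = unname(adj[2]),
                 ci_high = unname(adj[3])),
    coefficients = co, vif = vifs, glm_fit = fit),
    class = "adjusted_ror")
}

#' @export
print.adjusted_ror <- function(x, ...) {
  cat(sprintf("Age/sex-adjusted reporting odds ratio%s (n11 = %d)\n",
              if (is.null(x$drug_name)) "" else paste0(" for ",
                                                       x$drug_name),
              x$n11))
  cat(sprintf("  crude    %s (%s-%s)\n", format_half_up(x$crude[1]),
              format_half_up(x$crude[2]), format_half_up(x$crude[3])))
  cat(sprintf("  adjusted %s (%s-%s)\n", format_half_up(x$adjusted[1]),
              format_half_up(x$adjusted[2]),
              format_half_up(x$adjusted[3])))
  cat("  VIF:", paste(names(x$vif), format_half_up(x$vif), sep = "=",
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.adjusted_ror <- function(object, ...) object$coefficients

#' Crude and adjusted ROR table across drugs
#'
#' Fits [fit_adjusted()] for every drug in `drug_list` with at least
#' `min_cases` target-event reports and lays out the publication-style
#' table: drug, cases, total exposed, crude ROR (CI), adjusted ROR
#' (CI). Drugs below the gate (or refused for separation) are omitted.
#'
#' @param x an `srs_reports` object after [label_cases()].
#' @param drug_list character vector of drug names.
#' @param min_cases minimum exposed cases (default 30).
#' @return data.frame, one row per retained drug, cases descending.
#' @export
adjusted_summary_table <- function(x, drug_list, min_cases = 30) {
  rows <- lapply(unique(normalize_drug_name(drug_list)), function(dn) {
    res <- tryCatch(fit_adjusted(x, dn, min_cases = min_cases),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(
      drug = dn, cases = res$n11,
      total = sum(build_design(x, dn)$D),
      crude_ror_ci = sprintf("%s (%s-%s)", format_half_up(res$crude[1]),
                             format_half_up(res$crude[2]),
                             format_half_up(res$crude[3])),
      adjusted_ror_ci = sprintf("%s (%s-%s)",
                                format_half_up(res$adjusted[1]),
                                format_half_up(res$adjusted[2]),
                                format_half_up(res$adjusted[3])),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(drug = character(0), cases = integer(0),
                      total = integer(0), crude_ror_ci = character(0),
                      adjusted_ror_ci = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$cases, out$drug), ]
  rownames(out) <- NULL
  out
}
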