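# Disproportionality statistics on the 2x2 report table: the reporting
# odds ratio with its Wald interval, and the BCPNN information component
# with its +/- 2 SD credible interval.

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (n11/n10) / (n01/n00), the odds of the target event among
#' reports of the target drug over the same odds among all other
#' reports. The interval is the log-scale Wald interval,
#' exp(ln ROR +/- 1.96 * sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)).
#' A signal requires the lower bound to exceed 1. Any zero cell makes
#' the estimate undefined; the result is then flagged degenerate and
#' carries no signal.
#'
#' @param table a `contingency_table`.
#' @param conf_z normal quantile for the interval (1.96 for 95%).
#' @return object of class `srs_ror`: `ror`, `ci_low`, `ci_high`,
#'   `signal`, `degenerate`.
#' @examples
#' ror(contingency_from_margins(3968, 72107, 24485, 10177264))
#' @export
ror <- function(table, conf_z = 1.96) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  if (any(cells == 0)) {
    return(structure(list(ror = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, signal = FALSE,
                          degenerate = TRUE),
                     class = "srs_ror"))
  }
  est <- (table$n11 / table$n10) / (table$n01 / table$n00)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(est) + c(-1, 1) * conf_z * se)
  structure(list(ror = est, ci_low = ci[1], ci_high = ci[2],
                 signal = ci[1] > 1, degenerate = FALSE),
            class = "srs_ror")
}

#' BCPNN information component with 95% credible interval
#'
#' The information component is the posterior-expected log2 ratio of the
#' observed to expected joint reporting probability under the Bayesian
#' Confidence Propagation Neural Network model with conventional priors
#' (gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2):
#'
#'   E(IC) = log2 ( (n11 + gamma11)(N + alpha)(N + beta) /
#'                  ((N + gamma)(n1+ + alpha1)(n+1 + beta1)) )
#'
#' with gamma = gamma11 (N + alpha)(N + beta) /
#' ((n1+ + alpha1)(n+1 + beta1)) and N = n++. The variance is the
#' three-term closed form over the joint and the two marginal
#' posteriors, scaled by 1/ln^2(2); the credible interval is
#' E(IC) +/- 2 sqrt(V). A signal requires IC025 > 0.
#'
#' @param table a `contingency_table` with positive total.
#' @return object of class `srs_ic`: `ic`, `variance`, `ic025`, `ic975`,
#'   `signal`, `prior_gamma`, and the prior constants in `priors`.
#' @examples
#' information_component(contingency_from_margins(10, 1139, 24485, 10177264))
#' @export
information_component <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  N <- table$nplusplus
  if (N <= 0) stop("information component undefined for an empty table")
  g11 <- 1; a1 <- 1; b1 <- 1; a <- 2; b <- 2
  n11 <- table$n11; n1p <- table$n1plus; np1 <- table$nplus1
  gam <- g11 * (N + a) * (N + b) / ((n1p + a1) * (np1 + b1))
  ic <- log2((n11 + g11) * (N + a) * (N + b) /
               ((N + gam) * (n1p + a1) * (np1 + b1)))
  v <- (1 / log(2)^2) * (
    (N - n11 + gam - g11) / ((n11 + g11) * (1 + N + gam)) +
    (N - n1p + a - a1)    / ((n1p + a1) * (1 + N + a)) +
    (N - np1 + b - b1)    / ((np1 + b1) * (1 + N + b)))
  ci <- ic + c(-2, 2) * sqrt(v)
  structure(list(ic = ic, variance = v, ic025 = ci[1], ic975 = ci[2],
                 signal = ci[1] > 0, prior_gamma = gam,
                 priors = c(gamma11 = g11, alpha1 = a1, beta1 = b1,
                            alpha = a, beta = b)),
            class = "srs_ic")
}

#' @export
print.srs_ror <- function(x, digits = 2, ...) {
  if (x$degenerate) {
    cat("ROR undefined (zero cell)\n")
  } else {
    cat(sprintf("ROR %s (95%% CI %s-%s)%s\n",
                format_half_up(x$ror, digits),
                format_half_up(x$ci_low, digits),
                format_half_up(x$ci_high, digits),
                if (x$signal) "  [signal]" else ""))
  }
  invisible(x)
}

#' @export
print.srs_ic <- function(x, digits = 2, ...) {
  cat(sprintf("IC %s (IC025 %s)%s\n", format_half_up(x$ic, digits),
              format_half_up(x$ic025, digits),
              if (x$signal) "  [signal]" else ""))
  invisible(x)
}

#' Round half away from zero
#'
#' Published SRS tables round half-up (2.675 -> 2.68), not to even as
#' [round()] does; used when comparing recomputed statistics against
#' printed values.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_half_up <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
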