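# Weibull characterisation of time-to-onset. The estimator is the
# classical probability plot: regress ln(-ln(1 - F_i)) on ln(t_i) using
# rank-based plotting positions; the slope is the shape parameter beta
# and exp(-intercept/slope) the scale. beta < 1 means a hazard falling
# with time on drug (early failure), beta = 1 a constant hazard (random
# failure), beta > 1 a rising hazard (wear-out failure); classification
# uses the 95% CI of the slope.

#' Plotting positions for a Weibull probability plot
#'
#' Sorts the times ascending and assigns the empirical CDF position for
#' rank i: the mean rank i/(n+1) for samples of 30 or more, otherwise
#' the median rank by Benard's approximation (i - 0.3)/(n + 0.4). Ties
#' keep distinct sequential ranks in stable sorted order, so positions
#' are strictly increasing and lie inside (0, 1).
#'
#' @param times positive numeric vector, length >= 2.
#' @param method `"auto"` (mean rank iff n >= 30), `"mean_rank"` or
#'   `"median_rank"`.
#' @return data.frame `time`, `position`, with the method used as
#'   attribute `rank_method`.
#' @export
empirical_cdf_ranks <- function(times,
                                method = c("auto", "mean_rank",
                                           "median_rank")) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2) stop("at least two onset times are required")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("onset times must be positive and finite")
  if (method == "auto")
    method <- if (n >= 30) "mean_rank" else "median_rank"
  i <- seq_len(n)
  pos <- if (method == "mean_rank") i / (n + 1) else (i - 0.3) / (n + 0.4)
  out <- data.frame(time = sort(times), position = pos)
  attr(out, "rank_method") <- method
  out
}

# Plot slope in closed form (cov/var), used by the bootstrap loop.
plot_slope <- function(times, n, mean_rank) {
  x <- log(sort(times))
  i <- seq_len(n)
  pos <- if (mean_rank) i / (n + 1) else (i - 0.3) / (n + 0.4)
  y <- log(-log(1 - pos))
  stats::cov(x, y) / stats::var(x)
}

#' Fit a Weibull distribution to onset times by probability plot
#'
#' Least-squares line of y = ln(-ln(1 - F)) on x = ln(t) over the
#' plotting positions of [empirical_cdf_ranks()]. The slope estimates
#' the shape beta, exp(-intercept/slope) the scale in days. The 95% CI
#' of beta is, by default, the percentile interval of a nonparametric
#' bootstrap of the plot slope (the naive regression standard error is
#' far too small here, because the plot's points are order statistics
#' and strongly correlated; its interval is available as
#' `ci_method = "regression"` for comparison but badly undercovers).
#' The failure pattern is early failure if the CI lies below 1,
#' wear-out failure if above 1, random failure if it spans 1. Summary
#' statistics (mean, median, IQR) are computed from the raw times with
#' linearly interpolated quantiles. The bootstrap draws from the
#' current RNG stream; seed it for reproducibility.
#'
#' @param times positive onset times in days.
#' @param min_cases refuse the fit below this sample size (default 20,
#'   the usual gate for onset characterisation).
#' @param method plotting-position rule, see [empirical_cdf_ranks()].
#' @param ci_method `"bootstrap"` (default) or `"regression"`
#'   (t-based interval from the naive regression slope SE).
#' @param boot_reps bootstrap resamples for the CI.
#' @return object of class `weibull_tto`.
#' @examples
#' set.seed(1)
#' fit <- fit_weibull_plot(rweibull(100, shape = 0.6, scale = 30))
#' fit
#' coef(fit)
#' @export
fit_weibull_plot <- function(times, min_cases = 20, method = "auto",
                             ci_method = c("bootstrap", "regression"),
                             boot_reps = 200) {
  ci_method <- match.arg(ci_method)
  n <- length(times)
  if (n < min_cases)
    stop(sprintf(paste0("n = %d is below the minimum of %d cases ",
                        "required for time-to-onset analysis"),
                 n, min_cases))
  if (any(!is.finite(times)) || any(times <= 0))
    stop("onset times must be positive and finite")
  rk <- empirical_cdf_ranks(times, method)
  x <- log(rk$time)
  y <- log(-log(1 - rk$position))
  if (stats::sd(x) == 0)
    stop("all onset times identical; Weibull plot is degenerate")
  fit <- stats::lm(y ~ x)
  beta <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (ci_method == "regression") {
    se <- summary(fit)$coefficients[2, 2]
    ci <- beta + c(-1, 1) * stats::qt(0.975, df = n - 2) * se
  } else {
    mean_rank <- attr(rk, "rank_method") == "mean_rank"
    bs <- vapply(seq_len(boot_reps), function(b) {
      plot_slope(sample(times, n, replace = TRUE), n, mean_rank)
    }, numeric(1))
    ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  pattern <- if (ci[2] < 1) "early_failure"
             else if (ci[1] > 1) "wear_out_failure"
             else "random_failure"
  q <- unname(stats::quantile(times, c(0.25, 0.5, 0.75)))
  structure(list(
    n = n, shape = beta, shape_ci = ci, scale = exp(-intercept / beta),
    mean_days = mean(times), median_days = q[2], iqr = q[c(1, 3)],
    pattern = pattern, rank_method = attr(rk, "rank_method"),
    ci_method = ci_method,
    plot_data = data.frame(log_time = x, log_neglog = y),
    lm_fit = fit), class = "weibull_tto")
}

#' Maximum-likelihood Weibull fit (diagnostic cross-check)
#'
#' Direct Newton optimisation of the Weibull log-likelihood, offered as
#' an independent check on the probability-plot estimate; the plot
#' method remains the primary estimator because it is the standard of
#' SRS time-to-onset practice.
#'
#' @param times positive onset times in days.
#' @return named vector `shape`, `scale`.
#' @export
fit_weibull_mle <- function(times) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop("onset times must be positive and finite")
  nll <- function(p) -sum(stats::dweibull(times, exp(p[1]), exp(p[2]),
                                          log = TRUE))
  p0 <- c(0, log(mean(times)))
  opt <- stats::optim(p0, nll, method = "BFGS")
  c(shape = exp(opt$par[1]), scale = exp(opt$par[2]))
}

#' @export
print.weibull_tto <- function(x, ...) {
  cat(sprintf(paste0("Weibull time-to-onset fit (probability plot, ",
                     "%s)\n  n = %d, shape beta = %.2f (95%% CI ",
                     "%.2f-%.2f), scale = %.1f days\n  median %.1f ",
                     "days (IQR %.1f, %.1f); pattern: %s\n"),
              gsub("_", " ", x$rank_method), x$n, x$shape,
              x$shape_ci[1], x$shape_ci[2], x$scale, x$median_days,
              x$iqr[1], x$iqr[2], gsub("_", " ", x$pattern)))
  invisible(x)
}

#' @export
coef.weibull_tto <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' @export
confint.weibull_tto <- function(object, parm = "shape", level = 0.95,
                                ...) {
  if (level != 0.95)
    stop("only the 95% interval is computed at fit time")
  matrix(object$shape_ci, nrow = 1,
         dimnames = list("shape", sprintf("%g %%",
                         c((1 - level) / 2, 1 - (1 - level) / 2) * 100)))
}

#' @export
summary.weibull_tto <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.weibull_tto <- function(x, ...) {
  graphics::plot(x$plot_data$log_time, x$plot_data$log_neglog,
                 xlab = "ln(time to onset, days)",
                 ylab = "ln(-ln(1 - F))",
                 main = "Weibull probability plot", ...)
  graphics::abline(x$lm_fit, col = 2)
  invisible(x)
}

#' Per-drug time-to-onset summary table
#'
#' Fits the Weibull plot for every drug with at least `min_cases` onset
#' records and lays the results out as a publication-style table:
#' cases, mean days, median (IQR), shape with CI, failure pattern.
#' Drugs below the gate are omitted.
#'
#' @param onset_records data.frame with columns `drug_name` and
#'   `time_to_onset_days` (rows from [compute_onset()], possibly
#'   several drugs bound together).
#' @param min_cases minimum records per drug (default 20).
#' @return data.frame, one row per retained drug, sorted by cases
#'   descending.
#' @export
onset_summary_table <- function(onset_records, min_cases = 20) {
  empty <- data.frame(drug = character(0), cases = integer(0),
                      mean_time = numeric(0), median_iqr = character(0),
                      shape_ci = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(onset_records)) return(empty)
  rows <- lapply(split(onset_records$time_to_onset_days,
                       onset_records$drug_name), function(t) t)
  rows <- rows[vapply(rows, length, 1L) >= min_cases]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, lapply(names(rows), function(dn) {
    f <- fit_weibull_plot(rows[[dn]], min_cases = min_cases)
    data.frame(
      drug = dn, cases = f$n, mean_time = round_half_up(f$mean_days, 1),
      median_iqr = sprintf("%s (%s, %s)",
                           format_half_up(f$median_days, 1),
                           format_half_up(f$iqr[1], 1),
                           format_half_up(f$iqr[2], 1)),
      shape_ci = sprintf("%s (%s-%s)", format_half_up(f$shape),
                         format_half_up(f$shape_ci[1]),
                         format_half_up(f$shape_ci[2])),
      pattern = f$pattern, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$cases, out$drug), ]
  rownames(out) <- NULL
  out
}
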