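# Parametric-bootstrap uncertainty: coefficient triples are drawn from the
# asymptotic multivariate normal sampling distribution of the Poisson fit,
# each draw is pushed through rate prediction and the life table, and the
# percentile interval of the resulting life expectancies is reported.

#' Draw coefficient triples from a fitted rate model
#'
#' Multivariate normal draws with mean the estimates and covariance the
#' fit's covariance, via a symmetric eigenvalue factorisation. Eigenvalues
#' between -1e-10 and 0 are clipped to zero (numerical PSD tolerance); anything
#' more negative is an error naming the offending eigenvalue.
#'
#' @param fit A converged [fit_poisson_quadratic()] object.
#' @param n_sim Number of draws.
#' @param seed Integer seed; identical seeds give identical draw matrices.
#' @return `n_sim` x 3 matrix of coefficient draws.
#' @export
draw_coefficients <- function(fit, n_sim = 1000L, seed = 1L) {
  if (!isTRUE(fit$converged))
    stop("refusing to simulate from an unconverged fit", call. = FALSE)
  V <- (fit$vcov + t(fit$vcov)) / 2
  eg <- eigen(V, symmetric = TRUE)
  if (any(eg$values < -1e-10))
    stop(sprintf("covariance is not positive semi-definite (eigenvalue %.3e)",
                 min(eg$values)), call. = FALSE)
  vals <- pmax(eg$values, 0)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_sim * 3L), n_sim, 3L)
  draws <- z %*% (t(eg$vectors) * sqrt(vals))
  draws <- sweep(draws, 2L, fit$coefficients, "+")
  colnames(draws) <- names(fit$coefficients)
  draws
}

#' Life expectancy with a simulation confidence interval
#'
#' For each coefficient draw, predicts the age-specific rates, builds the
#' period life table and records the total life expectancy; the interval is
#' the percentile interval of those draws. The point estimate always comes
#' from the point-estimate coefficients, not the draw mean. Draws yielding a
#' non-finite life expectancy are rejected and counted; more than 1%
#' rejections is an error.
#'
#' @param fit A converged [fit_poisson_quadratic()] object.
#' @param n_sim Number of simulation draws (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param ages,a,radix Life-table settings (see [build_life_table()]).
#' @return Object of class `le_estimate`: total life expectancy (starting
#'   age added back), interval, the draw vector and the point life table.
#' @export
le_interval <- function(fit, n_sim = 1000L, seed = 1L, level = 0.95,
                        ages = 18:100, a = 0.5, radix = 1e5) {
  draws <- draw_coefficients(fit, n_sim, seed)
  le <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    mi <- predict_rates(fit, ages, coefficients = draws[i, ])
    le[i] <- if (all(is.finite(mi)))
      total_life_expectancy(build_life_table(mi, ages, a, radix))
    else NA_real_
  }
  bad <- !is.finite(le)
  if (mean(bad) > 0.01)
    stop(sprintf("%.1f%% of simulation draws produced non-finite life \
expectancy", 100 * mean(bad)), call. = FALSE)
  if (any(bad))
    message(sum(bad), " simulation draw(s) rejected (non-finite)")
  le <- le[!bad]
  lt <- build_life_table(predict_rates(fit, ages), ages, a, radix)
  ci <- unname(stats::quantile(le, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(list(
    group = fit$group, sex = fit$sex,
    total_life_expectancy = total_life_expectancy(lt),
    ci_low = ci[1], ci_high = ci[2], level = level,
    n_sim = n_sim, n_rejected = sum(bad), seed = seed,
    draws = le, life_table = lt
  ), class = "le_estimate")
}

#' @export
print.le_estimate <- function(x, ...) {
  cat(sprintf(
    "Total life expectancy (%s, %s): %.2f years (%d%% CI: %.2f-%.2f)\n",
    paste(x$group, collapse = "/"), paste(x$sex, collapse = "/"),
    x$total_life_expectancy, round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Years-of-life-lost interval from two fitted rate models
#'
#' Independent coefficient draws for the two groups (the models are fitted
#' separately), paired by draw index; the reported interval is the
#' percentile interval of the pairwise differences comparison minus exposed.
#' The exposed group uses `seed` and the comparison group `seed + 1`.
#'
#' @param fit_exposed,fit_comparison Converged fits for the same sex.
#' @inheritParams le_interval
#' @return Object of class `yll_estimate` (see [years_of_life_lost()]).
#' @export
yll_interval <- function(fit_exposed, fit_comparison, n_sim = 1000L,
                         seed = 1L, level = 0.95, ages = 18:100, a = 0.5,
                         radix = 1e5) {
  if (!identical(fit_exposed$sex, fit_comparison$sex))
    stop("both fits must describe the same sex", call. = FALSE)
  le_e <- le_interval(fit_exposed, n_sim, seed, level, ages, a, radix)
  le_c <- le_interval(fit_comparison, n_sim, seed + 1L, level, ages, a, radix)
  years_of_life_lost(le_e, le_c, level)
}
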