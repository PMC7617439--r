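#' Fit the full life-expectancy-gap model to a strata table
#'
#' The central estimator of the package. Given deaths and person-years
#' stratified by group (exposed / comparison), sex and single year of age,
#' it fits one quadratic-age Poisson rate model per group and sex, converts
#' each to a period life table and a total life expectancy with a
#' parametric-bootstrap confidence interval, forms the years-of-life-lost
#' contrast per sex from paired simulation draws, and estimates per-sex
#' mortality rate ratios (age-adjusted and crude).
#'
#' @param strata Data frame with columns `group` (`"exposed"`,
#'   `"comparison"`), `sex`, `age`, `deaths`, `person_years` — the output of
#'   [tabulate_strata()] or an equivalent user table.
#' @param n_sim Simulation draws per group for the intervals (default 1000).
#' @param seed Integer seed driving all simulation draws.
#' @param level Confidence level (default 0.95).
#' @param ages Ages spanned by the life table (default 18 to 100).
#' @param a Fraction-of-interval-lived constant (default 0.5).
#' @param radix Life-table radix (default 100 000).
#' @return Object of class `lifegap` with components `fits` (named
#'   `group.sex` list of [fit_poisson_quadratic()] objects), `le` (named
#'   list of `le_estimate`s), `yll` (per-sex `yll_estimate`s), `mrr`
#'   (per-sex `mrr_estimate`s) and the input `strata`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' sim <- simulate_ehr(sim_config(n_practices = 5, persons_per_practice = 200,
#'                                exposure_prevalence = 0.5, seed = 7))
#' cb <- build_cohort(sim$persons, sim$practices, match_ratio = 0)
#' strata <- tabulate_strata(cb$cohort, sim$persons)
#' fit <- lifegap(strata, n_sim = 100, seed = 1)
#' print(fit)
#' @export
lifegap <- function(strata, n_sim = 1000L, seed = 1L, level = 0.95,
                    ages = 18:100, a = 0.5, radix = 1e5) {
  need <- c("group", "sex", "age", "deaths", "person_years")
  miss <- setdiff(need, names(strata))
  if (length(miss))
    stop("strata table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sexes <- sort(unique(strata$sex))
  groups <- sort(unique(strata$group))

  fits <- list()
  le <- list()
  k <- 0L
  for (g in groups) for (s in sexes) {
    sub <- strata[strata$group == g & strata$sex == s, , drop = FALSE]
    if (!nrow(sub) || sum(sub$deaths) == 0) next
    key <- paste(g, s, sep = ".")
    fits[[key]] <- fit_poisson_quadratic(sub, group = g, sex = s)
    le[[key]] <- le_interval(fits[[key]], n_sim = n_sim, seed = seed + k,
                             level = level, ages = ages, a = a, radix = radix)
    k <- k + 2L
  }

  yll <- list()
  mrr <- list()
  for (s in sexes) {
    ke <- paste("exposed", s, sep = ".")
    kc <- paste("comparison", s, sep = ".")
    if (!is.null(le[[ke]]) && !is.null(le[[kc]])) {
      yll[[s]] <- years_of_life_lost(le[[ke]], le[[kc]], level)
      mrr[[s]] <- estimate_mrr(strata, sex = s, level = level)
    }
  }

  structure(list(fits = fits, le = le, yll = yll, mrr = mrr,
                 strata = strata, n_sim = n_sim, seed = seed, level = level,
                 ages = ages, a = a, radix = radix),
            class = "lifegap")
}

#' @export
print.lifegap <- function(x, ...) {
  cat("Life-expectancy gap model\n")
  cat(sprintf("  strata: %d cells, %d deaths, %.0f person-years\n",
              nrow(x$strata), sum(x$strata$deaths),
              sum(x$strata$person_years)))
  for (key in names(x$le)) {
    e <- x$le[[key]]
    cat(sprintf("  LE %-20s %6.2f (%.2f-%.2f)\n", key,
                e$total_life_expectancy, e$ci_low, e$ci_high))
  }
  for (s in names(x$yll)) {
    y <- x$yll[[s]]
    cat(sprintf("  YLL %-19s %6.2f (%.2f-%.2f)\n", s, y$yll, y$ci_low,
                y$ci_high))
  }
  for (s in names(x$mrr)) {
    m <- x$mrr[[s]]
    cat(sprintf("  MRR %-19s %6.2f (%.2f-%.2f) adjusted; %.2f crude\n", s,
                m$ratio, m$ci_low, m$ci_high, m$crude_ratio))
  }
  invisible(x)
}

#' @export
summary.lifegap <- function(object, ...) {
  le_tab <- do.call(rbind, lapply(names(object$le), function(k) {
    e <- object$le[[k]]
    data.frame(group = e$group, sex = e$sex,
               total_le = e$total_life_expectancy,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  }))
  yll_tab <- do.call(rbind, lapply(names(object$yll), function(s) {
    y <- object$yll[[s]]
    data.frame(sex = s, yll = y$yll, ci_low = y$ci_low, ci_high = y$ci_high,
               stringsAsFactors = FALSE)
  }))
  mrr_tab <- do.call(rbind, lapply(names(object$mrr), function(s) {
    m <- object$mrr[[s]]
    data.frame(sex = s, ratio = m$ratio, ci_low = m$ci_low,
               ci_high = m$ci_high, crude_ratio = m$crude_ratio,
               stringsAsFactors = FALSE)
  }))
  out <- list(le = le_tab, yll = yll_tab, mrr = mrr_tab,
              coefficients = coef(object), level = object$level)
  class(out) <- "summary.lifegap"
  out
}

#' @export
print.summary.lifegap <- function(x, ...) {
  cat(sprintf("Total life expectancy (%d%% CI):\n", round(100 * x$level)))
  print(x$le, row.names = FALSE, digits = 5)
  if (!is.null(x$yll)) {
    cat("\nYears of life lost (comparison - exposed):\n")
    print(x$yll, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$mrr)) {
    cat("\nMortality rate ratios (age-adjusted; crude alongside):\n")
    print(x$mrr, row.names = FALSE, digits = 4)
  }
  cat("\nPoisson coefficients (log rate; z = (age - 50)/10):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.lifegap <- function(object, ...) {
  t(vapply(object$fits, coef, numeric(3)))
}

#' Predicted modelled rates for every fitted group and sex
#'
#' @param object A [lifegap()] fit.
#' @param ages Ages at which to evaluate (defaults to the fit's ages).
#' @param per Multiplier for reporting (default 1: per person-year).
#' @param ... Unused.
#' @return Long data frame `group`, `sex`, `age`, `rate`.
#' @export
predict.lifegap <- function(object, ages = NULL, per = 1, ...) {
  if (is.null(ages)) ages <- object$ages
  do.call(rbind, lapply(names(object$fits), function(k) {
    f <- object$fits[[k]]
    data.frame(group = f$group, sex = f$sex, age = ages,
               rate = predict_rates(f, ages) * per,
               stringsAsFactors = FALSE)
  }))
}

#' @export
residuals.lifegap <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  do.call(rbind, lapply(names(object$fits), function(k) {
    f <- object$fits[[k]]
    mu <- f$data$person_years * predict_rates(f, f$data$age)
    d <- f$data$deaths
    r <- if (type == "pearson") (d - mu) / sqrt(mu)
    else sign(d - mu) * sqrt(2 * (ifelse(d > 0, d * log(d / mu), 0) - (d - mu)))
    data.frame(group = f$group, sex = f$sex, age = f$data$age, residual = r,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate life-expectancy draws from a fitted model
#'
#' Re-runs the parametric bootstrap: coefficient draws from each fit's
#' sampling distribution pushed through the life table.
#'
#' @param object A [lifegap()] fit.
#' @param nsim Draws per group/sex (defaults to the fit's `n_sim`).
#' @param seed Seed (defaults to the fit's seed).
#' @param ... Unused.
#' @return Data frame `group`, `sex`, `draw`, `total_le`.
#' @export
simulate.lifegap <- function(object, nsim = NULL, seed = NULL, ...) {
  if (is.null(nsim)) nsim <- object$n_sim
  if (is.null(seed)) seed <- object$seed
  k <- 0L
  out <- lapply(names(object$fits), function(key) {
    f <- object$fits[[key]]
    est <- le_interval(f, n_sim = nsim, seed = seed + k, level = object$level,
                       ages = object$ages, a = object$a, radix = object$radix)
    k <<- k + 2L
    data.frame(group = f$group, sex = f$sex,
               draw = seq_along(est$draws), total_le = est$draws,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot modelled and crude mortality rates by age
#'
#' Base-graphics plot of the modelled rate curves (per 100 000 person-years,
#' log scale) for every group and sex, with crude stratum rates overlaid as
#' points sized by information.
#'
#' @param x A [lifegap()] fit.
#' @param per Rate multiplier (default 1e5).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lifegap <- function(x, per = 1e5, ...) {
  pr <- predict.lifegap(x, per = per)
  keys <- unique(paste(pr$group, pr$sex, sep = "."))
  cols <- seq_along(keys)
  rng <- range(pr$rate[pr$rate > 0])
  graphics::plot(NA, xlim = range(pr$age), ylim = rng, log = "y",
                 xlab = "Age (years)",
                 ylab = sprintf("Mortality rate per %g person-years", per),
                 main = "Modelled mortality rates by age", ...)
  for (i in seq_along(keys)) {
    sel <- paste(pr$group, pr$sex, sep = ".") == keys[i]
    graphics::lines(pr$age[sel], pr$rate[sel], col = cols[i], lwd = 2)
    st <- x$strata[paste(x$strata$group, x$strata$sex, sep = ".") == keys[i] &
                     x$strata$person_years > 0, ]
    graphics::points(st$age, pmax(st$deaths / st$person_years * per,
                                  rng[1]), col = cols[i], pch = 1,
                     cex = 0.5)
  }
  graphics::legend("topleft", legend = keys, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
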