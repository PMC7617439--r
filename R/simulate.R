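# Synthetic primary-care cohort generator.
#
# Emulates the structure the downstream analysis assumes: practices with
# data-quality dates, persons with year-of-birth only, registration churn,
# an optional exposure diagnosis, and death dates drawn from a Gompertz
# hazard multiplied by a rate ratio from the diagnosis onward. Because the
# generating hazard is known in closed form, pipeline output can be checked
# against numerically integrated truth.

# Cumulative Gompertz hazard from age 0: H(x) = a/b * (exp(b x) - 1), or a*x
# when b = 0.
gompertz_cumhaz <- function(x, a, b) {
  if (b > 0) a / b * expm1(b * x) else a * x
}

gompertz_inv_cumhaz <- function(u, a, b) {
  if (a <= 0) return(rep(Inf, length(u)))
  if (b > 0) log1p(b * u / a) / b else u / a
}

#' Sample ages at death from a piecewise Gompertz hazard
#'
#' Draws by exact inversion of the cumulative hazard. The hazard is
#' a * exp(b * x) up to `diagnosis_age` and `rate_ratio` times that
#' thereafter, so exposed persons who die before their diagnosis age are
#' sampled from the unexposed portion of the hazard, which is exactly the
#' self-consistency the cohort builder relies on.
#'
#' @param n Number of draws.
#' @param a,b Gompertz parameters: hazard a * exp(b * x) per person-year.
#' @param rate_ratio Hazard multiplier from `diagnosis_age` onward.
#' @param diagnosis_age Age (years) at which the multiplier switches on;
#'   `Inf` (default) means never. Recycled against `n`.
#' @param max_age Ages beyond this are treated as censored and returned `NA`
#'   (default 110).
#' @return Numeric vector of death ages in years; `NA` where no death occurs
#'   before `max_age` (including the a = 0 deathless case).
#' @export
sample_death_age <- function(n, a, b, rate_ratio = 1, diagnosis_age = Inf,
                             max_age = 110) {
  if (!is.finite(a) || a < 0 || !is.finite(b) || b < 0 ||
      !is.finite(rate_ratio) || rate_ratio <= 0)
    stop("non-finite or negative hazard parameters", call. = FALSE)
  if (a == 0) return(rep(NA_real_, n))
  e <- stats::rexp(n)
  xd <- rep_len(diagnosis_age, n)
  h_xd <- ifelse(is.finite(xd), gompertz_cumhaz(xd, a, b), Inf)
  pre <- e <= h_xd
  age <- numeric(n)
  age[pre] <- gompertz_inv_cumhaz(e[pre], a, b)
  if (any(!pre)) {
    age[!pre] <- gompertz_inv_cumhaz(
      h_xd[!pre] + (e[!pre] - h_xd[!pre]) / rate_ratio, a, b)
  }
  age[age > max_age] <- NA_real_
  age
}

#' Remaining life expectancy under a Gompertz hazard
#'
#' Numerically integrates the survival function of the hazard
#' `rate_ratio * a * exp(b x)` conditional on survival to `age`:
#' e(age) = integral of S(x)/S(age) for x > age. This is the closed-form-side
#' truth used to validate the simulated cohorts and the life-table pipeline.
#'
#' @param a,b Gompertz parameters.
#' @param age Conditioning age (default 18).
#' @param rate_ratio Constant hazard multiplier (applied at all ages).
#' @param total If `TRUE` (default) return `age + e(age)`, the total expected
#'   length of life, matching the reporting convention for life tables.
#' @return A single number of years.
#' @export
gompertz_le <- function(a, b, age = 18, rate_ratio = 1, total = TRUE) {
  stopifnot(is.finite(a), a > 0, is.finite(b), b >= 0, rate_ratio > 0)
  aa <- a * rate_ratio
  surv <- function(x) exp(-(gompertz_cumhaz(x, aa, b) -
                              gompertz_cumhaz(age, aa, b)))
  e <- stats::integrate(surv, lower = age, upper = Inf,
                        rel.tol = 1e-10)$value
  if (total) age + e else e
}

#' Generate synthetic primary-care practices
#'
#' @param config A [sim_config()] object.
#' @return A data frame with columns `practice_id`, `quality_date` (the later
#'   of the acceptable-mortality-recording and acceptable-computer-usage
#'   dates, collapsed to one), `data_start`, `data_end`.
#' @export
generate_practices <- function(config) {
  validate_sim_config(config)
  set.seed(practice_seed(config$seed, "practices"))
  n <- config$n_practices
  lo <- as.numeric(config$study_start) - round(10 * DAYS_PER_YEAR)
  hi <- as.numeric(config$study_end)
  data_start <- as.Date(round(stats::runif(n, lo, hi)), origin = "1970-01-01")
  # most practices contribute through the end of the study window
  through <- stats::runif(n) < 0.8
  data_end <- as.Date(ifelse(through, hi,
                             round(stats::runif(n, as.numeric(data_start), hi))),
                      origin = "1970-01-01")
  quality <- pmin_date(
    data_start + round(stats::runif(n, 0, 3 * DAYS_PER_YEAR)),
    as.Date(hi, origin = "1970-01-01"))
  data.frame(
    practice_id = sprintf("p%04d", seq_len(n)),
    quality_date = quality,
    data_start = data_start,
    data_end = data_end,
    stringsAsFactors = FALSE
  )
}

sample_diagnosis_age <- function(n, da) {
  if (da$dist == "uniform") {
    stats::runif(n, da$min, da$max)
  } else {
    pmax(stats::rnorm(n, da$mean, da$sd), 0)
  }
}

#' Generate synthetic persons for a set of practices
#'
#' One block of `persons_per_practice` persons per practice, generated from a
#' per-practice child seed so that output is invariant to practice order.
#' Each person carries sex, birth year (no finer date of birth), a
#' registration window, an optional exposure diagnosis date, an optional
#' death date drawn from the configured Gompertz hazard (rate ratio applied
#' from diagnosis), a Townsend deprivation quintile, and one `cond_<name>`
#' date column per configured baseline condition (recorded at registration).
#'
#' Persons whose sampled death precedes their diagnosis age never become
#' diagnosed (no diagnosis date); persons whose death precedes their drawn
#' registration date have the registration clamped to the death date and so
#' contribute no eligible follow-up.
#'
#' @param practices Output of [generate_practices()].
#' @param config A [sim_config()] object.
#' @return A persons data frame (one row per person).
#' @export
generate_persons <- function(practices, config) {
  validate_sim_config(config)
  if (is.null(practices) || nrow(practices) == 0L)
    stop("`practices` must be a non-empty practice table", call. = FALSE)
  blocks <- vector("list", nrow(practices))
  for (i in seq_len(nrow(practices))) {
    blocks[[i]] <- generate_practice_persons(practices[i, ], config)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

generate_practice_persons <- function(prac, config) {
  set.seed(practice_seed(config$seed, prac$practice_id))
  n <- config$persons_per_practice
  birth_year <- sample(seq.int(config$birth_year_range[1L],
                               config$birth_year_range[2L]),
                       n, replace = TRUE)
  dob <- dob_from_birth_year(birth_year)
  exposed <- stats::runif(n) < config$exposure_prevalence
  p_male <- ifelse(exposed, config$sex_ratio_exposed, config$sex_ratio_unexposed)
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")

  diag_age <- rep(Inf, n)
  diag_age[exposed] <- sample_diagnosis_age(sum(exposed), config$diagnosis_age)
  death_age <- sample_death_age(n, config$gompertz_a, config$gompertz_b,
                                config$exposure_rate_ratio, diag_age)
  # death before the would-be diagnosis: the person is never diagnosed
  undiagnosed <- exposed & !is.na(death_age) & death_age < diag_age
  exposed[undiagnosed] <- FALSE
  diag_age[undiagnosed] <- Inf

  death_date <- dob + round(death_age * DAYS_PER_YEAR)
  diag_date <- as.Date(ifelse(is.finite(diag_age),
                              as.numeric(dob) + round(diag_age * DAYS_PER_YEAR),
                              NA_real_), origin = "1970-01-01")

  lo <- as.numeric(config$study_start) - round(10 * DAYS_PER_YEAR)
  hi <- as.numeric(config$study_end)
  reg <- as.Date(round(stats::runif(n, lo, hi)), origin = "1970-01-01")
  reg <- pmax_date(reg, dob)
  reg <- pmin_date(reg, death_date)   # the dead do not register later

  if (config$registration_churn_rate > 0) {
    wait <- stats::rexp(n, config$registration_churn_rate)
    dereg <- reg + pmax(round(wait * DAYS_PER_YEAR), 1)
    dereg[as.numeric(dereg) > hi] <- NA
  } else {
    dereg <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  }

  townsend <- sample(c(1:5, NA), n, replace = TRUE,
                     prob = c(rep(0.19, 5), 0.05))

  out <- data.frame(
    person_id = sprintf("%s-%05d", prac$practice_id, seq_len(n)),
    practice_id = prac$practice_id,
    sex = sex,
    birth_year = birth_year,
    registration_date = reg,
    deregistration_date = dereg,
    exposed = exposed,
    exposure_diagnosis_date = diag_date,
    death_date = death_date,
    townsend_quintile = townsend,
    stringsAsFactors = FALSE
  )
  for (nm in names(config$condition_prevalences)) {
    p <- config$condition_prevalences[[nm]]
    prob <- ifelse(exposed, p[["exposed"]], p[["unexposed"]])
    has <- stats::runif(n) < prob
    out[[paste0("cond_", nm)]] <-
      as.Date(ifelse(has, as.numeric(reg), NA_real_), origin = "1970-01-01")
  }
  out
}

#' Simulate a complete synthetic primary-care dataset
#'
#' Convenience wrapper running [generate_practices()] then
#' [generate_persons()].
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `persons`, `practices` and the resolved
#'   `config`.
#' @export
simulate_ehr <- function(config = sim_config()) {
  practices <- generate_practices(config)
  persons <- generate_persons(practices, config)
  list(persons = persons, practices = practices, config = config)
}
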