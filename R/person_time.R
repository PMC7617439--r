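# Lexis splitting: follow-up is partitioned at successive birthdays so that
# every day of person-time is attributed to the single year of age attained
# on that day ("time-varying age"). Intervals are half-open [entry, exit);
# the death day belongs to the stratum containing exit - 1 day, which keeps
# a death on a birthday in the interval actually lived.

AGE_MIN <- 18L
AGE_MAX <- 100L

# Vectorised core: entry/exit Date vectors, birth_year integer vector.
# Returns a data.frame(row = member index, age, days).
split_segments <- function(entry, exit, birth_year) {
  if (any(entry >= exit))
    stop("entry must precede exit for every member", call. = FALSE)
  a0 <- attained_age(entry, birth_year)
  a1 <- attained_age(exit - 1L, birth_year)
  nseg <- a1 - a0 + 1L
  idx <- rep.int(seq_along(entry), nseg)
  age <- a0[idx] + (sequence(nseg) - 1L)
  bd_lo <- july1(birth_year[idx] + age)        # birthday opening the age
  bd_hi <- july1(birth_year[idx] + age + 1L)   # next birthday
  seg_start <- pmax_date(entry[idx], bd_lo)
  seg_end <- pmin_date(exit[idx], bd_hi)
  data.frame(row = idx, age = age,
             days = as.integer(seg_end - seg_start))
}

#' Split one member's follow-up into single-year-of-age segments
#'
#' @param entry,exit Entry and exit dates (half-open interval `[entry, exit)`).
#' @param dob Working date of birth (see [dob_from_birth_year()]).
#' @return Data frame with `age` (attained age during the segment) and
#'   `days`; the days sum exactly to `exit - entry`.
#' @export
split_person_time <- function(entry, exit, dob) {
  stopifnot(length(entry) == 1L, length(exit) == 1L, length(dob) == 1L)
  by <- as.integer(format(dob, "%Y"))
  seg <- split_segments(as.Date(entry), as.Date(exit), by)
  seg[c("age", "days")]
}

#' Tabulate deaths and person-years by group, sex and single year of age
#'
#' Splits every member's follow-up at birthdays, pools ages above 100 into
#' the age-100 stratum, and returns the complete (group, sex, age 18-100)
#' grid of death counts and person-years (days / 365.25). This table is the
#' interchange format the rate model and life tables consume.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param persons Persons table supplying sex and birth year.
#' @param age_range Inclusive age span of the strata grid (default 18-100).
#' @return Data frame with columns `group`, `sex`, `age`, `deaths`,
#'   `person_years`.
#' @export
tabulate_strata <- function(cohort, persons, age_range = c(AGE_MIN, AGE_MAX)) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  m <- match(cohort$person_id, persons$person_id)
  if (anyNA(m)) stop("cohort references persons absent from the persons table",
                     call. = FALSE)
  sex <- persons$sex[m]
  by <- as.integer(persons$birth_year[m])

  seg <- split_segments(cohort$entry_date, cohort$exit_date, by)
  seg_age <- pmin(seg$age, age_range[2L])
  if (any(seg_age < age_range[1L]))
    stop("person-time before age ", age_range[1L],
         " encountered; the cohort builder should prevent this", call. = FALSE)

  grp <- cohort$group[seg$row]
  sx <- sex[seg$row]
  keyf <- function(g, s, a) paste(g, s, a, sep = "\r")
  py <- rowsum(seg$days / DAYS_PER_YEAR, keyf(grp, sx, seg_age))

  # death attributed to the stratum containing (exit - 1 day)
  died <- which(cohort$died_in_followup)
  death_age <- pmin(attained_age(cohort$exit_date[died] - 1L, by[died]),
                    age_range[2L])
  dth <- rowsum(rep(1L, length(died)),
                keyf(cohort$group[died], sex[died], death_age))

  grid <- expand.grid(
    age = seq.int(age_range[1L], age_range[2L]),
    sex = sort(unique(sex)),
    group = sort(unique(cohort$group)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("group", "sex", "age")]
  k <- keyf(grid$group, grid$sex, grid$age)
  grid$deaths <- as.integer(dth[match(k, rownames(dth))])
  grid$deaths[is.na(grid$deaths)] <- 0L
  grid$person_years <- as.numeric(py[match(k, rownames(py))])
  grid$person_years[is.na(grid$person_years)] <- 0
  rownames(grid) <- NULL
  grid
}

#' Crude mortality rates with exact Poisson confidence intervals
#'
#' Rates are deaths / person-years times `per` (default per 100 000
#' person-years). The confidence interval uses the exact relationship
#' between the Poisson count and chi-square quantiles: with `d` deaths the
#' lower bound is `qchisq(alpha/2, 2d)/2` (zero when `d = 0`) and the upper
#' `qchisq(1 - alpha/2, 2(d+1))/2`, divided by person-years.
#'
#' @param strata Strata table from [tabulate_strata()].
#' @param per Rate multiplier (default 1e5).
#' @param level Confidence level (default 0.95).
#' @param age_breaks Optional vector of left-closed age-band cut points
#'   (e.g. `c(18, 25, 35, 45, 55, 65, 101)`) to pool single-year strata into
#'   bands before computing rates.
#' @param warn_zero Warn when strata with zero person-years are present
#'   (default `TRUE`; the pipeline disables it for sparse per-age tables).
#' @return Data frame of rates and interval bounds; strata with zero
#'   person-years get `NA` rates.
#' @export
crude_rates <- function(strata, per = 1e5, level = 0.95, age_breaks = NULL,
                        warn_zero = TRUE) {
  df <- strata
  if (!is.null(age_breaks)) {
    band <- cut(df$age, breaks = age_breaks, right = FALSE,
                include.lowest = TRUE)
    key <- paste(df$group, df$sex, band, sep = "\r")
    dth <- rowsum(df$deaths, key)
    py <- rowsum(df$person_years, key)
    parts <- do.call(rbind, strsplit(rownames(dth), "\r", fixed = TRUE))
    df <- data.frame(group = parts[, 1], sex = parts[, 2],
                     age_band = parts[, 3], deaths = as.integer(dth),
                     person_years = as.numeric(py), stringsAsFactors = FALSE)
    df <- df[order(df$group, df$sex, df$age_band), , drop = FALSE]
    rownames(df) <- NULL
  }
  alpha <- 1 - level
  d <- df$deaths
  py <- df$person_years
  rate <- ifelse(py > 0, d / py * per, NA_real_)
  lo <- ifelse(py > 0,
               ifelse(d == 0, 0, stats::qchisq(alpha / 2, 2 * d) / 2) / py * per,
               NA_real_)
  hi <- ifelse(py > 0,
               stats::qchisq(1 - alpha / 2, 2 * (d + 1)) / 2 / py * per,
               NA_real_)
  if (warn_zero && any(py == 0))
    warning("strata with zero person-years have undefined rates (NA)",
            call. = FALSE)
  df$rate <- rate
  df$ci_low <- lo
  df$ci_high <- hi
  df
}
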