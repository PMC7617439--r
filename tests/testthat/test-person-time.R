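test_that("follow-up is split at birthdays with exact day counts", {
  # born 1980 (DOB 1980-07-01): [2000-01-01, 2001-01-01) spans the 20th
  # birthday; 2000 is a leap year
  seg <- split_person_time(as.Date("2000-01-01"), as.Date("2001-01-01"),
                           dob_from_birth_year(1980))
  expect_equal(seg$age, c(19L, 20L))
  expect_equal(seg$days, c(182L, 184L))

  # a window inside one birthday interval stays a single segment
  seg2 <- split_person_time(as.Date("2000-08-01"), as.Date("2001-03-01"),
                            dob_from_birth_year(1980))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$age, 20L)
  expect_equal(seg2$days, as.integer(as.Date("2001-03-01") -
                                       as.Date("2000-08-01")))

  expect_error(split_person_time(as.Date("2001-01-01"), as.Date("2001-01-01"),
                                 dob_from_birth_year(1980)),
               "entry must precede exit")
})

test_that("segment days always sum to the raw window length", {
  set.seed(5)
  n <- 1000
  by <- sample(1930:1990, n, replace = TRUE)
  entry <- as.Date("2000-01-01") + sample.int(5000, n, replace = TRUE)
  exit <- entry + sample.int(6000, n, replace = TRUE)
  for (i in seq_len(n)) {
    seg <- split_person_time(entry[i], exit[i], dob_from_birth_year(by[i]))
    expect_identical(sum(seg$days), as.integer(exit[i] - entry[i]))
  }
})

test_that("strata tabulation conserves person-time and deaths", {
  # one member straddling one birthday, no death
  persons <- fixture_person("a", birth_year = 1970)
  cohort <- data.frame(person_id = "a", group = "comparison",
                       matched_set_id = NA, entry_date = as.Date("2001-07-01"),
                       exit_date = as.Date("2003-07-01"),
                       died_in_followup = FALSE, stringsAsFactors = FALSE)
  st <- tabulate_strata(cohort, persons)
  expect_equal(sum(st$person_years), 730 / 365.25)
  expect_equal(sum(st$deaths), 0L)
  expect_equal(sort(st$age[st$person_years > 0]), c(31L, 32L))

  # cohort level: conservation to 1e-9 years and death-count conservation,
  # and invariance of the tabulation to row order
  cfg <- sim_config(n_practices = 6, persons_per_practice = 800,
                    exposure_prevalence = 0.1,
                    birth_year_range = c(1925, 1980), seed = 23)
  sim <- simulate_ehr(cfg)
  cb <- build_cohort(sim$persons, sim$practices, match_ratio = 5)
  st2 <- tabulate_strata(cb$cohort, sim$persons)
  direct <- sum(as.numeric(cb$cohort$exit_date - cb$cohort$entry_date)) / 365.25
  expect_lt(abs(sum(st2$person_years) - direct), 1e-9)
  expect_equal(sum(st2$deaths), sum(cb$cohort$died_in_followup))
  expect_true(all(st2$deaths[st2$person_years == 0] == 0))
  shuf <- cb$cohort[sample.int(nrow(cb$cohort)), ]
  expect_equal(tabulate_strata(shuf, sim$persons), st2)
})

test_that("deaths land in the stratum lived during the final day", {
  persons <- fixture_person("a", birth_year = 1950)
  # death on the 60th birthday: the last day lived is age 59
  cohort <- data.frame(person_id = "a", group = "exposed",
                       matched_set_id = NA, entry_date = as.Date("2009-01-01"),
                       exit_date = as.Date("2010-07-01"),
                       died_in_followup = TRUE, stringsAsFactors = FALSE)
  st <- tabulate_strata(cohort, persons)
  expect_equal(st$deaths[st$age == 59], 1L)
  expect_equal(sum(st$deaths), 1L)
})

test_that("ages above the cap pool into the terminal stratum", {
  persons <- fixture_person("a", birth_year = 1900)
  cohort <- data.frame(person_id = "a", group = "comparison",
                       matched_set_id = NA, entry_date = as.Date("2000-07-01"),
                       exit_date = as.Date("2003-07-01"),
                       died_in_followup = TRUE, stringsAsFactors = FALSE)
  st <- tabulate_strata(cohort, persons)  # ages 100-102 all pooled at 100
  expect_equal(st$person_years[st$age == 100],
               as.numeric(as.Date("2003-07-01") - as.Date("2000-07-01")) / 365.25)
  expect_equal(st$deaths[st$age == 100], 1L)
})

test_that("pooled death rate matches a constant generating hazard", {
  # constant hazard via b = 0: pooled deaths/person-years within 3 Poisson SEs
  cfg <- sim_config(n_practices = 5, persons_per_practice = 3000,
                    exposure_prevalence = 0, gompertz_a = 0.01, gompertz_b = 0,
                    birth_year_range = c(1940, 1980),
                    registration_churn_rate = 0, seed = 29)
  sim <- simulate_ehr(cfg)
  cb <- build_cohort(sim$persons, sim$practices, match_ratio = 0)
  st <- tabulate_strata(cb$cohort, sim$persons)
  d <- sum(st$deaths); py <- sum(st$person_years)
  expect_lt(abs(d / py - 0.01), 3 * sqrt(d) / py)
})

test_that("crude rates use the exact Poisson interval", {
  strata <- data.frame(group = "exposed", sex = "male", age = c(40L, 41L),
                       deaths = c(2L, 10L), person_years = c(1000, 10000))
  cr <- crude_rates(strata)
  expect_equal(cr$rate[1], 200)  # 2 / 1000 py per 1e5

  # 10 deaths / 10 000 py: chi-square bounds equal CDF root-finding bounds
  oracle <- poisson_ci_bruteforce(10) / 10000 * 1e5
  expect_equal(cr$ci_low[2], oracle[1], tolerance = 1e-7)
  expect_equal(cr$ci_high[2], oracle[2], tolerance = 1e-7)

  # zero deaths: rate 0, lower bound 0
  s0 <- data.frame(group = "g", sex = "male", age = 50L, deaths = 0L,
                   person_years = 100)
  cr0 <- crude_rates(s0)
  expect_equal(cr0$rate, 0)
  expect_equal(cr0$ci_low, 0)

  # zero person-years: NA with a warning
  s1 <- data.frame(group = "g", sex = "male", age = 50L, deaths = 0L,
                   person_years = 0)
  expect_warning(crn <- crude_rates(s1), "zero person-years")
  expect_true(is.na(crn$rate))

  # age-band pooling preserves totals
  strata2 <- expand.grid(group = "exposed", sex = "male", age = 18:100,
                         stringsAsFactors = FALSE)
  set.seed(1)
  strata2$deaths <- rpois(nrow(strata2), 3)
  strata2$person_years <- runif(nrow(strata2), 500, 1500)
  bands <- crude_rates(strata2, age_breaks = c(18, 45, 101))
  expect_equal(sum(bands$deaths), sum(strata2$deaths))
  expect_equal(sum(bands$person_years), sum(strata2$person_years))
})
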