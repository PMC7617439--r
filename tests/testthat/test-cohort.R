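practices <- fixture_practices()

test_that("entry date is the latest candidate date, floored at age 18", {
  pr <- practices[1, ]
  # all candidate dates coincide
  p <- fixture_person(birth_year = 1960, registration_date = "1997-07-01")
  pr_eq <- pr; pr_eq$quality_date <- as.Date("1998-01-01")
  pr_eq$data_start <- as.Date("1998-01-01")
  p$registration_date <- as.Date("1997-07-01") # +6m = 1998-01-01
  expect_equal(entry_date(p, pr_eq, study_start = as.Date("1998-01-01")),
               as.Date("1998-01-01"))

  # diagnosis is the maximum for the exposed arm
  p2 <- fixture_person(birth_year = 1960, registration_date = "1999-01-01",
                       exposed = TRUE,
                       exposure_diagnosis_date = "2003-05-10")
  expect_equal(entry_date(p2, pr, exposed = TRUE), as.Date("2003-05-10"))
  # and is ignored for the comparison rules
  expect_equal(entry_date(p2, pr, exposed = FALSE), as.Date("2000-01-01"))

  # registration + 6 calendar months binds for a late registrant
  p3 <- fixture_person(birth_year = 1960, registration_date = "2005-03-01")
  expect_equal(entry_date(p3, pr), as.Date("2005-09-01"))

  # the 18th birthday floors the entry of a young person
  p4 <- fixture_person(birth_year = 1990, registration_date = "1999-01-01")
  expect_equal(entry_date(p4, pr), as.Date("2008-07-01"))
})

test_that("calendar-month addition clamps day-of-month overflow", {
  expect_equal(add_months(as.Date("2005-03-01"), 6), as.Date("2005-09-01"))
  expect_equal(add_months(as.Date("2003-08-31"), 6), as.Date("2004-02-29"))
  expect_equal(add_months(as.Date("2001-08-31"), 6), as.Date("2002-02-28"))
  expect_equal(add_months(as.Date("1999-10-15"), 6), as.Date("2000-04-15"))
})

test_that("exit date is the earliest candidate and flags deaths", {
  pr <- practices[1, ]
  p <- fixture_person()
  expect_equal(exit_date(p, pr), as.Date("2019-01-16"))  # study end binds
  p$death_date <- as.Date("2010-04-04")
  expect_equal(exit_date(p, pr), as.Date("2010-04-04"))
  p$deregistration_date <- as.Date("2005-01-01")
  expect_equal(exit_date(p, pr), as.Date("2005-01-01"))
})

test_that("matching selects the whole risk set when it is exactly the ratio", {
  persons <- fixture_matching_pool(n_pool = 10)
  for (seed in c(1, 99)) {
    cb <- build_cohort(persons, practices, match_ratio = 10, match_seed = seed)
    cmp <- sort(cb$cohort$person_id[cb$cohort$group == "comparison"])
    expect_equal(cmp, sprintf("c%02d", 1:10))
  }
})

test_that("a risk set below the strict ratio excludes the exposed member", {
  persons <- fixture_matching_pool(n_pool = 7)
  cb <- build_cohort(persons, practices, match_ratio = 10)
  expect_equal(cb$report$n_excluded_insufficient_matches, 1L)
  expect_equal(cb$report$n_included_exposed, 0L)
  expect_equal(nrow(cb$cohort), 0L)
  # a lower min_matches admits the set with all available comparators
  cb2 <- build_cohort(persons, practices, match_ratio = 10, min_matches = 5)
  expect_equal(cb2$report$n_included_exposed, 1L)
  expect_equal(sum(cb2$cohort$group == "comparison"), 7L)
})

test_that("comparators are sampled uniformly from the risk set", {
  persons <- fixture_matching_pool(n_pool = 20)
  counts <- setNames(numeric(20), sprintf("c%02d", 1:20))
  for (r in 1:2000) {
    cb <- build_cohort(persons, practices, match_ratio = 10, match_seed = r)
    sel <- cb$cohort$person_id[cb$cohort$group == "comparison"]
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / 2000
  expect_true(all(abs(freq - 0.5) < 0.04))
})

test_that("matched sets agree on practice, sex, birth year and entry date", {
  cfg <- sim_config(n_practices = 8, persons_per_practice = 1200,
                    exposure_prevalence = 0.03,
                    birth_year_range = c(1955, 1975), seed = 13)
  sim <- simulate_ehr(cfg)
  cb <- build_cohort(sim$persons, sim$practices, match_ratio = 5,
                     match_seed = 3)
  expect_gt(cb$report$n_included_exposed, 20)
  co <- cb$cohort
  m <- match(co$person_id, sim$persons$person_id)
  key <- paste(sim$persons$practice_id[m], sim$persons$sex[m],
               sim$persons$birth_year[m], co$entry_date)
  per_set <- tapply(key, co$matched_set_id, function(k) length(unique(k)))
  expect_true(all(per_set == 1))
  size <- table(co$matched_set_id)
  expect_true(all(size == 6))  # 1 exposed + 5 comparators

  # no comparator is exposed on or before entry; exposed entry >= diagnosis
  diag <- sim$persons$exposure_diagnosis_date[m]
  cmp <- co$group == "comparison"
  expect_true(all(is.na(diag[cmp]) | diag[cmp] > co$entry_date[cmp]))
  expo <- co$group == "exposed"
  expect_true(all(co$entry_date[expo] >= diag[expo]))

  # global without-replacement: a person appears at most once as comparator
  expect_false(any(duplicated(co$person_id[cmp])))

  # set composition is reproducible under the same matching seed
  cb2 <- build_cohort(sim$persons, sim$practices, match_ratio = 5,
                      match_seed = 3)
  expect_identical(cb$cohort, cb2$cohort)
})

test_that("later-diagnosed comparators are censored at their diagnosis", {
  persons <- fixture_matching_pool(n_pool = 10)
  persons$exposed[5] <- TRUE  # c04 diagnosed during follow-up
  persons$exposure_diagnosis_date[5] <- as.Date("2010-03-03")
  cb <- build_cohort(persons, practices, match_ratio = 10)
  cmp_row <- cb$cohort[cb$cohort$person_id == "c04" &
                         cb$cohort$group == "comparison", ]
  expect_equal(cmp_row$exit_date, as.Date("2010-03-03"))
  expect_false(cmp_row$died_in_followup)
  # under global without-replacement every other pool member is already used,
  # so c04 cannot head their own set and is excluded as insufficient
  expect_equal(cb$report$n_excluded_insufficient_matches, 1L)
  # allowing reuse across sets (and accepting 9 comparators) lets the
  # later-diagnosed person enter the exposed arm from their diagnosis date
  cb_r <- build_cohort(persons, practices, match_ratio = 10, min_matches = 9,
                       replace_across_sets = TRUE)
  expo_row <- cb_r$cohort[cb_r$cohort$person_id == "c04" &
                            cb_r$cohort$group == "exposed", ]
  expect_equal(expo_row$entry_date, as.Date("2010-03-03"))
  # policy off: comparator keeps their full window
  cb2 <- build_cohort(persons, practices, match_ratio = 10,
                      censor_comparators_at_diagnosis = FALSE)
  cmp2 <- cb2$cohort[cb2$cohort$person_id == "c04" &
                       cb2$cohort$group == "comparison", ]
  expect_equal(cmp2$exit_date, as.Date("2019-01-16"))
})

test_that("build report arithmetic and degenerate inputs behave", {
  # zero exposed persons: empty cohort, zero report
  pool <- fixture_matching_pool(n_pool = 5)
  pool$exposed <- FALSE
  pool$exposure_diagnosis_date <- as.Date(NA)
  cb <- build_cohort(pool, practices)
  expect_equal(nrow(cb$cohort), 0L)
  expect_equal(cb$report$n_identified, 0L)

  # exposed person with no diagnosis date is flagged, not an exception
  pool2 <- fixture_matching_pool(n_pool = 10)
  pool2$exposure_diagnosis_date[1] <- as.Date(NA)
  cb2 <- build_cohort(pool2, practices)
  expect_equal(cb2$report$n_excluded_no_date, 1L)
  expect_equal(cb2$report$n_included_exposed, 0L)

  # death on the entry date: zero follow-up, diagnostics tally
  pool3 <- fixture_matching_pool(n_pool = 10)
  pool3$death_date[1] <- as.Date("2005-06-15")  # equals diagnosis/entry
  cb3 <- build_cohort(pool3, practices)
  expect_equal(cb3$report$n_zero_followup, 1L)
  expect_equal(cb3$report$n_identified, 0L)

  # report identity on a generated input
  cfg <- sim_config(n_practices = 6, persons_per_practice = 600,
                    exposure_prevalence = 0.05, seed = 17)
  sim <- simulate_ehr(cfg)
  cb4 <- build_cohort(sim$persons, sim$practices, match_ratio = 10)
  r <- cb4$report
  expect_equal(r$n_included_exposed,
               r$n_identified - r$n_excluded_no_date -
                 r$n_excluded_insufficient_matches)
  expect_equal(r$n_included_comparison, 10L * r$n_included_exposed)
  expect_error(build_report(5, 4, 3), "exceed")
})

test_that("schema violations are reported as input errors", {
  expect_error(build_cohort(data.frame(person_id = "x"), practices),
               "missing columns")
  p <- fixture_person(practice_id = "nonexistent")
  expect_error(build_cohort(p, practices), "unknown practice")
})

test_that("mortality and baseline summaries compute printed-style figures", {
  cfg <- sim_config(n_practices = 6, persons_per_practice = 800,
                    exposure_prevalence = 0.4,
                    birth_year_range = c(1940, 1970),
                    condition_prevalences = list(
                      flag = c(exposed = 0.10, unexposed = 0.05)),
                    seed = 31)
  sim <- simulate_ehr(cfg)
  cb <- build_cohort(sim$persons, sim$practices, match_ratio = 0)
  mt <- summarize_mortality(cb$cohort, sim$persons)
  expect_equal(mt$pct_died, percentage(mt$deaths, mt$n))
  expect_true(all(mt$deaths <= mt$n))

  bl <- summarize_baseline(cb$cohort, sim$persons)
  expect_true(all(bl$demographics$median_age_entry >= 18))
  cond <- bl$conditions
  # generated difference 5 percentage points, binomial noise a fraction of 1
  n_arm <- min(tapply(cb$cohort$person_id, cb$cohort$group, length))
  expect_gt(n_arm, 500)
  pooled <- tapply(cond$difference, cond$condition, mean)
  expect_lt(abs(pooled[["flag"]] - 5), 2.5)
})

test_that("degenerate baseline inputs give exact summaries", {
  # every member enters exactly at their 18th birthday
  persons <- do.call(rbind, lapply(1:6, function(i) {
    fixture_person(sprintf("p%d", i), birth_year = 1985,
                   registration_date = "1999-01-01",
                   exposed = i <= 3,
                   exposure_diagnosis_date = if (i <= 3) "2000-01-01" else NA)
  }))
  persons$cond_nothing <- as.Date(NA)
  cb <- build_cohort(persons, fixture_practices(), match_ratio = 0)
  # entry = 18th birthday 2003-07-01 for all (diagnosis earlier)
  expect_true(all(cb$cohort$entry_date == as.Date("2003-07-01")))
  bl <- summarize_baseline(cb$cohort, persons)
  expect_true(all(bl$demographics$median_age_entry == 18))
  expect_true(all(bl$demographics$age_entry_q3 -
                    bl$demographics$age_entry_q1 == 0))
  expect_true(all(bl$conditions$pct_exposed == 0))
  expect_true(all(bl$conditions$difference == 0))
})
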