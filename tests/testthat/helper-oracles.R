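# Independent oracles and small hand-built fixtures used across tests.

# Naive period life-table recursion, written as a straight element-by-element
# loop, independent of build_life_table()'s vectorised implementation.
naive_life_table <- function(m, ages = 18:100, a = 0.5, radix = 1e5) {
  n <- length(m)
  q <- numeric(n); l <- numeric(n); d <- numeric(n); L <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- if (i == n) 1 else m[i] / (1 + (1 - a) * m[i])
    l[i] <- if (i == 1) radix else l[i - 1] * (1 - q[i - 1])
    d[i] <- l[i] * q[i]
  }
  for (i in seq_len(n)) {
    L[i] <- if (i == n) {
      if (l[i] > 0) l[i] / m[i] else 0
    } else l[i] - d[i] + a * d[i]
  }
  Tx <- numeric(n); e <- numeric(n)
  for (i in rev(seq_len(n))) Tx[i] <- L[i] + if (i == n) 0 else Tx[i + 1]
  for (i in seq_len(n)) e[i] <- if (l[i] > 0) Tx[i] / l[i] else 0
  list(age = ages, m = m, q = q, l = l, d = d, L = L, T = Tx, e = e)
}

# Exact Poisson CI bounds by brute-force root finding on the Poisson CDF,
# independent of the chi-square shortcut used by crude_rates().
poisson_ci_bruteforce <- function(d, level = 0.95) {
  alpha <- 1 - level
  upper <- stats::uniroot(function(mu) ppois(d, mu) - alpha / 2,
                          c(d + 1e-9, 20 * d + 50), tol = 1e-10)$root
  lower <- if (d == 0) 0 else
    stats::uniroot(function(mu) 1 - ppois(d - 1, mu) - alpha / 2,
                   c(1e-12, d * 5 + 10), tol = 1e-10)$root
  c(lower, upper)
}

# Hand-built two-practice fixture with fully controlled dates.
fixture_practices <- function() {
  data.frame(
    practice_id = c("pA", "pB"),
    quality_date = as.Date(c("1998-06-01", "2001-03-15")),
    data_start = as.Date(c("1997-01-01", "1999-06-01")),
    data_end = as.Date(c("2020-01-01", "2015-06-30")),
    stringsAsFactors = FALSE
  )
}

fixture_person <- function(person_id = "x1", practice_id = "pA",
                           sex = "male", birth_year = 1980L,
                           registration_date = "1999-01-01",
                           deregistration_date = NA,
                           exposed = FALSE,
                           exposure_diagnosis_date = NA,
                           death_date = NA) {
  data.frame(
    person_id = person_id, practice_id = practice_id, sex = sex,
    birth_year = birth_year,
    registration_date = as.Date(registration_date),
    deregistration_date = as.Date(deregistration_date),
    exposed = exposed,
    exposure_diagnosis_date = as.Date(exposure_diagnosis_date),
    death_date = as.Date(death_date),
    stringsAsFactors = FALSE
  )
}

# A practice cell with one exposed person and `n_pool` matchable unexposed
# persons sharing practice/sex/birth year and wide-open windows.
fixture_matching_pool <- function(n_pool = 20L, birth_year = 1970L,
                                  diagnosis_date = "2005-06-15") {
  exposed <- fixture_person("e1", exposed = TRUE, birth_year = birth_year,
                            exposure_diagnosis_date = diagnosis_date)
  pool <- do.call(rbind, lapply(seq_len(n_pool), function(i) {
    fixture_person(sprintf("c%02d", i), birth_year = birth_year)
  }))
  rbind(exposed, pool)
}
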