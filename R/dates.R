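# Calendar helpers shared by the generator, cohort builder and Lexis splitter.
# All person-level age arithmetic uses the 1-July date-of-birth convention:
# only the year of birth is carried, so every working DOB is 1 July of that
# year (at most a 6-month error either way).

DAYS_PER_YEAR <- 365.25

#' Working date of birth from a year of birth
#'
#' Records carry only the year of birth, so a working date of birth is needed
#' for age arithmetic. The convention is 1 July of the birth year (the
#' mid-year date), giving at most a six-month error in either direction.
#'
#' @param birth_year Integer vector of birth years.
#' @param month,day Components of the working birthday (defaults 1 July).
#' @return A `Date` vector.
#' @export
dob_from_birth_year <- function(birth_year, month = 7L, day = 1L) {
  as.Date(sprintf("%d-%02d-%02d", as.integer(birth_year), month, day))
}

# 1 July of each year, vectorised via a small per-call lookup table so that
# million-row splits do not pay for repeated string parsing.
july1 <- function(year) {
  year <- as.integer(year)
  if (length(year) == 0L) return(as.Date(integer(0), origin = "1970-01-01"))
  rng <- range(year)
  yrs <- seq.int(rng[1L], rng[2L])
  tab <- as.Date(paste0(yrs, "-07-01"))
  tab[year - rng[1L] + 1L]
}

# Attained age (completed years) at `date` for someone born `birth_year`
# under the 1-July DOB convention.
attained_age <- function(date, birth_year) {
  y <- as.integer(format(date, "%Y"))
  y - as.integer(birth_year) - (date < july1(y))
}

#' Add calendar months to a date
#'
#' Calendar-month addition with day-of-month overflow clamped to the end of
#' the target month (e.g. 2005-03-01 + 6 months is 2005-09-01; 2003-08-31 +
#' 6 months is 2004-02-29). Used for the "registration date + 6 months"
#' eligibility rule.
#'
#' @param date A `Date` vector.
#' @param n Integer number of months to add (scalar).
#' @return A `Date` vector.
#' @export
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + as.integer(n)
  y <- m0 %/% 12L
  m <- m0 %% 12L
  # clamp day to the length of the target month
  first <- as.Date(sprintf("%d-%02d-01", y + 1900L, m + 1L))
  next_first <- as.Date(sprintf("%d-%02d-01", (y + (m == 11L)) + 1900L,
                                ((m + 1L) %% 12L) + 1L))
  last_day <- as.integer(next_first - first)
  first + pmin(lt$mday, last_day) - 1L
}

# Difference in fractional years, days / 365.25.
years_between <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}

# pmin/pmax over Date columns where NA means "no such event": NA dates are
# treated as +Inf (for minima) or -Inf (for maxima).
pmin_date <- function(...) {
  args <- lapply(list(...), function(d) {
    x <- as.numeric(d)
    x[is.na(x)] <- Inf
    x
  })
  out <- do.call(pmin, args)
  out[!is.finite(out)] <- NA_real_
  as.Date(out, origin = "1970-01-01")
}

pmax_date <- function(...) {
  args <- lapply(list(...), function(d) {
    x <- as.numeric(d)
    x[is.na(x)] <- -Inf
    x
  })
  out <- do.call(pmax, args)
  out[!is.finite(out)] <- NA_real_
  as.Date(out, origin = "1970-01-01")
}
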