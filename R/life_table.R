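# Period life table in the complete (single-year) ONS style, starting from
# adult ages. Central rates m_x are converted to conditional death
# probabilities q_x through the fraction-of-interval-lived constant a
# (default 0.5: deaths fall on average halfway through the year of age),
# survivors l_x descend from a radix of 100 000 at the starting age, and the
# open terminal interval is closed with L = l / m (constant-hazard closure).

#' Build a period life table from age-specific mortality rates
#'
#' @param m Central mortality rates per person-year, one per age in `ages`,
#'   finite and non-negative; the terminal rate must be positive whenever
#'   any survivors reach the terminal age.
#' @param ages Integer ages the rates refer to (default 18 to 100).
#' @param a Fraction of the year of age lived by those dying in it
#'   (default 0.5).
#' @param radix Survivors at the first age (default 100 000); all reported
#'   quantities are invariant to it.
#' @return A data frame of class `life_table` with columns `age`, `m`, `q`,
#'   `l`, `d`, `L`, `T`, `e` and attributes `a`, `radix`, `start_age`.
#' @export
build_life_table <- function(m, ages = 18:100, a = 0.5, radix = 1e5) {
  n <- length(ages)
  if (length(m) != n)
    stop("`m` must supply one rate per age", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("all mortality rates must be finite and non-negative", call. = FALSE)
  if (a < 0 || a > 1) stop("`a` must lie in [0, 1]", call. = FALSE)

  # cap at 1: for a < 1 the conversion exceeds 1 once m > 1/(a*(1-a))-ish,
  # which legitimately occurs in extreme bootstrap draws
  q <- pmin(m / (1 + (1 - a) * m), 1)
  q[n] <- 1
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- c(l[-1] + a * d[-n], 0)
  if (l[n] > 0) {
    if (m[n] <= 0)
      stop("terminal rate must be positive while survivors remain",
           call. = FALSE)
    L[n] <- l[n] / m[n]
  }
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  structure(
    data.frame(age = ages, m = m, q = q, l = l, d = d, L = L, T = Tx, e = e),
    class = c("life_table", "data.frame"),
    a = a, radix = radix, start_age = ages[1L])
}

#' Total expected length of life from a life table
#'
#' The reporting convention adds the starting age back to the remaining
#' life expectancy at that age: a table starting at 18 with e(18) = 55.26
#' reports a total life expectancy of 73.26 years.
#'
#' @param lt A [build_life_table()] object.
#' @return Total life expectancy in years.
#' @export
total_life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  attr(lt, "start_age") + lt$e[1L]
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Period life table, ages %d-%d (a = %g, radix = %g)\n",
              x$age[1L], x$age[nrow(x)], attr(x, "a"), attr(x, "radix")))
  cat(sprintf("Total life expectancy at %d: %.2f years\n",
              attr(x, "start_age"), total_life_expectancy(x)))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = digits,
                   row.names = FALSE)
  cat("  ...\n")
  invisible(x)
}

#' Years of life lost: comparison minus exposed life expectancy
#'
#' Point estimate is the difference of the two total life expectancies; the
#' confidence interval comes from the paired simulation draws carried by the
#' two [le_interval()] estimates (never from subtracting interval
#' endpoints).
#'
#' @param le_exposed,le_comparison `le_estimate` objects for the same sex.
#' @param level Confidence level; defaults to the level of the inputs.
#' @return Object of class `yll_estimate`.
#' @export
years_of_life_lost <- function(le_exposed, le_comparison, level = NULL) {
  stopifnot(inherits(le_exposed, "le_estimate"),
            inherits(le_comparison, "le_estimate"))
  if (!identical(le_exposed$sex, le_comparison$sex))
    stop("years of life lost compares the two groups within one sex; got '",
         le_exposed$sex, "' vs '", le_comparison$sex, "'", call. = FALSE)
  if (is.null(level)) level <- le_exposed$level
  point <- le_comparison$total_life_expectancy -
    le_exposed$total_life_expectancy
  nd <- min(length(le_exposed$draws), length(le_comparison$draws))
  diffs <- le_comparison$draws[seq_len(nd)] - le_exposed$draws[seq_len(nd)]
  ci <- unname(stats::quantile(diffs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(list(sex = le_exposed$sex, yll = point,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 draws = diffs), class = "yll_estimate")
}

#' @export
print.yll_estimate <- function(x, ...) {
  cat(sprintf("Years of life lost (%s): %.2f (%d%% CI: %.2f-%.2f)\n",
              x$sex, x$yll, round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}
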