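# Descriptive reporting: participant counts, baseline condition prevalence,
# deaths and crude percentages. Rounding happens here and only here.

#' Round half away from zero
#'
#' Reporting convention for printed percentages: 0.825 rounds to 0.83, not
#' the IEEE banker's 0.82.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total
#'
#' `100 * n / total`, rounded half-up to `digits` decimals — the convention
#' used for all printed proportions (deaths, diagnosis prevalence, baseline
#' conditions).
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage.
#' @export
percentage <- function(n, total, digits = 2L) {
  round_half_up(100 * n / total, digits)
}

cohort_sex <- function(cohort, persons) {
  if ("sex" %in% names(cohort)) return(cohort$sex)
  persons$sex[match(cohort$person_id, persons$person_id)]
}

#' Deaths and crude death percentages by group and sex
#'
#' @param cohort Cohort table from [build_cohort()]; if it lacks a `sex`
#'   column, `persons` supplies it.
#' @param persons Optional persons table for the sex lookup.
#' @return Data frame with `group`, `sex`, `n`, `deaths`, `pct_died`
#'   (half-up, 2 decimals).
#' @export
summarize_mortality <- function(cohort, persons = NULL) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  sex <- cohort_sex(cohort, persons)
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(cohort)), deaths = as.integer(cohort$died_in_followup)),
    by = list(group = cohort$group, sex = sex), FUN = sum)
  agg$pct_died <- percentage(agg$deaths, agg$n)
  agg[order(agg$group, agg$sex), , drop = FALSE]
}

#' Baseline characteristics by group and sex
#'
#' For each group and sex: N, median and inter-quartile range of age at
#' entry, the percentage entering aged 18-24, the percentage entering after
#' a cutoff calendar year, and the baseline prevalence of every `cond_*`
#' condition (first-record date on or before the entry date) together with
#' the exposed-minus-comparison difference.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param persons Persons table (for birth year and condition dates).
#' @param entry_year_cutoff Calendar year; the report includes the share of
#'   members entering in a later year (default 2010).
#' @return A list of class `baseline_summary` with elements `demographics`
#'   and `conditions` (both data frames).
#' @export
summarize_baseline <- function(cohort, persons, entry_year_cutoff = 2010L) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  m <- match(cohort$person_id, persons$person_id)
  dob <- dob_from_birth_year(persons$birth_year[m])
  age_entry <- years_between(dob, cohort$entry_date)
  entry_year <- as.integer(format(cohort$entry_date, "%Y"))
  sex <- persons$sex[m]

  demo_list <- list()
  for (g in sort(unique(cohort$group))) {
    for (s in sort(unique(sex))) {
      sel <- cohort$group == g & sex == s
      if (!any(sel)) next
      q <- stats::quantile(age_entry[sel], c(0.25, 0.5, 0.75), names = FALSE)
      demo_list[[length(demo_list) + 1L]] <- data.frame(
        group = g, sex = s, n = sum(sel),
        median_age_entry = round_half_up(q[2], 2L),
        age_entry_q1 = round_half_up(q[1], 2L),
        age_entry_q3 = round_half_up(q[3], 2L),
        pct_age_18_24 = percentage(sum(age_entry[sel] < 25), sum(sel)),
        pct_entry_after_cutoff =
          percentage(sum(entry_year[sel] > entry_year_cutoff), sum(sel)),
        stringsAsFactors = FALSE
      )
    }
  }
  demographics <- do.call(rbind, demo_list)

  cond_cols <- grep("^cond_", names(persons), value = TRUE)
  cond_list <- list()
  for (cc in cond_cols) {
    first <- persons[[cc]][m]
    at_baseline <- !is.na(first) & first <= cohort$entry_date
    for (s in sort(unique(sex))) {
      p_by_group <- vapply(c("exposed", "comparison"), function(g) {
        sel <- cohort$group == g & sex == s
        if (!any(sel)) return(NA_real_)
        percentage(sum(at_baseline[sel]), sum(sel))
      }, numeric(1))
      cond_list[[length(cond_list) + 1L]] <- data.frame(
        condition = sub("^cond_", "", cc), sex = s,
        pct_exposed = p_by_group[["exposed"]],
        pct_comparison = p_by_group[["comparison"]],
        difference = p_by_group[["exposed"]] - p_by_group[["comparison"]],
        stringsAsFactors = FALSE
      )
    }
  }
  conditions <- if (length(cond_list)) do.call(rbind, cond_list) else
    data.frame(condition = character(0), sex = character(0),
               pct_exposed = numeric(0), pct_comparison = numeric(0),
               difference = numeric(0))

  structure(list(demographics = demographics, conditions = conditions,
                 entry_year_cutoff = entry_year_cutoff),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("Baseline characteristics by group and sex\n\n")
  print(x$demographics, row.names = FALSE)
  if (nrow(x$conditions)) {
    cat("\nPre-existing conditions at baseline (%):\n")
    print(x$conditions, row.names = FALSE)
  }
  invisible(x)
}
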