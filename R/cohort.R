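# Cohort assembly: eligibility windows and exposure-density matching.
#
# Entry is the latest of the candidate dates (diagnosis for the exposed arm,
# practice quality date, registration + 6 months, practice data start, the
# study start, and the 18th birthday); exit is the earliest of death,
# deregistration, practice data end and study end. Starting exposed
# follow-up at diagnosis removes immortal time. Comparators are drawn from
# the risk set at each exposed person's entry date (exposure-density
# sampling) and assigned that same entry date.

STUDY_START_DEFAULT <- as.Date("2000-01-01")
STUDY_END_DEFAULT <- as.Date("2019-01-16")

#' Cohort entry date
#'
#' The latest of: the exposure diagnosis date (exposed persons only), the
#' practice data-quality date, registration date + 6 calendar months, the
#' practice's first data-contribution date, the study start, and the
#' person's 18th birthday (adult cohort). Vectorised over persons.
#'
#' @param persons Persons data frame (rows aligned with `practice_rows`).
#' @param practice_rows Practice table rows matched to each person.
#' @param study_start Study start date (default 2000-01-01).
#' @param exposed Logical: compute the exposed-arm entry (include the
#'   diagnosis date in the maximum). Exposed persons with no diagnosis date
#'   are not an error here; they are flagged upstream in the build report.
#' @return A `Date` vector.
#' @export
entry_date <- function(persons, practice_rows,
                       study_start = STUDY_START_DEFAULT, exposed = FALSE) {
  adult <- dob_from_birth_year(persons$birth_year + 18L)
  e <- pmax_date(
    practice_rows$quality_date,
    add_months(persons$registration_date, 6L),
    practice_rows$data_start,
    rep(as.Date(study_start), nrow(persons)),
    adult
  )
  if (exposed) e <- pmax_date(e, persons$exposure_diagnosis_date)
  e
}

#' Cohort exit date
#'
#' The earliest of: death date, deregistration date, the practice's last
#' data-contribution date, and the study end (default 2019-01-16).
#'
#' @inheritParams entry_date
#' @param study_end Study end date.
#' @return A `Date` vector.
#' @export
exit_date <- function(persons, practice_rows, study_end = STUDY_END_DEFAULT) {
  pmin_date(
    persons$death_date,
    persons$deregistration_date,
    practice_rows$data_end,
    rep(as.Date(study_end), nrow(persons))
  )
}

#' Construct a cohort build report
#'
#' Records the exclusion flow of the exposed arm. The inclusion identity
#' `n_included_exposed = n_identified - n_excluded_no_date -
#' n_excluded_insufficient_matches` is enforced; exposed persons with an
#' empty eligibility window (for example death on the entry date) are a
#' separate diagnostics tally and are not part of `n_identified`.
#'
#' @param n_identified Exposed persons identified with a usable record.
#' @param n_excluded_no_date Exposed persons with no diagnosis date.
#' @param n_excluded_insufficient_matches Exposed persons dropped because the
#'   matching risk set was smaller than `min_matches`.
#' @param n_included_comparison Comparison persons included.
#' @param n_zero_followup Diagnostics tally of exposed persons with an empty
#'   eligibility window.
#' @return An object of class `build_report`.
#' @export
build_report <- function(n_identified, n_excluded_no_date = 0L,
                         n_excluded_insufficient_matches = 0L,
                         n_included_comparison = 0L, n_zero_followup = 0L) {
  n_inc <- n_identified - n_excluded_no_date - n_excluded_insufficient_matches
  if (n_inc < 0)
    stop("exclusions exceed the number of identified exposed persons",
         call. = FALSE)
  structure(list(
    n_identified = as.integer(n_identified),
    n_excluded_no_date = as.integer(n_excluded_no_date),
    n_excluded_insufficient_matches = as.integer(n_excluded_insufficient_matches),
    n_included_exposed = as.integer(n_inc),
    n_included_comparison = as.integer(n_included_comparison),
    n_zero_followup = as.integer(n_zero_followup)
  ), class = "build_report")
}

#' @export
print.build_report <- function(x, ...) {
  cat("Cohort build report\n")
  cat(sprintf("  exposed identified:            %d\n", x$n_identified))
  cat(sprintf("  excluded, no diagnosis date:   %d\n", x$n_excluded_no_date))
  cat(sprintf("  excluded, too few matches:     %d\n",
              x$n_excluded_insufficient_matches))
  cat(sprintf("  exposed included:              %d\n", x$n_included_exposed))
  cat(sprintf("  comparison included:           %d\n", x$n_included_comparison))
  if (x$n_zero_followup > 0)
    cat(sprintf("  (exposed with zero follow-up:  %d)\n", x$n_zero_followup))
  invisible(x)
}

derive_exposed_flag <- function(persons) {
  if ("exposed" %in% names(persons)) as.logical(persons$exposed)
  else !is.na(persons$exposure_diagnosis_date)
}

#' Build an exposure-density-matched cohort
#'
#' Resolves every person's eligibility window, enumerates exposed persons in
#' ascending entry-date order, and for each samples `match_ratio` comparators
#' uniformly without replacement from the risk set at that entry date: same
#' practice, sex and birth year; no exposure diagnosis on or before the date;
#' own (unexposed-rule) entry date on or before, and exit after, the date.
#' Comparators are assigned the exposed person's entry date. A person serves
#' as a comparator in at most one set (global without-replacement); this can
#' be relaxed to within-set-only with `replace_across_sets = TRUE`.
#'
#' Comparators later diagnosed with the exposure are censored as comparators
#' at their diagnosis date (and, being exposed, head their own set if
#' eligible), keeping exposure-density sampling consistent; set
#' `censor_comparators_at_diagnosis = FALSE` to disable.
#'
#' With `match_ratio = 0` no matching is performed: every person enters under
#' their own eligibility window and `group` is their exposure status (an
#' unmatched design, useful for simulation studies).
#'
#' @param persons,practices Tables in the package schema ([read_cohort_tables()]).
#' @param match_ratio Comparators per exposed person (default 10).
#' @param min_matches Minimum acceptable risk-set size; below it the exposed
#'   person is excluded ("too few matched comparison participants").
#'   Defaults to `match_ratio` (strict full-ratio matching).
#' @param study_start,study_end Study window.
#' @param match_seed Integer seed controlling comparator sampling.
#' @param censor_comparators_at_diagnosis Censor a comparator at a later
#'   exposure diagnosis (default `TRUE`).
#' @param replace_across_sets Allow one person to appear in several matched
#'   sets (default `FALSE`).
#' @return A list with `cohort` (one row per member: `person_id`, `group`,
#'   `matched_set_id`, `entry_date`, `exit_date`, `died_in_followup`) and
#'   `report` (a [build_report()]).
#' @export
build_cohort <- function(persons, practices, match_ratio = 10L,
                         min_matches = match_ratio,
                         study_start = STUDY_START_DEFAULT,
                         study_end = STUDY_END_DEFAULT,
                         match_seed = 1L,
                         censor_comparators_at_diagnosis = TRUE,
                         replace_across_sets = FALSE) {
  check_person_schema(persons)
  check_practice_schema(practices)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)

  pr_idx <- match(persons$practice_id, practices$practice_id)
  if (anyNA(pr_idx))
    stop("persons reference unknown practice_id values: ",
         paste(utils::head(unique(persons$practice_id[is.na(pr_idx)]), 5),
               collapse = ", "), call. = FALSE)
  prac <- practices[pr_idx, , drop = FALSE]

  exposed <- derive_exposed_flag(persons)
  entry_unexp <- entry_date(persons, prac, study_start, exposed = FALSE)
  exit_all <- exit_date(persons, prac, study_end)
  diag <- persons$exposure_diagnosis_date
  death <- persons$death_date

  if (match_ratio == 0L) {
    return(unmatched_cohort(persons, exposed, entry_unexp, exit_all, diag,
                            death))
  }

  no_date <- exposed & is.na(diag)
  entry_exp <- pmax_date(entry_unexp, diag)

  cand_mask <- exposed & !no_date
  zero_fu <- cand_mask & !(entry_exp < exit_all & !is.na(exit_all))
  eligible_exposed <- which(cand_mask & !zero_fu)
  # exposure-density order: ascending entry date, ties broken by person id
  ord <- eligible_exposed[order(entry_exp[eligible_exposed],
                                persons$person_id[eligible_exposed])]

  # risk-set cells keyed by practice x sex x birth year, candidate indices
  # pre-sorted by person id for deterministic seeded sampling
  key <- paste(persons$practice_id, persons$sex, persons$birth_year, sep = "\r")
  cells <- split(seq_len(nrow(persons)), key)
  cells <- lapply(cells, function(ix) ix[order(persons$person_id[ix])])

  used <- logical(nrow(persons))
  set.seed(as.integer(match_seed))

  n_sets_max <- length(ord)
  rows_i <- integer(0)       # person index per cohort row
  rows_grp <- character(0)
  rows_set <- character(0)
  rows_entry <- numeric(0)
  rows_exit <- numeric(0)
  out_list <- vector("list", n_sets_max)
  n_insufficient <- 0L
  set_no <- 0L

  entry_unexp_n <- as.numeric(entry_unexp)
  exit_n <- as.numeric(exit_all)
  diag_n <- as.numeric(diag)
  death_n <- as.numeric(death)

  for (i in ord) {
    e_i <- as.numeric(entry_exp[i])
    cand <- cells[[key[i]]]
    cand <- cand[cand != i & !used[cand]]
    ok <- (is.na(diag_n[cand]) | diag_n[cand] > e_i) &
      entry_unexp_n[cand] <= e_i &
      !is.na(exit_n[cand]) & exit_n[cand] > e_i
    cand <- cand[ok]
    if (length(cand) < min_matches) {
      n_insufficient <- n_insufficient + 1L
      next
    }
    take <- min(match_ratio, length(cand))
    sel <- cand[sample.int(length(cand), take)]
    if (!replace_across_sets) used[sel] <- TRUE
    set_no <- set_no + 1L
    set_id <- sprintf("set%06d", set_no)

    cmp_exit <- exit_n[sel]
    if (censor_comparators_at_diagnosis) {
      has_diag <- !is.na(diag_n[sel])
      cmp_exit[has_diag] <- pmin(cmp_exit[has_diag], diag_n[sel][has_diag])
    }
    out_list[[set_no]] <- data.frame(
      idx = c(i, sel),
      group = c("exposed", rep("comparison", length(sel))),
      matched_set_id = set_id,
      entry = c(e_i, rep(e_i, length(sel))),
      exit = c(exit_n[i], cmp_exit),
      stringsAsFactors = FALSE
    )
  }

  if (set_no == 0L) {
    cohort <- empty_cohort()
  } else {
    rows <- do.call(rbind, out_list[seq_len(set_no)])
    died <- !is.na(death_n[rows$idx]) & rows$exit == death_n[rows$idx]
    cohort <- data.frame(
      person_id = persons$person_id[rows$idx],
      group = rows$group,
      matched_set_id = rows$matched_set_id,
      entry_date = as.Date(rows$entry, origin = "1970-01-01"),
      exit_date = as.Date(rows$exit, origin = "1970-01-01"),
      died_in_followup = died,
      stringsAsFactors = FALSE
    )
  }

  report <- build_report(
    n_identified = sum(exposed) - sum(zero_fu),
    n_excluded_no_date = sum(no_date),
    n_excluded_insufficient_matches = n_insufficient,
    n_included_comparison = sum(cohort$group == "comparison"),
    n_zero_followup = sum(zero_fu)
  )
  stopifnot(report$n_included_exposed == sum(cohort$group == "exposed"))
  list(cohort = cohort, report = report)
}

# Unmatched design: every person enters once under their own eligibility
# window, grouped by exposure status (exposed persons from their diagnosis).
unmatched_cohort <- function(persons, exposed, entry_unexp, exit_all, diag,
                             death) {
  entry <- entry_unexp
  entry[exposed] <- pmax_date(entry_unexp[exposed], diag[exposed])
  exit <- exit_all
  keep <- !is.na(entry) & !is.na(exit) & entry < exit &
    !(exposed & is.na(diag))
  cohort <- data.frame(
    person_id = persons$person_id[keep],
    group = ifelse(exposed[keep], "exposed", "comparison"),
    matched_set_id = NA_character_,
    entry_date = entry[keep],
    exit_date = exit[keep],
    died_in_followup = !is.na(death[keep]) & death[keep] == exit[keep],
    stringsAsFactors = FALSE
  )
  report <- build_report(
    n_identified = sum(exposed & !is.na(diag) &
                         !is.na(entry) & !is.na(exit) & entry < exit),
    n_excluded_no_date = sum(exposed & is.na(diag)),
    n_excluded_insufficient_matches = 0L,
    n_included_comparison = sum(cohort$group == "comparison"),
    n_zero_followup = sum(exposed & !is.na(diag) &
                            !(!is.na(entry) & !is.na(exit) & entry < exit))
  )
  list(cohort = cohort, report = report)
}

empty_cohort <- function() {
  data.frame(person_id = character(0), group = character(0),
             matched_set_id = character(0),
             entry_date = as.Date(character(0)),
             exit_date = as.Date(character(0)),
             died_in_followup = logical(0), stringsAsFactors = FALSE)
}

check_person_schema <- function(persons) {
  need <- c("person_id", "practice_id", "sex", "birth_year",
            "registration_date")
  miss <- setdiff(need, names(persons))
  if (length(miss))
    stop("persons table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(persons)
}

check_practice_schema <- function(practices) {
  need <- c("practice_id", "quality_date", "data_start", "data_end")
  miss <- setdiff(need, names(practices))
  if (length(miss))
    stop("practices table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(practices)
}
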