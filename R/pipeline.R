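# End-to-end orchestration: simulate or read tables, build the matched
# cohort, tabulate person-time, fit the models and write every interchange
# file plus a human-readable report. All interchange files carry full
# precision; rounding happens only in the report.

#' Default pipeline configuration
#'
#' @param output_dir Where stage outputs are written.
#' @param input_dir Directory with `persons.csv` / `practices.csv` when not
#'   simulating.
#' @param simulate Generate synthetic tables instead of reading them.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param match_ratio,min_matches Matching parameters (default 1:10 strict).
#' @param study_start,study_end Study window.
#' @param age_range Strata and life-table age span (default 18-100).
#' @param a,radix Life-table constants.
#' @param n_sim Simulation draws for confidence intervals.
#' @param match_seed,sim_seed Seeds for comparator sampling and for the
#'   uncertainty simulation (the generator's own seed lives in `sim`).
#' @param entry_year_cutoff Calendar year used in the baseline summary.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "lifegap-output",
                            input_dir = NULL,
                            simulate = TRUE,
                            sim = sim_config(),
                            match_ratio = 10L,
                            min_matches = match_ratio,
                            study_start = STUDY_START_DEFAULT,
                            study_end = STUDY_END_DEFAULT,
                            age_range = c(18L, 100L),
                            a = 0.5, radix = 1e5,
                            n_sim = 1000L,
                            match_seed = 1L, sim_seed = 1L,
                            entry_year_cutoff = 2010L) {
  cfg <- list(output_dir = output_dir, input_dir = input_dir,
              simulate = simulate, sim = sim, match_ratio = match_ratio,
              min_matches = min_matches,
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              age_range = age_range, a = a, radix = radix, n_sim = n_sim,
              match_seed = match_seed, sim_seed = sim_seed,
              entry_year_cutoff = entry_year_cutoff)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of [pipeline_config()]
#' (with an optional nested `sim:` block mirroring [sim_config()]); unset
#' keys keep their defaults, and the fully resolved configuration is echoed
#' to the output directory when the pipeline runs.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  sim <- if (is.null(sim_args)) sim_config() else do.call(sim_config, sim_args)
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

#' Run the full analysis pipeline
#'
#' Chains every stage: data simulation (or loading), input validation,
#' cohort matching, person-time tabulation, Poisson rate fitting, life
#' tables and simulation intervals. Writes `persons.csv`/`practices.csv`
#' (when simulating), `cohort.csv`, `build_report.json`, `strata.csv`,
#' `rates.csv`, `fits.json`, `lifetable.csv`, `estimates.json`, a markdown
#' `report.md` and a `MANIFEST.json` recording the configuration
#' fingerprint and per-stage completion.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the fitted [lifegap()] object, the cohort,
#'   the build report, the strata and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  manifest_path <- file.path(out, "MANIFEST.json")
  cfg_json <- config_to_json(config)
  write_manifest <- function() {
    jsonlite::write_json(
      list(package = "lifegap",
           version = as.character(utils::packageVersion("lifegap")),
           config_hash = fnv1a(cfg_json),
           stages_completed = stages,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(cfg_json, file.path(out, "config.json"))

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    message(sprintf("[lifegap] stage '%s' complete", name))
    res
  }

  dat <- run_stage("data", {
    if (isTRUE(config$simulate)) {
      d <- simulate_ehr(config$sim)
      write_cohort_tables(d$persons, d$practices, out, config$sim)
      d
    } else {
      read_cohort_tables(config$input_dir)
    }
  })

  run_stage("validate", {
    v <- validate_inputs(dat$persons, dat$practices)
    n_err <- sum(v$violations$severity == "error")
    if (n_err > 0)
      stop(sprintf("%d input violations; see validate_inputs()", n_err))
    v
  })

  cb <- run_stage("cohort", {
    cb <- build_cohort(dat$persons, dat$practices,
                       match_ratio = config$match_ratio,
                       min_matches = config$min_matches,
                       study_start = config$study_start,
                       study_end = config$study_end,
                       match_seed = config$match_seed)
    utils::write.csv(cb$cohort, file.path(out, "cohort.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(unclass(cb$report),
                         file.path(out, "build_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cb
  })
  if (nrow(cb$cohort) == 0L) {
    write_manifest()
    stop("cohort is empty after matching; nothing to analyse", call. = FALSE)
  }

  strata <- run_stage("person_time", {
    s <- tabulate_strata(cb$cohort, dat$persons, config$age_range)
    utils::write.csv(s, file.path(out, "strata.csv"), row.names = FALSE)
    s
  })

  fit <- run_stage("model", {
    f <- lifegap(strata, n_sim = config$n_sim, seed = config$sim_seed,
                 ages = seq.int(config$age_range[1L], config$age_range[2L]),
                 a = config$a, radix = config$radix)
    rates <- predict.lifegap(f)
    crude <- crude_rates(strata, warn_zero = FALSE)
    rates$crude_rate <- crude$rate[match(
      paste(rates$group, rates$sex, rates$age),
      paste(crude$group, crude$sex, crude$age))] / 1e5
    utils::write.csv(rates, file.path(out, "rates.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(f$fits, function(ft) list(
        group = ft$group, sex = ft$sex,
        coefficients = as.list(ft$coefficients),
        covariance = ft$vcov, converged = ft$converged,
        deviance = ft$deviance, n_strata = ft$n_strata,
        total_deaths = ft$total_deaths)),
      file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    lts <- do.call(rbind, lapply(names(f$le), function(k) {
      lt <- as.data.frame(f$le[[k]]$life_table)
      cbind(group = f$le[[k]]$group, sex = f$le[[k]]$sex, lt)
    }))
    utils::write.csv(lts, file.path(out, "lifetable.csv"), row.names = FALSE)
    f
  })

  run_stage("estimates", {
    est <- list(
      life_expectancy = lapply(fit$le, function(e) list(
        group = e$group, sex = e$sex,
        total_life_expectancy = e$total_life_expectancy,
        ci_low = e$ci_low, ci_high = e$ci_high, level = e$level,
        n_sim = e$n_sim)),
      years_of_life_lost = lapply(fit$yll, function(y) list(
        sex = y$sex, yll = y$yll, ci_low = y$ci_low, ci_high = y$ci_high)),
      mortality_rate_ratio = lapply(fit$mrr, function(m) list(
        sex = m$sex, ratio = m$ratio, ci_low = m$ci_low,
        ci_high = m$ci_high, crude_ratio = m$crude_ratio))
    )
    jsonlite::write_json(est, file.path(out, "estimates.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    est
  })

  run_stage("report", {
    write_report_md(file.path(out, "report.md"), dat, cb, strata, fit,
                    config)
  })

  write_manifest()
  invisible(list(fit = fit, cohort = cb$cohort, report = cb$report,
                 strata = strata, output_dir = out))
}

config_to_json <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  for (nm in c("study_start", "study_end")) cfg[[nm]] <- format(cfg[[nm]])
  if (!is.null(cfg$sim)) {
    cfg$sim$study_start <- format(cfg$sim$study_start)
    cfg$sim$study_end <- format(cfg$sim$study_end)
  }
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

write_report_md <- function(path, dat, cb, strata, fit, config) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Life-expectancy gap report")
  w("")
  w("## Cohort flow")
  r <- cb$report
  w("- exposed identified: %d", r$n_identified)
  w("- excluded (no diagnosis date): %d", r$n_excluded_no_date)
  w("- excluded (too few matches): %d", r$n_excluded_insufficient_matches)
  w("- exposed included: %d; comparison included: %d",
    r$n_included_exposed, r$n_included_comparison)
  w("")
  w("## Deaths during follow-up")
  mt <- summarize_mortality(cb$cohort, dat$persons)
  w("| group | sex | n | deaths | %% died |")
  w("|---|---|---|---|---|")
  for (i in seq_len(nrow(mt)))
    w("| %s | %s | %d | %d | %.2f |", mt$group[i], mt$sex[i], mt$n[i],
      mt$deaths[i], mt$pct_died[i])
  w("")
  w("## Mortality rates by age band (per 100 000 person-years)")
  cr <- crude_rates(strata, age_breaks = c(18, 25, 35, 45, 55, 65,
                                           config$age_range[2L] + 1L),
                    warn_zero = FALSE)
  w("| group | sex | ages | deaths | person-years | rate (95%% CI) |")
  w("|---|---|---|---|---|---|")
  for (i in seq_len(nrow(cr))) {
    if (is.na(cr$rate[i])) next
    w("| %s | %s | %s | %d | %.0f | %.1f (%.1f-%.1f) |", cr$group[i],
      cr$sex[i], cr$age_band[i], cr$deaths[i], cr$person_years[i],
      cr$rate[i], cr$ci_low[i], cr$ci_high[i])
  }
  w("")
  w("## Life expectancy and years of life lost")
  for (k in names(fit$le)) {
    e <- fit$le[[k]]
    w("- total LE, %s %s: %.2f (%.2f-%.2f)", e$group, e$sex,
      e$total_life_expectancy, e$ci_low, e$ci_high)
  }
  for (s in names(fit$yll)) {
    y <- fit$yll[[s]]
    w("- years of life lost, %s: %.2f (%.2f-%.2f)", s, y$yll, y$ci_low,
      y$ci_high)
  }
  w("")
  w("## Mortality rate ratios")
  for (s in names(fit$mrr)) {
    m <- fit$mrr[[s]]
    w("- %s: %.2f (%.2f-%.2f) age-adjusted; %.2f crude", s, m$ratio,
      m$ci_low, m$ci_high, m$crude_ratio)
  }
  invisible(path)
}

#' Validate user-supplied persons and practices tables
#'
#' Schema, date-parse and invariant checks with row-level diagnostics:
#' required columns, registration before deregistration, death on or after
#' registration, practice windows ordered, all person practice references
#' resolvable, and exposed persons carrying a diagnosis date.
#'
#' @param persons,practices Data frames in the package schema.
#' @return Object of class `validation_report` with a `violations` data
#'   frame (`table`, `row`, `field`, `message`); zero rows means clean.
#' @export
validate_inputs <- function(persons, practices) {
  v <- list()
  flag <- function(tbl, rows, field, msg, severity = "error") {
    if (length(rows))
      v[[length(v) + 1L]] <<- data.frame(table = tbl, row = rows,
                                         field = field, message = msg,
                                         severity = severity,
                                         stringsAsFactors = FALSE)
  }
  miss_p <- setdiff(c("person_id", "practice_id", "sex", "birth_year",
                      "registration_date"), names(persons))
  flag("persons", if (length(miss_p)) 0L else integer(0), "schema",
       paste("missing columns:", paste(miss_p, collapse = ", ")))
  miss_q <- setdiff(c("practice_id", "quality_date", "data_start",
                      "data_end"), names(practices))
  flag("practices", if (length(miss_q)) 0L else integer(0), "schema",
       paste("missing columns:", paste(miss_q, collapse = ", ")))

  if (!length(miss_p) && !length(miss_q)) {
    dereg <- persons$deregistration_date
    flag("persons",
         which(!is.na(dereg) & dereg <= persons$registration_date),
         "deregistration_date", "deregistration on or before registration")
    if ("death_date" %in% names(persons))
      flag("persons",
           which(!is.na(persons$death_date) &
                   persons$death_date < persons$registration_date),
           "death_date", "death before registration")
    flag("persons", which(is.na(persons$registration_date)),
         "registration_date", "unparseable or missing date")
    flag("persons",
         which(!persons$sex %in% c("male", "female")),
         "sex", "sex must be 'male' or 'female'")
    flag("persons",
         which(is.na(match(persons$practice_id, practices$practice_id))),
         "practice_id", "unknown practice")
    if (all(c("exposed", "exposure_diagnosis_date") %in% names(persons)))
      flag("persons",
           which(derive_exposed_flag(persons) &
                   is.na(persons$exposure_diagnosis_date) &
                   "exposed" %in% names(persons)),
           "exposure_diagnosis_date",
           "exposed person with no diagnosis date (will be excluded)",
           severity = "warning")
    flag("practices",
         which(practices$data_start > practices$data_end),
         "data_start", "data_start after data_end")
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(0), row = integer(0), field = character(0),
               message = character(0), severity = character(0),
               stringsAsFactors = FALSE)
  structure(list(violations = violations,
                 n_persons = nrow(persons), n_practices = nrow(practices)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validated %d persons, %d practices: %d violation(s)\n",
              x$n_persons, x$n_practices, nrow(x$violations)))
  if (nrow(x$violations)) print(utils::head(x$violations, 20),
                                row.names = FALSE)
  invisible(x)
}
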