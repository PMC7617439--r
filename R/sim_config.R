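#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the synthetic primary-care data
#' generator. Identical configurations (including `seed`) always produce
#' byte-identical tables, across sessions.
#'
#' Mortality follows a Gompertz hazard m(x) = a * exp(b * x) per person-year
#' at age x, multiplied by `exposure_rate_ratio` from the exposure diagnosis
#' onward. The defaults (a = 3e-5, b = 0.09) put unexposed life expectancy
#' near 80 years; they are defaults, not empirical claims.
#'
#' @param n_practices Number of primary-care practices.
#' @param persons_per_practice Persons generated per practice.
#' @param exposure_prevalence Probability a person carries the exposure
#'   diagnosis (before any death-before-diagnosis attrition).
#' @param sex_ratio_exposed,sex_ratio_unexposed Proportion male in each arm.
#'   Exposed defaults to 0.78, mirroring the strong male skew of diagnosed
#'   ADHD in primary care; unexposed defaults to 0.5.
#' @param gompertz_a Baseline hazard at age 0, per person-year (> 0, or 0 for
#'   a deathless population).
#' @param gompertz_b Log-hazard slope per year of age (>= 0).
#' @param exposure_rate_ratio Multiplicative hazard ratio applied from the
#'   diagnosis date onward (> 0).
#' @param study_start,study_end Study window (`Date` or ISO-8601 string).
#'   Defaults 2000-01-01 and 2019-01-16.
#' @param birth_year_range Inclusive integer interval of birth years.
#' @param registration_churn_rate Per person-year rate of deregistration,
#'   modelled as an exponential waiting time independent of death.
#' @param diagnosis_age Named list describing the diagnosis-age distribution;
#'   currently `list(dist = "uniform", min = 6, max = 40)` (the default) or
#'   `list(dist = "normal", mean, sd)` truncated at 0.
#' @param condition_prevalences Named list mapping a condition name to a
#'   length-2 numeric vector `c(exposed = p1, unexposed = p0)` of baseline
#'   probabilities.
#' @param seed Integer root seed. Per-practice child seeds are derived from it
#'   so output is invariant to generation order.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_practices = 20L,
                       persons_per_practice = 500L,
                       exposure_prevalence = 0.02,
                       sex_ratio_exposed = 0.78,
                       sex_ratio_unexposed = 0.5,
                       gompertz_a = 3e-5,
                       gompertz_b = 0.09,
                       exposure_rate_ratio = 2.0,
                       study_start = "2000-01-01",
                       study_end = "2019-01-16",
                       birth_year_range = c(1930L, 1995L),
                       registration_churn_rate = 0.02,
                       diagnosis_age = list(dist = "uniform", min = 6, max = 40),
                       condition_prevalences = list(
                         depression = c(exposed = 0.28, unexposed = 0.08),
                         anxiety = c(exposed = 0.24, unexposed = 0.09),
                         smoking = c(exposed = 0.35, unexposed = 0.20)
                       ),
                       seed = 1L) {
  cfg <- list(
    n_practices = as.integer(n_practices),
    persons_per_practice = as.integer(persons_per_practice),
    exposure_prevalence = exposure_prevalence,
    sex_ratio_exposed = sex_ratio_exposed,
    sex_ratio_unexposed = sex_ratio_unexposed,
    gompertz_a = gompertz_a,
    gompertz_b = gompertz_b,
    exposure_rate_ratio = exposure_rate_ratio,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    birth_year_range = as.integer(birth_year_range),
    registration_churn_rate = registration_churn_rate,
    diagnosis_age = diagnosis_age,
    condition_prevalences = condition_prevalences,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation configuration: `%s` %s", field, why),
         call. = FALSE)
  }
  chk_count <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1L || is.na(x) || x < 1L) bad(field, "must be a positive integer")
  }
  chk_prop <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) bad(field, "must lie in [0, 1]")
  }
  chk_count("n_practices")
  chk_count("persons_per_practice")
  chk_prop("exposure_prevalence")
  chk_prop("sex_ratio_exposed")
  chk_prop("sex_ratio_unexposed")
  if (!is.finite(cfg$gompertz_a) || cfg$gompertz_a < 0)
    bad("gompertz_a", "must be finite and >= 0")
  if (!is.finite(cfg$gompertz_b) || cfg$gompertz_b < 0)
    bad("gompertz_b", "must be finite and >= 0")
  if (!is.finite(cfg$exposure_rate_ratio) || cfg$exposure_rate_ratio <= 0)
    bad("exposure_rate_ratio", "must be finite and > 0")
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      cfg$study_start >= cfg$study_end)
    bad("study_start/study_end", "must satisfy study_start < study_end")
  if (length(cfg$birth_year_range) != 2L || any(is.na(cfg$birth_year_range)) ||
      cfg$birth_year_range[1L] > cfg$birth_year_range[2L])
    bad("birth_year_range", "must be an inclusive integer interval")
  if (!is.finite(cfg$registration_churn_rate) ||
      cfg$registration_churn_rate < 0 || cfg$registration_churn_rate >= 1)
    bad("registration_churn_rate", "must lie in [0, 1)")
  da <- cfg$diagnosis_age
  if (!is.list(da) || is.null(da$dist) ||
      !da$dist %in% c("uniform", "normal"))
    bad("diagnosis_age", "must name a supported distribution (uniform, normal)")
  if (da$dist == "uniform" &&
      (is.null(da$min) || is.null(da$max) || da$min < 0 || da$min > da$max))
    bad("diagnosis_age", "uniform needs 0 <= min <= max")
  if (da$dist == "normal" && (is.null(da$mean) || is.null(da$sd) || da$sd < 0))
    bad("diagnosis_age", "normal needs mean and sd >= 0")
  for (nm in names(cfg$condition_prevalences)) {
    p <- cfg$condition_prevalences[[nm]]
    if (length(p) != 2L || any(!is.finite(p)) || any(p < 0) || any(p > 1))
      bad(paste0("condition_prevalences$", nm),
          "must be two probabilities c(exposed=, unexposed=)")
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    bad("seed", "must be a single integer")
  invisible(cfg)
}

# Deterministic per-practice child seed derived from the practice identity
# (not its row position), so person generation is invariant to the order in
# which practices are processed. Kept inside 32-bit range.
practice_seed <- function(root_seed, id) {
  h <- if (is.character(id)) {
    sum(as.numeric(utf8ToInt(id)) * seq_len(nchar(id)) * 131)
  } else as.numeric(id)
  as.integer((as.numeric(root_seed) * 7919 + h * 104729) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  practices: %d x %d persons (seed %d)\n",
              x$n_practices, x$persons_per_practice, x$seed))
  cat(sprintf("  exposure prevalence %.4g, hazard ratio %.3g\n",
              x$exposure_prevalence, x$exposure_rate_ratio))
  cat(sprintf("  Gompertz hazard a = %.3g, b = %.3g per year of age\n",
              x$gompertz_a, x$gompertz_b))
  cat(sprintf("  study window %s to %s, births %d-%d\n",
              format(x$study_start), format(x$study_end),
              x$birth_year_range[1], x$birth_year_range[2]))
  invisible(x)
}
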