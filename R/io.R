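# Plain-CSV interchange. Dates are ISO-8601 strings on disk; full numeric
# precision is preserved (rounding happens only in the reporting layer).

date_cols_persons <- function(df) {
  c("registration_date", "deregistration_date", "exposure_diagnosis_date",
    "death_date", grep("^cond_", names(df), value = TRUE))
}

#' Write synthetic or user cohort tables to a directory
#'
#' Writes `persons.csv` and `practices.csv` with ISO-8601 dates, plus a
#' sidecar `sim_config.json` of the resolved generator configuration
#' (including the seed) when one is supplied, for provenance.
#'
#' @param persons,practices Data frames in the package schema.
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] to echo alongside the tables.
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(persons, practices, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "persons.csv")
  qq <- file.path(dir, "practices.csv")
  utils::write.csv(persons, pp, row.names = FALSE, na = "")
  utils::write.csv(practices, qq, row.names = FALSE, na = "")
  paths <- c(persons = pp, practices = qq)
  if (!is.null(config)) {
    cj <- file.path(dir, "sim_config.json")
    cfg <- unclass(config)
    cfg$study_start <- format(cfg$study_start)
    cfg$study_end <- format(cfg$study_end)
    jsonlite::write_json(cfg, cj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, config = cj)
  }
  invisible(paths)
}

#' Read persons and practices tables
#'
#' Reads the CSV schema written by [write_cohort_tables()] (or supplied by a
#' user), parsing all date columns to `Date` and empty strings to `NA`.
#'
#' @param dir Directory containing `persons.csv` and `practices.csv`.
#' @return A list with `persons` and `practices` data frames.
#' @export
read_cohort_tables <- function(dir) {
  pf <- file.path(dir, "persons.csv")
  qf <- file.path(dir, "practices.csv")
  if (!file.exists(pf) || !file.exists(qf))
    stop("expected persons.csv and practices.csv under ", dir, call. = FALSE)
  persons <- utils::read.csv(pf, stringsAsFactors = FALSE, na.strings = "")
  practices <- utils::read.csv(qf, stringsAsFactors = FALSE, na.strings = "")
  for (cn in intersect(date_cols_persons(persons), names(persons)))
    persons[[cn]] <- as.Date(persons[[cn]])
  for (cn in c("quality_date", "data_start", "data_end"))
    if (cn %in% names(practices)) practices[[cn]] <- as.Date(practices[[cn]])
  if ("exposed" %in% names(persons))
    persons$exposed <- as.logical(persons$exposed)
  list(persons = persons, practices = practices)
}

# FNV-1a over a string; used for the pipeline MANIFEST's config fingerprint.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
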