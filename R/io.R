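# CSV interfaces: three documented tables (dogs, reports, questionnaires),
# UTF-8, ISO-8601 dates, unknown parents as empty fields, plus a ground-truth
# sidecar JSON written only by the simulator for test introspection.

dogs_schema <- c("dog_id", "sire_id", "dam_id", "sex", "birth_date", "purpose",
                 "swims", "latitude", "longitude", "household_type",
                 "smoker_household", "coat", "neutered")
reports_schema <- c("dog_id", "report_date", "text", "vet_visit")
questionnaires_schema <- c("dog_id", "sign_limp_end", "sign_limp_length",
                           "sign_stiff_base", "sign_hair_on_end", "sign_painful",
                           "attribution", "pain_score", "qol_score",
                           "pain_reported", "n_episodes", "duration_category",
                           "swims_ever")

write_csv_utf8 <- function(x, path) {
  for (col in names(x)) if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a simulated cohort to its three CSV tables
#'
#' Emits `dogs.csv`, `reports.csv` and `questionnaires.csv` under `dir`, and
#' (when `statuses` is supplied) a `ground_truth.json` sidecar holding the
#' latent statuses, sire effects and report template classes, for use by
#' tests only.
#'
#' @param dir output directory (created if needed).
#' @param cohort,reports,questionnaires the generator outputs.
#' @param statuses optional [simulate_case_status()] result.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort_tables <- function(dir, cohort, reports, questionnaires, statuses = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dogs = file.path(dir, "dogs.csv"),
    reports = file.path(dir, "reports.csv"),
    questionnaires = file.path(dir, "questionnaires.csv")
  )
  write_csv_utf8(cohort, paths[["dogs"]])
  write_csv_utf8(reports[setdiff(names(reports), "template_class")], paths[["reports"]])
  write_csv_utf8(questionnaires, paths[["questionnaires"]])
  if (!is.null(statuses)) {
    gt <- list(
      status = statuses$status,
      sire_effects = as.list(statuses$sire_effects),
      template_class = if ("template_class" %in% names(reports)) {
        reports[c("dog_id", "report_date", "template_class")]
      }
    )
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, ground_truth = file.path(dir, "ground_truth.json"))
  }
  invisible(paths)
}

read_table_checked <- function(path, schema, what) {
  if (!file.exists(path)) abort_arg("%s file not found: %s", what, path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(schema, names(x))
  if (length(missing_cols)) {
    abort_arg("%s is missing required column(s): %s", what,
              paste(missing_cols, collapse = ", "))
  }
  x
}

#' Read the dog table
#'
#' Parses `dogs.csv`, coercing dates and booleans and normalising empty
#' parent fields to `NA`.
#'
#' @param path path to `dogs.csv`.
#' @return Data frame of dog records.
#' @export
read_dogs <- function(path) {
  x <- read_table_checked(path, dogs_schema, "dogs.csv")
  x$birth_date <- as.Date(x$birth_date)
  for (col in c("swims", "smoker_household", "neutered")) x[[col]] <- as.logical(x[[col]])
  for (col in c("sire_id", "dam_id")) {
    x[[col]][!is.na(x[[col]]) & x[[col]] == ""] <- NA
  }
  x
}

#' Read the free-text illness report table
#' @param path path to `reports.csv`.
#' @return Data frame of illness reports.
#' @export
read_reports <- function(path) {
  x <- read_table_checked(path, reports_schema, "reports.csv")
  x$report_date <- as.Date(x$report_date)
  x$vet_visit <- as.logical(x$vet_visit)
  x$text[is.na(x$text)] <- ""
  x
}

#' Read the tail-health questionnaire table
#' @param path path to `questionnaires.csv`.
#' @return Data frame of questionnaire responses.
#' @export
read_questionnaires <- function(path) {
  x <- read_table_checked(path, questionnaires_schema, "questionnaires.csv")
  x$swims_ever <- as.logical(x$swims_ever)
  x
}

#' Validate the three input tables
#'
#' Schema check (required columns, value domains, date parsing) plus
#' referential integrity: every report and questionnaire `dog_id` must occur
#' in the dog table. Returns all violations rather than stopping at the
#' first.
#'
#' @param dogs_path,reports_path,questionnaires_path file paths; a
#'   questionnaire path may be `NULL` when that stage is not run.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_inputs <- function(dogs_path, reports_path, questionnaires_path = NULL) {
  violations <- character(0)
  note <- function(fmt, ...) violations <<- c(violations, sprintf(fmt, ...))
  dogs <- tryCatch(read_dogs(dogs_path), error = function(e) { note("%s", conditionMessage(e)); NULL })
  reports <- tryCatch(read_reports(reports_path), error = function(e) { note("%s", conditionMessage(e)); NULL })
  quest <- if (!is.null(questionnaires_path)) {
    tryCatch(read_questionnaires(questionnaires_path),
             error = function(e) { note("%s", conditionMessage(e)); NULL })
  }
  if (!is.null(dogs)) {
    if (anyDuplicated(dogs$dog_id)) note("dogs.csv: duplicate dog_id")
    if (anyNA(dogs$birth_date)) note("dogs.csv: unparseable birth_date")
    bad_lat <- !is.na(dogs$latitude) & (dogs$latitude < -90 | dogs$latitude > 90)
    if (any(bad_lat)) note("dogs.csv: latitude outside [-90, 90]")
    bad_purpose <- !dogs$purpose %in% c("household_pet", "working", "gundog_and_pet", "other")
    if (any(bad_purpose)) note("dogs.csv: unknown purpose value(s): %s",
                               paste(unique(dogs$purpose[bad_purpose]), collapse = ", "))
    if (!all(dogs$sex %in% c("F", "M"))) note("dogs.csv: sex must be F or M")
  }
  if (!is.null(reports)) {
    if (anyNA(reports$report_date)) note("reports.csv: unparseable report_date")
    if (!is.null(dogs)) {
      orphan <- setdiff(reports$dog_id, dogs$dog_id)
      if (length(orphan)) note("reports.csv: dog_id(s) absent from dogs.csv: %s",
                               paste(orphan, collapse = ", "))
    }
  }
  if (!is.null(quest)) {
    for (col in c("sign_limp_end", "sign_limp_length", "sign_stiff_base",
                  "sign_hair_on_end", "sign_painful")) {
      if (!all(quest[[col]] %in% c("yes", "no", "unsure"))) {
        note("questionnaires.csv: %s must be yes/no/unsure", col)
      }
    }
    for (col in c("pain_score", "qol_score")) {
      v <- quest[[col]]
      if (any(!is.na(v) & (v < 0 | v > 10))) note("questionnaires.csv: %s outside [0, 10]", col)
    }
    if (!is.null(dogs)) {
      orphan <- setdiff(quest$dog_id, dogs$dog_id)
      if (length(orphan)) note("questionnaires.csv: dog_id(s) absent from dogs.csv: %s",
                               paste(orphan, collapse = ", "))
    }
  }
  violations
}
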