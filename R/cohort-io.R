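# CSV round trip for the three cohort tables. Missing values are written
# as empty fields; dates are integer days since randomisation (day 0).

patient_cols <- c(id = "integer", arm = "character", age = "numeric",
                  sex = "character", apache2 = "integer",
                  pf_ratio = "numeric", prime_condition = "character",
                  surgery_admission = "logical", icu_days = "integer",
                  vent_days = "integer", hospital_days = "integer",
                  death_day = "integer", alive_1yr = "logical",
                  discharged_to_other_hospital = "logical",
                  readmission_days = "integer", stepdown_level = "character")

crf_cols <- c(patient_id = "integer", day_index = "integer",
              organs_supported = "integer", on_ventilation = "logical",
              on_rrt = "logical", xray_count = "integer",
              chest_drain = "logical", drug_antibiotic = "integer",
              drug_sedative = "integer", drug_muscle_relaxant = "integer")

quest_cols <- c(patient_id = "integer", wave = "character",
                returned = "logical", eq5d_state = "character",
                gp_visits = "integer", outpatient_visits = "integer",
                community_visits = "integer", inpatient_days = "integer",
                aids_items = "character", travel_miles = "integer",
                lost_earnings = "numeric", oop_expenses = "numeric",
                carer_travel_miles = "integer",
                carer_lost_earnings = "numeric")

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `daily_crf.csv` and `questionnaires.csv` into
#' `directory`. Missing values are encoded as empty fields, and
#' `read_cohort()` restores the tables identically.
#'
#' @param cohort An `ards_cohort` (or a bare list with elements
#'   `patients`, `daily_crf`, `questionnaires`).
#' @param directory Output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory,
                     c("patients.csv", "daily_crf.csv", "questionnaires.csv"))
  tables <- list(cohort$patients, cohort$daily_crf, cohort$questionnaires)
  for (i in 1:3) {
    utils::write.csv(tables[[i]], paths[i], row.names = FALSE, na = "")
  }
  invisible(paths)
}

read_cohort_table <- function(path, spec, label) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols))
    stop(label, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[names(spec)]
  for (col in names(spec)) {
    raw <- df[[col]]
    raw[raw == ""] <- NA
    parsed <- switch(spec[[col]],
                     integer = suppressWarnings(as.integer(raw)),
                     numeric = suppressWarnings(as.numeric(raw)),
                     logical = as.logical(raw),
                     character = raw)
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad))
      stop(label, " row ", bad[1], ", column '", col,
           "': cannot parse value '", raw[bad[1]], "'", call. = FALSE)
    df[[col]] <- parsed
  }
  df
}

check_nonneg <- function(df, cols, label) {
  for (col in cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop(label, " row ", bad[1], ", column '", col,
           "': negative value ", df[[col]][bad[1]], call. = FALSE)
  }
}

validate_patients <- function(p, label = "patients.csv") {
  check_nonneg(p, c("age", "apache2", "pf_ratio", "icu_days", "vent_days",
                    "hospital_days", "death_day", "readmission_days"), label)
  bad <- which(p$icu_days < 1)
  if (length(bad))
    stop(label, " row ", bad[1], ", column 'icu_days': must be >= 1",
         call. = FALSE)
  bad <- which(p$apache2 > 71)
  if (length(bad))
    stop(label, " row ", bad[1],
         ", column 'apache2': exceeds the admissible maximum of 71",
         call. = FALSE)
  bad <- which(p$vent_days > p$icu_days | p$icu_days > p$hospital_days)
  if (length(bad))
    stop(label, " row ", bad[1],
         ": requires vent_days <= icu_days <= hospital_days", call. = FALSE)
  bad <- which(p$alive_1yr != (is.na(p$death_day) | p$death_day > 365))
  if (length(bad))
    stop(label, " row ", bad[1],
         ", column 'alive_1yr': inconsistent with death_day", call. = FALSE)
  if (anyDuplicated(p$id))
    stop(label, ": duplicated patient id ", p$id[anyDuplicated(p$id)],
         call. = FALSE)
  invisible(p)
}

validate_crf <- function(d, label = "daily_crf.csv") {
  check_nonneg(d, c("day_index", "organs_supported", "xray_count",
                    "drug_antibiotic", "drug_sedative",
                    "drug_muscle_relaxant"), label)
  bad <- which(d$organs_supported > 6)
  if (length(bad))
    stop(label, " row ", bad[1],
         ", column 'organs_supported': exceeds 6", call. = FALSE)
  if (anyDuplicated(d[c("patient_id", "day_index")]))
    stop(label, ": duplicated (patient_id, day_index) pair", call. = FALSE)
  invisible(d)
}

validate_questionnaires <- function(q, label = "questionnaires.csv") {
  check_nonneg(q, c("gp_visits", "outpatient_visits", "community_visits",
                    "inpatient_days", "travel_miles", "lost_earnings",
                    "oop_expenses", "carer_travel_miles",
                    "carer_lost_earnings"), label)
  content <- setdiff(names(q), c("patient_id", "wave", "returned"))
  for (col in content) {
    bad <- which(!q$returned & !is.na(q[[col]]))
    if (length(bad))
      stop(label, " row ", bad[1], ", column '", col,
           "': value present on a non-returned questionnaire", call. = FALSE)
  }
  bad <- which(q$returned & is.na(q$eq5d_state))
  if (length(bad))
    stop(label, " row ", bad[1],
         ", column 'eq5d_state': missing on a returned questionnaire",
         call. = FALSE)
  invisible(q)
}

#' Read a cohort from CSV files
#'
#' Reads the three tables written by [write_cohort()], restoring column
#' types and the empty-field encoding of missing values, and validates
#' the domain invariants (non-negative counts, nested lengths of stay,
#' vital-status consistency, content absent on non-returned
#' questionnaires). Malformed rows are reported with row number and
#' column.
#'
#' @param directory Directory containing `patients.csv`, `daily_crf.csv`
#'   and `questionnaires.csv`.
#' @return An `ards_cohort` list.
#' @export
read_cohort <- function(directory) {
  p <- read_cohort_table(file.path(directory, "patients.csv"),
                         patient_cols, "patients.csv")
  d <- read_cohort_table(file.path(directory, "daily_crf.csv"),
                         crf_cols, "daily_crf.csv")
  q <- read_cohort_table(file.path(directory, "questionnaires.csv"),
                         quest_cols, "questionnaires.csv")
  # read.csv drops NA-only typing on empty tables; aids_items "" round trip:
  q$aids_items[!is.na(q$eq5d_state) & is.na(q$aids_items)] <- ""
  validate_patients(p)
  validate_crf(d)
  validate_questionnaires(q)
  structure(list(patients = p, daily_crf = d, questionnaires = q),
            class = "ards_cohort")
}
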