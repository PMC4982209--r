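# Bottom-up micro-costing: unit costs times volumes of resource use,
# summed per patient over each care pathway, all in base-year prices.

#' Load a unit-cost table
#'
#' Reads the unit costs used by the costing engine from YAML. The bundled
#' table is illustrative (the national reference-cost, formulary and
#' PSSRU sources behind the original analysis are not redistributable);
#' the post-ICU ward day is anchored at GBP 297 to the published daily
#' quartile, and all entries can be replaced by pointing `file` at an
#' alternative YAML with the same keys.
#'
#' @param file Optional path to a YAML unit-cost file.
#' @return A list of class `unit_cost_table` with elements
#'   `cost_per_organ_day` (named by organ count 0--6), `rrt_cost`,
#'   `xray_cost`, `chest_drain_cost`, `drug_costs`, `vent_machine_price`,
#'   `vent_machine_life_years`, `vent_annual_maintenance`,
#'   `vent_utilisation_days`, `vent_circuit_cost`, `stepdown_cost_per_day`
#'   (named by care level, including `icu` for readmission days),
#'   `transfer_cost`, `sae_costs`, `visit_costs`, `inpatient_cost_per_day`,
#'   `aids_costs`, `petrol_rate`, `hchs_index`, `base_year`.
#' @export
default_unit_costs <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "unit_costs.yaml", package = "ardsecon",
                        mustWork = TRUE)
  }
  if (!file.exists(file))
    stop("unit-cost file not found: ", file, call. = FALSE)
  raw <- yaml::read_yaml(file)
  for (f in c("cost_per_organ_day", "drug_costs", "stepdown_cost_per_day",
              "sae_costs", "visit_costs", "aids_costs", "hchs_index")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  costs <- structure(raw, class = "unit_cost_table")
  validate_unit_costs(costs)
  costs
}

validate_unit_costs <- function(costs) {
  scalars <- c("rrt_cost", "xray_cost", "chest_drain_cost",
               "vent_machine_price", "vent_annual_maintenance",
               "vent_circuit_cost", "transfer_cost",
               "inpatient_cost_per_day", "petrol_rate")
  vals <- c(unlist(costs[scalars]), costs$cost_per_organ_day,
            costs$drug_costs, costs$stepdown_cost_per_day, costs$sae_costs,
            costs$visit_costs, costs$aids_costs)
  if (any(vals < 0))
    stop("unit costs must all be >= 0", call. = FALSE)
  if (costs$vent_machine_life_years <= 0)
    stop("vent_machine_life_years must be > 0", call. = FALSE)
  if (!as.character(costs$base_year) %in% names(costs$hchs_index))
    stop("hchs_index must contain the base year ", costs$base_year,
         call. = FALSE)
  invisible(costs)
}

#' Daily cost of mechanical ventilation
#'
#' Fixed machine costs are amortised straight-line over the machine's
#' life and spread over the assumed utilisation: `(machine_price /
#' life_years + annual_maintenance) / utilisation` per ventilated day.
#' The single-use circuit cost is a per-patient cost added once by
#' [cost_icu_stay()], not here.
#'
#' @param costs A `unit_cost_table`.
#' @param assumed_daily_utilisation Ventilator utilisation in days per
#'   year (defaults to the table's `vent_utilisation_days`).
#' @return GBP per ventilated day.
#' @export
daily_vent_cost <- function(costs,
                            assumed_daily_utilisation =
                              costs$vent_utilisation_days) {
  if (!is.numeric(assumed_daily_utilisation) || assumed_daily_utilisation <= 0)
    stop("ventilator utilisation must be > 0 days/year", call. = FALSE)
  (costs$vent_machine_price / costs$vent_machine_life_years +
     costs$vent_annual_maintenance) / assumed_daily_utilisation
}

lookup_cost <- function(table, keys, what) {
  idx <- match(as.character(keys), names(table))
  if (anyNA(idx)) {
    missing_key <- as.character(keys)[which(is.na(idx))[1]]
    stop("no unit cost configured for ", what, " '", missing_key, "'",
         call. = FALSE)
  }
  unname(table[idx])
}

#' Cost of the initial ICU stay for one patient
#'
#' Sums, over the patient's daily case-report rows, the organ-support
#' day cost (a lookup keyed by number of organs supported), renal
#' replacement, X-rays, chest drains, drug units at per-unit prices and
#' the daily ventilation cost on ventilated days, plus one single-use
#' circuit cost if the patient was ever ventilated. Linear in every unit
#' cost.
#'
#' @param crfs Daily CRF rows for a single patient.
#' @param costs A `unit_cost_table`.
#' @return GBP for the entire stay (0 for zero rows).
#' @export
cost_icu_stay <- function(crfs, costs) {
  if (nrow(crfs) == 0L) return(0)
  if (length(unique(crfs$patient_id)) > 1L)
    stop("cost_icu_stay expects the CRF rows of a single patient",
         call. = FALSE)
  organ <- lookup_cost(costs$cost_per_organ_day, crfs$organs_supported,
                       "organ-support count")
  drugs <- crfs$drug_antibiotic * lookup_cost(costs$drug_costs, "antibiotic",
                                              "drug") +
    crfs$drug_sedative * lookup_cost(costs$drug_costs, "sedative", "drug") +
    crfs$drug_muscle_relaxant * lookup_cost(costs$drug_costs,
                                            "muscle_relaxant", "drug")
  daily <- organ + crfs$on_rrt * costs$rrt_cost +
    crfs$xray_count * costs$xray_cost +
    crfs$chest_drain * costs$chest_drain_cost + drugs +
    crfs$on_ventilation * daily_vent_cost(costs)
  sum(daily) + if (any(crfs$on_ventilation)) costs$vent_circuit_cost else 0
}

#' Post-ICU hospital cost for one patient
#'
#' For a patient discharged alive from the initial ICU stay: days on the
#' step-down ward (until death or hospital discharge) at the cost of the
#' level of care required, ICU readmission days at the ICU daily rate,
#' an emergency-transfer cost if discharged to another hospital, and any
#' itemised serious-adverse-event costs. Patients who died during the
#' initial ICU stay incur no post-ICU cost.
#'
#' @param patient One row of the patients table.
#' @param costs A `unit_cost_table`.
#' @param sae_events Optional character vector of SAE codes for this
#'   patient, costed by lookup in `costs$sae_costs`.
#' @return GBP.
#' @export
cost_post_icu <- function(patient, costs, sae_events = character(0)) {
  died_in_icu <- !is.na(patient$death_day) &&
    patient$death_day <= patient$icu_days
  if (died_in_icu) return(0)
  end_day <- if (!is.na(patient$death_day))
    min(patient$hospital_days, patient$death_day) else patient$hospital_days
  post_days <- max(0L, end_day - patient$icu_days)
  readmit_days <- min(patient$readmission_days, post_days)
  stepdown_days <- post_days - readmit_days
  level_cost <- lookup_cost(costs$stepdown_cost_per_day,
                            patient$stepdown_level, "care level")
  icu_rate <- lookup_cost(costs$stepdown_cost_per_day, "icu", "care level")
  sae_cost <- if (length(sae_events))
    sum(lookup_cost(costs$sae_costs, sae_events, "SAE code")) else 0
  stepdown_days * level_cost + readmit_days * icu_rate +
    (isTRUE(patient$discharged_to_other_hospital)) * costs$transfer_cost +
    sae_cost
}

parse_aids <- function(aids_items) {
  if (is.na(aids_items) || !nzchar(aids_items)) return(character(0))
  strsplit(aids_items, ";", fixed = TRUE)[[1]]
}

wave_nhs_cost <- function(q, costs) {
  q$gp_visits * lookup_cost(costs$visit_costs, "gp", "service") +
    q$outpatient_visits * lookup_cost(costs$visit_costs, "outpatient",
                                      "service") +
    q$community_visits * lookup_cost(costs$visit_costs, "community",
                                     "service") +
    q$inpatient_days * costs$inpatient_cost_per_day +
    sum(lookup_cost(costs$aids_costs, parse_aids(q$aids_items), "aids item"))
}

wave_patient_carer_cost <- function(q, costs) {
  for (col in c("travel_miles", "lost_earnings", "oop_expenses",
                "carer_travel_miles", "carer_lost_earnings")) {
    if (!is.na(q[[col]]) && q[[col]] < 0)
      stop("negative reported amount in '", col, "' for patient ",
           q$patient_id, call. = FALSE)
  }
  (q$travel_miles + q$carer_travel_miles) * costs$petrol_rate +
    q$lost_earnings + q$oop_expenses + q$carer_lost_earnings
}

#' Post-hospital costs for one survivor
#'
#' Computes one-year post-hospital costs from the 6- and 12-month
#' questionnaires: the NHS component (primary, outpatient and community
#' visits at service unit costs, inpatient days, aids and equipment) and
#' the patient/carer component (patient plus carer travel miles at the
#' petrol rate, lost earnings, out-of-pocket expenses). Both components
#' are returned as missing unless both waves were returned; complete-case
#' and imputation handling happen downstream.
#'
#' @param questionnaires Questionnaire rows for a single patient (both
#'   waves).
#' @param costs A `unit_cost_table`.
#' @return A list with `nhs` and `patient_carer` (GBP, or `NA` when
#'   either wave is missing).
#' @export
cost_post_hospital <- function(questionnaires, costs) {
  q6 <- questionnaires[questionnaires$wave == "6m", , drop = FALSE]
  q12 <- questionnaires[questionnaires$wave == "12m", , drop = FALSE]
  both <- nrow(q6) == 1L && nrow(q12) == 1L && q6$returned && q12$returned
  if (!both) return(list(nhs = NA_real_, patient_carer = NA_real_))
  list(nhs = wave_nhs_cost(q6, costs) + wave_nhs_cost(q12, costs),
       patient_carer = wave_patient_carer_cost(q6, costs) +
         wave_patient_carer_cost(q12, costs))
}

#' Restate an amount in base-year prices
#'
#' Applies the hospital-and-community-health-services pay and prices
#' index: `amount * index[base_year] / index[from_year]`.
#'
#' @param amount GBP in `from_year` prices.
#' @param from_year Price year of `amount`.
#' @param costs A `unit_cost_table` carrying `hchs_index` and `base_year`.
#' @return GBP in base-year prices.
#' @export
inflate_cost <- function(amount, from_year, costs) {
  idx <- costs$hchs_index
  for (y in c(from_year, costs$base_year)) {
    if (!as.character(y) %in% names(idx))
      stop("year ", y, " absent from the HCHS index", call. = FALSE)
  }
  amount * unname(idx[as.character(costs$base_year)]) /
    unname(idx[as.character(from_year)])
}

#' Per-patient cost breakdown across care pathways
#'
#' Assembles the pathway components for one patient: initial ICU stay,
#' post-ICU hospital stay, post-hospital NHS and patient/carer costs
#' (missing unless both follow-up waves were returned, or the patient did
#' not survive the year, in which case they are 0). The societal total is
#' only formed when every component is present.
#'
#' @param patient One row of the patients table.
#' @param crfs Daily CRF rows for that patient.
#' @param questionnaires Questionnaire rows for that patient.
#' @param costs A `unit_cost_table`.
#' @param sae_events Optional SAE codes.
#' @return A one-row data frame with columns `patient_id`, `icu_cost`,
#'   `post_icu_hospital_cost`, `post_hospital_nhs_cost`,
#'   `patient_carer_cost`, `total_societal_cost`.
#' @export
assemble_breakdown <- function(patient, crfs, questionnaires, costs,
                               sae_events = character(0)) {
  stopifnot(nrow(patient) == 1L)
  ok <- function(expr, pathway) {
    tryCatch(expr, error = function(e)
      stop(pathway, " costing failed for patient ", patient$id, ": ",
           conditionMessage(e), call. = FALSE))
  }
  icu <- ok(cost_icu_stay(crfs, costs), "ICU")
  post_icu <- ok(cost_post_icu(patient, costs, sae_events), "post-ICU")
  if (patient$alive_1yr) {
    ph <- ok(cost_post_hospital(questionnaires, costs), "post-hospital")
    nhs <- ph$nhs
    pc <- ph$patient_carer
  } else {
    nhs <- 0
    pc <- 0
  }
  total <- if (is.na(nhs) || is.na(pc)) NA_real_ else icu + post_icu + nhs + pc
  data.frame(patient_id = patient$id, icu_cost = icu,
             post_icu_hospital_cost = post_icu,
             post_hospital_nhs_cost = nhs, patient_carer_cost = pc,
             total_societal_cost = total)
}

#' Cost breakdowns for a whole cohort
#'
#' Applies [assemble_breakdown()] to every patient. Additionally returns
#' the per-wave post-hospital components (NA for non-returned waves) that
#' the imputation stage consumes.
#'
#' @param cohort An `ards_cohort`.
#' @param costs A `unit_cost_table`.
#' @return A list with `breakdown` (one row per patient) and
#'   `wave_costs` (columns `patient_id`, `nhs_6m`, `nhs_12m`, `pc_6m`,
#'   `pc_12m`, survivors only).
#' @export
cost_cohort <- function(cohort, costs = default_unit_costs()) {
  p <- cohort$patients
  crf_split <- split(cohort$daily_crf,
                     factor(cohort$daily_crf$patient_id, levels = p$id))
  q_split <- split(cohort$questionnaires,
                   factor(cohort$questionnaires$patient_id, levels = p$id))
  rows <- lapply(seq_len(nrow(p)), function(i) {
    assemble_breakdown(p[i, ], crf_split[[i]], q_split[[i]], costs)
  })
  breakdown <- do.call(rbind, rows)

  surv <- p[p$alive_1yr, ]
  wave_costs <- do.call(rbind, lapply(surv$id, function(pid) {
    q <- q_split[[match(pid, p$id)]]
    one <- function(w, f) {
      qq <- q[q$wave == w & q$returned, , drop = FALSE]
      if (nrow(qq) != 1L) NA_real_ else f(qq[1, ], costs)
    }
    data.frame(patient_id = pid,
               nhs_6m = one("6m", wave_nhs_cost),
               nhs_12m = one("12m", wave_nhs_cost),
               pc_6m = one("6m", wave_patient_carer_cost),
               pc_12m = one("12m", wave_patient_carer_cost))
  }))
  list(breakdown = breakdown, wave_costs = wave_costs)
}
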