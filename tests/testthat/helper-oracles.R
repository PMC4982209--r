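# Independent brute-force oracles and tiny fixture builders. These
# deliberately recompute everything from first principles (plain loops,
# closed forms) and share no code with the package internals.

# UK TTO coefficients restated as a flat lookup, dimension x level.
oracle_eq5d <- function(state) {
  dec <- list(
    m = c(`1` = 0, `2` = 0.069, `3` = 0.314),
    s = c(`1` = 0, `2` = 0.104, `3` = 0.214),
    u = c(`1` = 0, `2` = 0.036, `3` = 0.094),
    p = c(`1` = 0, `2` = 0.123, `3` = 0.386),
    a = c(`1` = 0, `2` = 0.071, `3` = 0.236))
  d <- strsplit(state, "")[[1]]
  u <- 1
  if (any(d != "1")) u <- u - 0.081
  for (i in 1:5) u <- u - dec[[i]][[d[i]]]
  if (any(d == "3")) u <- u - 0.269
  u
}

# Plain-loop product-limit estimator.
oracle_km_surv <- function(times, events, at) {
  et <- sort(unique(times[events]))
  s <- 1
  for (t in et) {
    if (t > at) break
    n_risk <- sum(times >= t)
    n_event <- sum(times == t & events)
    s <- s * (1 - n_event / n_risk)
  }
  s
}

# Spreadsheet-style ICU costing: one row at a time, every item spelt out.
oracle_icu_cost <- function(crfs, costs) {
  total <- 0
  vent_daily <- (costs$vent_machine_price / costs$vent_machine_life_years +
                   costs$vent_annual_maintenance) / costs$vent_utilisation_days
  for (i in seq_len(nrow(crfs))) {
    r <- crfs[i, ]
    total <- total +
      costs$cost_per_organ_day[[as.character(r$organs_supported)]] +
      (if (r$on_rrt) costs$rrt_cost else 0) +
      r$xray_count * costs$xray_cost +
      (if (r$chest_drain) costs$chest_drain_cost else 0) +
      r$drug_antibiotic * costs$drug_costs[["antibiotic"]] +
      r$drug_sedative * costs$drug_costs[["sedative"]] +
      r$drug_muscle_relaxant * costs$drug_costs[["muscle_relaxant"]] +
      (if (r$on_ventilation) vent_daily else 0)
  }
  if (any(crfs$on_ventilation)) total <- total + costs$vent_circuit_cost
  total
}

# Exact one-year QALY of the two-component uniform death-day mixture
# (death day uniform on {1..30} w.p. pe, on {31..365} otherwise; death
# probability M; survivors fixed at 365), with fixed period utilities.
oracle_mixture_qaly <- function(M, pe, vent_days, u6, u12) {
  pd <- numeric(365)
  pd[1:30] <- M * pe / 30
  pd[31:365] <- M * (1 - pe) / 335
  p_alive <- 1 - M
  expected_overlap <- function(a, b) {
    vals <- pmax(0, pmin(1:365, b) - a)
    sum(pd * vals) + p_alive * (b - a)
  }
  u3 <- u6 - (u12 - u6) / 2
  u9 <- (u6 + u12) / 2
  (-0.4 * vent_days +
     u3 * expected_overlap(vent_days, 91.3) +
     u6 * expected_overlap(91.3, 182.6) +
     u9 * expected_overlap(182.6, 274) +
     u12 * expected_overlap(274, 365)) / 365.25
}

# Minimal hand-built patient rows (defaults: one-year survivor, 10 ICU
# days, ward step-down, no transfer or readmission).
make_patient <- function(id = 1L, icu_days = 10L, hospital_days = 20L,
                         vent_days = 5L, death_day = NA_integer_,
                         readmission_days = 0L, stepdown_level = "ward",
                         transfer = FALSE, age = 55, sex = "male",
                         apache2 = 20L, pf_ratio = 15, arm = "conventional") {
  data.frame(id = id, arm = arm, age = age, sex = sex, apache2 = apache2,
             pf_ratio = pf_ratio, prime_condition = "pneumonia",
             surgery_admission = FALSE, icu_days = icu_days,
             vent_days = vent_days, hospital_days = hospital_days,
             death_day = death_day,
             alive_1yr = is.na(death_day) || death_day > 365,
             discharged_to_other_hospital = transfer,
             readmission_days = readmission_days,
             stepdown_level = stepdown_level, stringsAsFactors = FALSE)
}

make_crf_day <- function(patient_id = 1L, day_index = 1L,
                         organs_supported = 2L, on_ventilation = FALSE,
                         on_rrt = FALSE, xray_count = 0L,
                         chest_drain = FALSE, drug_antibiotic = 0L,
                         drug_sedative = 0L, drug_muscle_relaxant = 0L) {
  data.frame(patient_id = patient_id, day_index = day_index,
             organs_supported = organs_supported,
             on_ventilation = on_ventilation, on_rrt = on_rrt,
             xray_count = xray_count, chest_drain = chest_drain,
             drug_antibiotic = drug_antibiotic,
             drug_sedative = drug_sedative,
             drug_muscle_relaxant = drug_muscle_relaxant,
             stringsAsFactors = FALSE)
}

make_questionnaire <- function(patient_id = 1L, wave = "6m",
                               returned = TRUE, eq5d_state = "11111",
                               gp_visits = 0L, outpatient_visits = 0L,
                               community_visits = 0L, inpatient_days = 0L,
                               aids_items = "", travel_miles = 0L,
                               lost_earnings = 0, oop_expenses = 0,
                               carer_travel_miles = 0L,
                               carer_lost_earnings = 0) {
  df <- data.frame(patient_id = patient_id, wave = wave, returned = returned,
                   eq5d_state = eq5d_state, gp_visits = gp_visits,
                   outpatient_visits = outpatient_visits,
                   community_visits = community_visits,
                   inpatient_days = inpatient_days, aids_items = aids_items,
                   travel_miles = travel_miles, lost_earnings = lost_earnings,
                   oop_expenses = oop_expenses,
                   carer_travel_miles = carer_travel_miles,
                   carer_lost_earnings = carer_lost_earnings,
                   stringsAsFactors = FALSE)
  if (!returned) df[setdiff(names(df), c("patient_id", "wave", "returned"))] <-
      NA
  df
}

# Patient table encoding given death counts by location, as in a trial
# flow chart: ICU deaths, post-ICU in-hospital deaths, post-discharge
# deaths within the year, and survivors making up the remainder of n.
patients_from_counts <- function(icu_deaths, hospital_deaths, late_deaths,
                                 n) {
  survivors <- n - icu_deaths - hospital_deaths - late_deaths
  rows <- list()
  add <- function(k, death_day, icu_days, hospital_days) {
    if (k > 0)
      rows[[length(rows) + 1]] <<- do.call(rbind, lapply(seq_len(k),
        function(i) make_patient(id = length(rows) * 10000L + i,
                                 icu_days = icu_days,
                                 hospital_days = hospital_days,
                                 vent_days = 1L, death_day = death_day)))
  }
  add(icu_deaths, death_day = 5L, icu_days = 10L, hospital_days = 15L)
  add(hospital_deaths, death_day = 12L, icu_days = 10L, hospital_days = 15L)
  add(late_deaths, death_day = 100L, icu_days = 10L, hospital_days = 15L)
  add(survivors, death_day = NA_integer_, icu_days = 10L,
      hospital_days = 15L)
  p <- do.call(rbind, rows)
  p$id <- seq_len(nrow(p))
  p
}

# Scale every monetary entry of a unit-cost table by a factor (leaves
# non-monetary assumptions -- life years, utilisation, index -- alone).
scale_unit_costs <- function(costs, factor) {
  money <- c("rrt_cost", "xray_cost", "chest_drain_cost",
             "vent_machine_price", "vent_annual_maintenance",
             "vent_circuit_cost", "transfer_cost", "inpatient_cost_per_day",
             "petrol_rate", "cost_per_organ_day", "drug_costs",
             "stepdown_cost_per_day", "sae_costs", "visit_costs",
             "aids_costs")
  for (f in money) costs[[f]] <- costs[[f]] * factor
  costs
}

# Reported monetary amounts (lost earnings, out-of-pocket items) are data
# the engine passes through, not unit costs; the full cost map is linear
# once they are scaled alongside the unit-cost table.
scale_reported_money <- function(cohort, factor) {
  for (f in c("lost_earnings", "oop_expenses", "carer_lost_earnings"))
    cohort$questionnaires[[f]] <- cohort$questionnaires[[f]] * factor
  cohort
}
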