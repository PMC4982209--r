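# Summary surfaces: mortality and response rates, baseline comparison,
# subgroup cost tables, cost per one-year survivor, ICER.

#' In-hospital and one-year mortality rates
#'
#' Deaths are classified from the episode timeline: during the initial
#' ICU stay (`death_day <= icu_days`), in hospital after ICU discharge
#' (`icu_days < death_day <= hospital_days`) or after hospital discharge
#' but within the year. Rates are percentages of randomised patients,
#' reported to one decimal place.
#'
#' @param patients Patients table with complete vital-status fields.
#' @return List with `in_hospital_rate`, `one_year_rate` (percent, 1 dp)
#'   and `counts` (icu_deaths, post_icu_hospital_deaths,
#'   post_discharge_deaths, n).
#' @export
mortality_rates <- function(patients) {
  bad <- which(patients$alive_1yr != (is.na(patients$death_day) |
                                        patients$death_day > 365))
  if (length(bad))
    stop("inconsistent vital status for patient id ",
         patients$id[bad[1]], call. = FALSE)
  d <- patients$death_day
  icu_deaths <- sum(!is.na(d) & d <= patients$icu_days)
  hosp_deaths <- sum(!is.na(d) & d > patients$icu_days &
                       d <= patients$hospital_days)
  late_deaths <- sum(!is.na(d) & d > patients$hospital_days & d <= 365)
  n <- nrow(patients)
  list(in_hospital_rate = round(100 * (icu_deaths + hosp_deaths) / n, 1),
       one_year_rate = round(100 * (icu_deaths + hosp_deaths + late_deaths) /
                               n, 1),
       counts = c(icu_deaths = icu_deaths,
                  post_icu_hospital_deaths = hosp_deaths,
                  post_discharge_deaths = late_deaths, n = n))
}

#' Questionnaire response rate at a wave
#'
#' Returned questionnaires over eligible survivors, as a percentage to
#' one decimal place.
#'
#' @param questionnaires Questionnaire table.
#' @param survivors Number of eligible survivors at the wave (the
#'   denominator), or a patients table from which one-year survivors are
#'   counted for the 12-month wave.
#' @param wave `"6m"` or `"12m"`.
#' @return Percentage (1 dp).
#' @export
response_rate <- function(questionnaires, survivors, wave = c("12m", "6m")) {
  wave <- match.arg(wave)
  if (is.data.frame(survivors)) survivors <- sum(survivors$alive_1yr)
  if (survivors <= 0) stop("survivor denominator must be > 0", call. = FALSE)
  returned <- sum(questionnaires$wave == wave & questionnaires$returned)
  round(100 * returned / survivors, 1)
}

summary_row <- function(label, x) {
  n <- length(x)
  m <- mean(x)
  qs <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  if (n >= 2) {
    se <- stats::sd(x) / sqrt(n)
    lo <- m - stats::qnorm(0.975) * se
    hi <- m + stats::qnorm(0.975) * se
  } else {
    lo <- hi <- NA_real_   # group of one: CI undefined
  }
  data.frame(label = label, n = n, mean = m, ci_lo = lo, ci_hi = hi,
             median = qs[2], q25 = qs[1], q75 = qs[3],
             stringsAsFactors = FALSE)
}

subgroup_factor <- function(patients, grouping, apache_cut = 26) {
  switch(grouping,
         none = factor(rep("all", nrow(patients))),
         age = factor(ifelse(patients$age < 65, "age<65", "age>=65")),
         sex = factor(patients$sex),
         apache = factor(ifelse(patients$apache2 < apache_cut,
                                paste0("APACHE<", apache_cut),
                                paste0("APACHE>=", apache_cut))),
         pf = factor(ifelse(patients$pf_ratio < 15, "PF<15", "PF>=15")),
         prime_condition = factor(patients$prime_condition),
         surgery = factor(ifelse(patients$surgery_admission, "surgery",
                                 "no surgery")),
         arm = factor(patients$arm),
         icu_los = factor(ifelse(patients$icu_days <= 15, "ICU los<=15",
                                 "ICU los>15")),
         stop("unknown grouping '", grouping, "'", call. = FALSE))
}

#' Subgroup cost summaries
#'
#' Mean with normal-based 95% CI, median and quartiles of a cost
#' component within patient subgroups defined by the published
#' cut-points: age 65 years, APACHE II 26 (22 also used in the source
#' tables; configurable), PaO2:FiO2 15 kPa, ICU stay 15 days.
#'
#' @param breakdowns Cost-breakdown table from [cost_cohort()] (or any
#'   data frame with `patient_id` and the `value` column).
#' @param patients Patients table.
#' @param grouping One of `"none"`, `"age"`, `"sex"`, `"apache"`, `"pf"`,
#'   `"prime_condition"`, `"surgery"`, `"arm"`, `"icu_los"`.
#' @param value Column of `breakdowns` to summarise.
#' @param apache_cut APACHE II cut-point (default 26).
#' @return Data frame of summary rows (label, n, mean, ci_lo, ci_hi,
#'   median, q25, q75). Rows with missing `value` are dropped.
#' @export
summarise_costs <- function(breakdowns, patients, grouping = "none",
                            value = "total_societal_cost",
                            apache_cut = 26) {
  if (!value %in% names(breakdowns))
    stop("no column '", value, "' in the breakdown table", call. = FALSE)
  g <- subgroup_factor(patients, grouping, apache_cut)
  x <- breakdowns[[value]][match(patients$id, breakdowns$patient_id)]
  keep <- !is.na(x)
  rows <- lapply(levels(g), function(lev) {
    xs <- x[keep & g == lev]
    if (length(xs) == 0L) return(NULL)
    summary_row(lev, xs)
  })
  do.call(rbind, rows)
}

#' Total societal cost per one-year survivor
#'
#' The sum of total (ICU + hospital + post-hospital) costs over all
#' randomised patients divided by the number of patients alive one year
#' after randomisation.
#'
#' @param breakdowns Cost-breakdown table with complete
#'   `total_societal_cost` (post-imputation).
#' @param patients Patients table.
#' @return GBP per survivor.
#' @export
cost_per_survivor <- function(breakdowns, patients) {
  total <- breakdowns$total_societal_cost
  if (anyNA(total))
    stop("total costs must be complete (impute post-hospital costs first)",
         call. = FALSE)
  survivors <- sum(patients$alive_1yr)
  if (survivors == 0) stop("no one-year survivors", call. = FALSE)
  sum(total) / survivors
}

#' Incremental cost-effectiveness ratio
#'
#' `(mean cost in HFOV - mean cost in conventional) / (mean QALY in HFOV
#' - mean QALY in conventional)`, with dominance handling: an
#' intervention that gains QALYs at no extra (or lower) cost is dominant;
#' one that loses QALYs at extra (or equal) cost is dominated. A zero
#' QALY difference leaves the ratio undefined.
#'
#' @param costs_by_arm Named numeric vector/list with elements
#'   `conventional` and `hfov` (mean 1-year costs).
#' @param qalys_by_arm Same structure for mean QALYs.
#' @return List of class `icer_result`: `delta_cost`, `delta_qaly`,
#'   `icer` (NA unless defined), `status` in
#'   `{"icer", "dominant", "dominated", "undefined"}`.
#' @export
icer <- function(costs_by_arm, qalys_by_arm) {
  dc <- costs_by_arm[["hfov"]] - costs_by_arm[["conventional"]]
  dq <- qalys_by_arm[["hfov"]] - qalys_by_arm[["conventional"]]
  if (dq == 0) {
    out <- list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
                status = "undefined")
  } else {
    status <- if (dq > 0 && dc <= 0) "dominant"
    else if (dq < 0 && dc >= 0) "dominated"
    else "icer"
    out <- list(delta_cost = dc, delta_qaly = dq, icer = dc / dq,
                status = status)
  }
  structure(out, class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("Incremental cost %.0f GBP, incremental QALY %.4f: ",
              x$delta_cost, x$delta_qaly))
  cat(switch(x$status,
             undefined = "ICER undefined (zero QALY difference)",
             dominant = sprintf("intervention dominant (ICER %.0f)", x$icer),
             dominated = sprintf("intervention dominated (ICER %.0f)",
                                 x$icer),
             icer = sprintf("ICER %.0f GBP/QALY", x$icer)), "\n")
  invisible(x)
}

#' Baseline comparison of survivors and non-survivors
#'
#' Welch t tests for continuous baseline variables and chi-squared tests
#' for categorical ones, comparing one-year survivors with
#' non-survivors; no multiple-testing correction is applied.
#'
#' @param patients Patients table.
#' @return Data frame with columns `variable`, `type`,
#'   `survivor_summary`, `nonsurvivor_summary`, `p`.
#' @export
baseline_table <- function(patients) {
  s <- patients$alive_1yr
  cont <- c("age", "apache2", "pf_ratio", "icu_days", "hospital_days")
  cat_vars <- list(female = patients$sex == "female",
                   pneumonia = patients$prime_condition == "pneumonia",
                   surgery = patients$surgery_admission)
  rows <- lapply(cont, function(v) {
    x <- patients[[v]]
    p <- stats::t.test(x[s], x[!s])$p.value
    data.frame(variable = v, type = "continuous",
               survivor_summary = sprintf("%.1f [%.1f]", mean(x[s]),
                                          stats::sd(x[s])),
               nonsurvivor_summary = sprintf("%.1f [%.1f]", mean(x[!s]),
                                             stats::sd(x[!s])),
               p = p, stringsAsFactors = FALSE)
  })
  rows2 <- lapply(names(cat_vars), function(v) {
    x <- cat_vars[[v]]
    p <- suppressWarnings(stats::chisq.test(table(x, s))$p.value)
    data.frame(variable = v, type = "categorical",
               survivor_summary = sprintf("%d (%.1f%%)", sum(x & s),
                                          100 * mean(x[s])),
               nonsurvivor_summary = sprintf("%d (%.1f%%)", sum(x & !s),
                                             100 * mean(x[!s])),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, rows2))
}
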