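# End-to-end evaluation: simulate (or load) a cohort, score utilities,
# cost every pathway, impute missing post-hospital costs, estimate
# quality-adjusted survival, and assemble the report tables.

#' Run the full one-year economic evaluation
#'
#' Chains every stage over a cohort: EQ-5D scoring of the follow-up
#' questionnaires, bottom-up costing of each care pathway, truncated
#' multiple imputation of post-hospital costs among one-year survivors
#' (pooled by Rubin's rules), Kaplan-Meier partitioned quality-adjusted
#' survival, mortality/response rates, subgroup cost tables, cost per
#' survivor and the arm-vs-arm ICER. Fully deterministic for a fixed
#' configuration: running twice yields identical results.
#'
#' @param config A [cohort_config()]; its `seed` drives every stage.
#' @param cohort Optional pre-built `ards_cohort` (e.g. from
#'   [read_cohort()]); generated from `config` when omitted.
#' @param unit_costs A `unit_cost_table`.
#' @param tariff EQ-5D tariff coefficients.
#' @param spec An [imputation_spec()]; its seed is taken from `config`.
#' @param boot Bootstrap resamples for the QALY interval.
#' @param groupings Subgroup tables to produce.
#' @return An object of class `ards_eval`; see Details.
#' @details The returned list contains `cohort`, `baseline` (survivor vs
#'   non-survivor comparison), `mortality`, `response`, `utilities` (per
#'   wave), `breakdown` (per-patient costs with imputed totals averaged
#'   over the m datasets), `pooled_post_hospital` (Rubin-pooled mean),
#'   `qaly` (a `qaly_result`), `qaly_by_arm`, `cost_tables`,
#'   `cost_per_survivor`, `icer` and `log` (seed and versions).
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         unit_costs = default_unit_costs(),
                         tariff = uk_tto_tariff(),
                         spec = imputation_spec(seed = config$seed),
                         boot = 1000,
                         groupings = c("none", "age", "sex", "apache", "pf",
                                       "prime_condition", "surgery", "arm",
                                       "icu_los")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("simulate", generate_cohort(config, tariff))
  p <- cohort$patients
  q <- cohort$questionnaires

  utilities <- stage("score", list(
    m6 = mean_wave_utility(q, "6m", tariff),
    m12 = mean_wave_utility(q, "12m", tariff)))

  costed <- stage("cost", cost_cohort(cohort, unit_costs))
  breakdown <- costed$breakdown

  # impute the four wave-level post-hospital cost components among
  # one-year survivors, then average the completed totals over the m
  # datasets for per-patient reporting
  wave <- costed$wave_costs
  pooled_post_hospital <- NULL
  if (nrow(wave) > 0L) {
    imputed <- stage("impute", {
      cov <- p[match(wave$patient_id, p$id),
               c("age", "sex", "apache2", "pf_ratio", "arm", "icu_days")]
      impute_costs(wave[-1], cov, spec)
    })
    post_totals <- vapply(imputed, function(d)
      rowSums(as.matrix(d)), numeric(nrow(wave)))
    pooled_post_hospital <- rubin_pool(
      colMeans(post_totals),
      apply(post_totals, 2, function(x) stats::var(x) / length(x)))

    idx <- match(wave$patient_id, breakdown$patient_id)
    nhs_pc <- vapply(imputed, function(d)
      c(rowSums(as.matrix(d[c("nhs_6m", "nhs_12m")])),
        rowSums(as.matrix(d[c("pc_6m", "pc_12m")]))),
      numeric(2 * nrow(wave)))
    breakdown$post_hospital_nhs_cost[idx] <-
      rowMeans(nhs_pc)[seq_len(nrow(wave))]
    breakdown$patient_carer_cost[idx] <-
      rowMeans(nhs_pc)[nrow(wave) + seq_len(nrow(wave))]
    breakdown$total_societal_cost <- breakdown$icu_cost +
      breakdown$post_icu_hospital_cost + breakdown$post_hospital_nhs_cost +
      breakdown$patient_carer_cost
  }

  qaly_fit <- stage("qaly", {
    times <- ifelse(is.na(p$death_day), 365, pmin(p$death_day, 365))
    quality_adjusted_survival(times, !p$alive_1yr, p$vent_days,
                              utilities$m6$mean, utilities$m12$mean,
                              tariff$unconscious_utility, boot = boot,
                              seed = config$seed)
  })

  qaly_by_arm <- stage("qaly", {
    lapply(stats::setNames(nm = c("conventional", "hfov")), function(a) {
      sel <- p$arm == a
      qs <- q[q$patient_id %in% p$id[sel], , drop = FALSE]
      u6 <- mean_wave_utility(qs, "6m", tariff)$mean
      u12 <- mean_wave_utility(qs, "12m", tariff)$mean
      times <- ifelse(is.na(p$death_day[sel]), 365,
                      pmin(p$death_day[sel], 365))
      quality_adjusted_survival(times, !p$alive_1yr[sel], p$vent_days[sel],
                                u6, u12, tariff$unconscious_utility,
                                boot = 0)$qaly
    })
  })

  cost_tables <- stage("report", {
    lapply(stats::setNames(nm = groupings), function(g)
      summarise_costs(breakdown, p, g))
  })

  mean_cost_by_arm <- lapply(stats::setNames(nm = c("conventional", "hfov")),
                             function(a) {
                               sel <- breakdown$patient_id %in% p$id[p$arm == a]
                               mean(breakdown$total_societal_cost[sel])
                             })

  result <- list(
    cohort = cohort,
    baseline = stage("report", baseline_table(p)),
    mortality = stage("report", mortality_rates(p)),
    response = list(
      m6 = response_rate(q, sum(is.na(p$death_day) | p$death_day > 183),
                         "6m"),
      m12 = response_rate(q, p, "12m")),
    utilities = utilities,
    breakdown = breakdown,
    pooled_post_hospital = pooled_post_hospital,
    qaly = qaly_fit,
    qaly_by_arm = qaly_by_arm,
    cost_tables = cost_tables,
    cost_per_survivor = stage("report", cost_per_survivor(breakdown, p)),
    icer = stage("report", icer(mean_cost_by_arm, qaly_by_arm)),
    log = list(seed = config$seed, n_patients = nrow(p),
               package_version = as.character(
                 utils::packageVersion("ardsecon"))))
  class(result) <- "ards_eval"
  result
}

#' @export
print.ards_eval <- function(x, ...) {
  p <- x$cohort$patients
  cat("One-year economic evaluation of an ARDS cohort (n =", nrow(p), ")\n")
  cat(sprintf("  mortality: %.1f%% in hospital, %.1f%% at one year\n",
              x$mortality$in_hospital_rate, x$mortality$one_year_rate))
  cat(sprintf("  EQ-5D means: %.4f at 6m (n=%d), %.4f at 12m (n=%d)\n",
              x$utilities$m6$mean, x$utilities$m6$n,
              x$utilities$m12$mean, x$utilities$m12$n))
  cat(sprintf("  quality-adjusted survival: %.4f QALY", x$qaly$qaly))
  if (!anyNA(x$qaly$ci))
    cat(sprintf(" (%.4f-%.4f)", x$qaly$ci[1], x$qaly$ci[2]))
  cat("\n")
  cat(sprintf("  mean societal cost: %.0f GBP; cost per survivor: %.0f GBP\n",
              mean(x$breakdown$total_societal_cost), x$cost_per_survivor))
  print(x$icer)
  invisible(x)
}

#' @export
summary.ards_eval <- function(object, ...) {
  cat("Cohort baseline (survivors vs non-survivors):\n")
  print(object$baseline, row.names = FALSE)
  cat("\nCosts at one year (all patients):\n")
  print(object$cost_tables$none, row.names = FALSE)
  cat("\nCosts by ventilation arm:\n")
  print(object$cost_tables$arm, row.names = FALSE)
  cat("\n")
  print(object)
  invisible(object)
}

#' Write an evaluation report bundle to disk
#'
#' Emits the cohort CSVs, the per-patient cost breakdown, the subgroup
#' cost tables, a JSON summary (rates, utilities, QALY, pooled costs,
#' ICER) and a plain-text run log. Deterministic: no timestamps, so two
#' runs with the same configuration produce byte-identical bundles.
#'
#' @param result An `ards_eval` from [run_pipeline()].
#' @param directory Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- write_cohort(result$cohort, directory)
  bpath <- file.path(directory, "cost_breakdown.csv")
  utils::write.csv(result$breakdown, bpath, row.names = FALSE, na = "")
  tpaths <- vapply(names(result$cost_tables), function(g) {
    fp <- file.path(directory, paste0("costs_by_", g, ".csv"))
    utils::write.csv(result$cost_tables[[g]], fp, row.names = FALSE)
    fp
  }, character(1))
  summary_json <- file.path(directory, "summary.json")
  jsonlite::write_json(list(
    mortality = result$mortality[c("in_hospital_rate", "one_year_rate")],
    response = result$response,
    utilities = list(m6 = result$utilities$m6$mean,
                     m12 = result$utilities$m12$mean),
    qaly = list(mean = result$qaly$qaly, ci = result$qaly$ci,
                by_arm = result$qaly_by_arm),
    pooled_post_hospital = result$pooled_post_hospital[
      c("point", "ci", "total_var")],
    cost_per_survivor = result$cost_per_survivor,
    icer = unclass(result$icer)),
    summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_path <- file.path(directory, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", result$log$seed),
    sprintf("n_patients: %d", result$log$n_patients),
    sprintf("ardsecon_version: %s", result$log$package_version),
    sprintf("qaly: %.6f", result$qaly$qaly)), log_path)
  invisible(c(paths, bpath, tpaths, summary_json, log_path))
}
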