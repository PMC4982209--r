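costs <- default_unit_costs()

test_that("ventilator amortisation follows the fixed-cost formula", {
  free <- costs
  free$vent_machine_price <- 0
  free$vent_annual_maintenance <- 0
  expect_equal(daily_vent_cost(free), 0)

  c2 <- costs
  c2$vent_machine_price <- 18250
  c2$vent_machine_life_years <- 5
  c2$vent_annual_maintenance <- 0
  expect_equal(daily_vent_cost(c2, 365), 10)
  c2$vent_annual_maintenance <- 365
  expect_equal(daily_vent_cost(c2, 365), 11)
  expect_error(daily_vent_cost(c2, 0), "> 0")
})

test_that("ICU stay costing is a sum of unit cost times volume", {
  expect_equal(cost_icu_stay(make_crf_day()[0, ], costs), 0)

  c2 <- costs
  c2$cost_per_organ_day[["2"]] <- 1000
  c2$xray_cost <- 50
  crfs <- rbind(make_crf_day(1, 1, organs_supported = 2),
                make_crf_day(1, 2, organs_supported = 2, xray_count = 1))
  expect_equal(cost_icu_stay(crfs, c2), 2050)

  expect_error(cost_icu_stay(make_crf_day(organs_supported = 9L), costs),
               "'9'")
  expect_error(cost_icu_stay(rbind(make_crf_day(1), make_crf_day(2)), costs),
               "single patient")
})

test_that("mixed-day fixtures equal the row-by-row oracle", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(1:12, 1)
    crfs <- do.call(rbind, lapply(seq_len(k), function(d)
      make_crf_day(1, d, organs_supported = sample(0:6, 1),
                   on_ventilation = runif(1) < 0.5,
                   on_rrt = runif(1) < 0.3,
                   xray_count = rpois(1, 0.5),
                   chest_drain = runif(1) < 0.1,
                   drug_antibiotic = rpois(1, 2),
                   drug_sedative = rpois(1, 1),
                   drug_muscle_relaxant = rpois(1, 0.5))))
    expect_equal(cost_icu_stay(crfs, costs), oracle_icu_cost(crfs, costs))
  }
})

test_that("post-ICU costing covers step-down, readmission and transfer", {
  p0 <- make_patient(icu_days = 10L, hospital_days = 10L)
  expect_equal(cost_post_icu(p0, costs), 0)

  # 10 ward days at the configured 297/day
  p1 <- make_patient(icu_days = 10L, hospital_days = 20L)
  expect_equal(cost_post_icu(p1, costs), 10 * 297)

  # hand-summed: 8 ward days + 4 readmission days at ICU rate + transfer
  p2 <- make_patient(icu_days = 10L, hospital_days = 22L,
                     readmission_days = 4L, transfer = TRUE)
  expect_equal(cost_post_icu(p2, costs),
               8 * 297 + 4 * costs$stepdown_cost_per_day[["icu"]] +
                 costs$transfer_cost)

  # death during the post-ICU stay truncates the days billed
  p3 <- make_patient(icu_days = 10L, hospital_days = 30L, death_day = 15L)
  expect_equal(cost_post_icu(p3, costs), 5 * 297)

  # death in ICU: no post-ICU cost
  p4 <- make_patient(icu_days = 10L, hospital_days = 30L, death_day = 5L)
  expect_equal(cost_post_icu(p4, costs), 0)

  p5 <- make_patient(stepdown_level = "palace")
  expect_error(cost_post_icu(p5, costs), "'palace'")

  expect_equal(cost_post_icu(p1, costs, sae_events = "pneumothorax"),
               10 * 297 + costs$sae_costs[["pneumothorax"]])
})

test_that("post-hospital costs need both waves and price items correctly", {
  both_zero <- rbind(make_questionnaire(1, "6m"),
                     make_questionnaire(1, "12m"))
  res <- cost_post_hospital(both_zero, costs)
  expect_equal(res$nhs, 0)
  expect_equal(res$patient_carer, 0)

  miles <- rbind(make_questionnaire(1, "6m", travel_miles = 100L),
                 make_questionnaire(1, "12m"))
  expect_equal(cost_post_hospital(miles, costs)$patient_carer, 100 * 0.45)

  one_wave <- make_questionnaire(1, "6m")
  expect_true(is.na(cost_post_hospital(one_wave, costs)$nhs))
  not_returned <- rbind(make_questionnaire(1, "6m"),
                        make_questionnaire(1, "12m", returned = FALSE))
  expect_true(is.na(cost_post_hospital(not_returned, costs)$patient_carer))

  neg <- rbind(make_questionnaire(1, "6m", lost_earnings = -5),
               make_questionnaire(1, "12m"))
  expect_error(cost_post_hospital(neg, costs), "negative")

  items <- rbind(make_questionnaire(1, "6m", gp_visits = 2L,
                                    inpatient_days = 3L,
                                    aids_items = "wheelchair;other"),
                 make_questionnaire(1, "12m", outpatient_visits = 1L))
  expect_equal(cost_post_hospital(items, costs)$nhs,
               2 * 45 + 3 * 305 + 220 + 75 + 135)
})

test_that("price-year adjustment uses the index ratio", {
  expect_equal(inflate_cost(100, 2012, costs), 100)
  c2 <- costs
  c2$hchs_index <- c(`2010` = 270, `2012` = 280)
  expect_equal(round(inflate_cost(100, 2010, c2), 2), 103.70)
  expect_equal(inflate_cost(0, 2010, c2), 0)
  expect_error(inflate_cost(100, 1999, costs), "1999")
})

test_that("breakdowns respect pathway logic and sum to an oracle total", {
  # patient who died in ICU: only the ICU pathway accrues cost
  p <- make_patient(icu_days = 3L, hospital_days = 3L, death_day = 2L,
                    vent_days = 2L)
  crfs <- rbind(make_crf_day(1, 1, on_ventilation = TRUE),
                make_crf_day(1, 2, on_ventilation = TRUE),
                make_crf_day(1, 3))
  bd <- assemble_breakdown(p, crfs, make_questionnaire(1)[0, ], costs)
  expect_equal(bd$post_icu_hospital_cost, 0)
  expect_equal(bd$post_hospital_nhs_cost, 0)
  expect_equal(bd$total_societal_cost, bd$icu_cost)

  # fixture survivor: components equal independently hand-computed sums
  p2 <- make_patient(icu_days = 2L, hospital_days = 7L)
  crfs2 <- rbind(make_crf_day(1, 1, organs_supported = 3L, on_rrt = TRUE),
                 make_crf_day(1, 2, organs_supported = 1L, xray_count = 2L))
  q2 <- rbind(make_questionnaire(1, "6m", gp_visits = 1L,
                                 travel_miles = 10L),
              make_questionnaire(1, "12m", lost_earnings = 100))
  bd2 <- assemble_breakdown(p2, crfs2, q2, costs)
  expect_equal(bd2$icu_cost, oracle_icu_cost(crfs2, costs))
  expect_equal(bd2$post_icu_hospital_cost, 5 * 297)
  expect_equal(bd2$post_hospital_nhs_cost, 45)
  expect_equal(bd2$patient_carer_cost, 10 * 0.45 + 100)
  expect_equal(bd2$total_societal_cost,
               bd2$icu_cost + 5 * 297 + 45 + 104.5)

  # survivor with a missing wave: post-hospital missing, total missing
  q3 <- make_questionnaire(1, "6m")
  bd3 <- assemble_breakdown(p2, crfs2, q3, costs)
  expect_true(is.na(bd3$post_hospital_nhs_cost))
  expect_true(is.na(bd3$total_societal_cost))
})

test_that("cohort costing equals the naive oracle and is exactly linear", {
  coh <- generate_cohort(cohort_config(n_patients = 50, seed = 19))
  res <- cost_cohort(coh, costs)
  crf_split <- split(coh$daily_crf, coh$daily_crf$patient_id)
  for (i in seq_len(nrow(coh$patients))) {
    pid <- coh$patients$id[i]
    crfs <- crf_split[[as.character(pid)]]
    if (is.null(crfs)) crfs <- coh$daily_crf[0, ]
    expect_equal(res$breakdown$icu_cost[i], oracle_icu_cost(crfs, costs))
  }
  # doubling every unit cost (and the reported pass-through amounts,
  # which are data rather than unit costs) exactly doubles every
  # component: factor 2 is exact in binary floating point
  res2 <- cost_cohort(scale_reported_money(coh, 2),
                      scale_unit_costs(costs, 2))
  for (col in c("icu_cost", "post_icu_hospital_cost",
                "post_hospital_nhs_cost", "patient_carer_cost",
                "total_societal_cost")) {
    expect_equal(res2$breakdown[[col]], 2 * res$breakdown[[col]])
  }
  # non-negativity and component additivity of present totals
  num <- res$breakdown[-1]
  expect_true(all(num >= 0, na.rm = TRUE))
  complete <- !is.na(res$breakdown$total_societal_cost)
  expect_equal(res$breakdown$total_societal_cost[complete],
               unname(rowSums(num[complete,
                                  c("icu_cost", "post_icu_hospital_cost",
                                    "post_hospital_nhs_cost",
                                    "patient_carer_cost")])))
})

test_that("ICU dominates hospital costs at a realistic share", {
  coh <- generate_cohort(cohort_config(n_patients = 1000, seed = 23))
  res <- cost_cohort(coh, costs)
  share <- sum(res$breakdown$icu_cost) /
    sum(res$breakdown$icu_cost + res$breakdown$post_icu_hospital_cost)
  expect_gt(share, 0.6)
  expect_lt(share, 0.8)
})
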