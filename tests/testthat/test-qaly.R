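test_that("product-limit estimator matches hand-worked curves", {
  # all censored at the horizon: flat at 1
  c1 <- km_estimate(rep(365, 5), rep(FALSE, 5))
  expect_equal(restricted_mean(c1, 0, 365), 365 / 365.25)

  # {1,2,3} with events {yes,no,yes}: S(1)=2/3, S(3)=0
  c2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(c2$surv, c(2 / 3, 0))
  expect_equal(c2$time, c(1, 3))

  # single patient dying at day 10: step from 1 to 0
  c3 <- km_estimate(10, TRUE)
  expect_equal(c3$surv, 0)
  expect_equal(restricted_mean(c3, 0, 365), 10 / 365.25)

  expect_error(km_estimate(numeric(0), logical(0)), "no observations")
})

test_that("product-limit estimator agrees with oracle and survfit on random fixtures", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    times <- sample(1:400, n, replace = TRUE)
    events <- runif(n) < 0.7
    if (!any(events)) events[1] <- TRUE
    fit <- km_estimate(times, events)
    # brute-force product-limit oracle at every event time
    for (j in seq_along(fit$time)) {
      expect_equal(fit$surv[j], oracle_km_surv(times, events, fit$time[j]))
    }
    # independent cross-check against the survival package
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(fit$time, sf$time[sf$n.event > 0])
    expect_equal(fit$surv, sf$surv[sf$n.event > 0])
  }
})

test_that("restricted means integrate the step function exactly", {
  # S = 0.5 after day 0 events: area over [0,100] is 50 days
  c1 <- km_estimate(c(0.5, rep(365, 1)), c(TRUE, FALSE))
  expect_equal(restricted_mean(c1, 1, 101), 50 / 365.25)

  # additivity over a partition equals the area over the union
  c2 <- km_estimate(c(20, 80, 150, 365, 365),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE))
  parts <- restricted_mean(c2, 0, 91.3) + restricted_mean(c2, 91.3, 240) +
    restricted_mean(c2, 240, 365)
  expect_equal(parts, restricted_mean(c2, 0, 365))

  expect_error(restricted_mean(c2, -1, 10), "0 <= a < b")
  expect_error(restricted_mean(c2, 0, 400), "0 <= a < b")
})

test_that("mid-point utilities lie on the 6-to-12-month line", {
  expect_equal(interpolate_utilities(0.6, 0.6), c(u3 = 0.6, u9 = 0.6))
  expect_equal(interpolate_utilities(0.5622, 0.5831)[["u9"]], 0.57265)
  expect_equal(interpolate_utilities(0.4, 0.6)[["u3"]], 0.3)
})

test_that("quality-adjusted survival has the right closed-form limits", {
  n <- 50
  full <- quality_adjusted_survival(rep(365, n), rep(FALSE, n),
                                    vent_days = 0, u6 = 1, u12 = 1,
                                    boot = 0)
  expect_equal(full$qaly, 365 / 365.25)

  dead <- quality_adjusted_survival(rep(0.01, n), rep(TRUE, n),
                                    vent_days = 0, u6 = 1, u12 = 1,
                                    boot = 0)
  expect_lt(dead$qaly, 1e-4)

  # utilities 1 and no ventilation: QALY equals restricted-mean survival
  set.seed(7)
  times <- pmin(365, sample(1:500, 60, replace = TRUE))
  events <- times < 365
  res <- quality_adjusted_survival(times, events, vent_days = 0,
                                   u6 = 1, u12 = 1, boot = 0)
  expect_equal(res$qaly,
               restricted_mean(km_estimate(times, events), 0, 365))

  # decomposition identity: qaly = vent term + sum of area * utility
  res2 <- quality_adjusted_survival(times, events, vent_days = 9,
                                    u6 = 0.5, u12 = 0.7, boot = 0)
  expect_equal(res2$qaly,
               -0.4 * res2$vent_period_years +
                 sum(res2$period_areas * res2$period_utilities[-1]))
  expect_lte(sum(res2$period_areas), 1)
  expect_error(quality_adjusted_survival(times, events, vent_days = 100,
                                         u6 = 0.5, u12 = 0.7),
               "first period")
})

test_that("QALY stays within its survival-implied bounds", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    times <- pmin(365, sample(1:700, n, replace = TRUE))
    events <- times < 365
    vent <- runif(1, 0, 60)
    u6 <- runif(1, -0.4, 0.9)
    u12 <- u6 + runif(1, -0.1, 0.1)  # keep the extrapolated u3 admissible
    res <- quality_adjusted_survival(times, events, vent, u6, u12, boot = 0)
    rms <- restricted_mean(km_estimate(times, events), 0, 365)
    expect_lte(res$qaly, rms + 1e-12)
    expect_gte(res$qaly, -0.4 * vent / 365.25 - 0.594 * rms - 1e-12)
  }
})

test_that("the bootstrap interval attains nominal coverage", {
  # cohorts drawn from the known mixture; exact truth from the oracle
  M <- 0.512; pe <- 0.958; vent <- 11; u6 <- 0.5622; u12 <- 0.5831
  truth <- oracle_mixture_qaly(M, pe, vent, u6, u12)
  set.seed(2024)
  n <- 200
  covered <- vapply(1:500, function(r) {
    dies <- runif(n) < M
    early <- runif(n) < pe
    times <- rep(365, n)
    times[dies & early] <- sample.int(30, sum(dies & early), replace = TRUE)
    times[dies & !early] <- 30 + sample.int(335, sum(dies & !early),
                                            replace = TRUE)
    res <- quality_adjusted_survival(times, dies, vent, u6, u12,
                                     boot = 1000, seed = r)
    res$ci[1] <= truth && truth <= res$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("adjusted mortality odds ratios behave as a logistic model", {
  # null: group independent of outcome gives OR near 1
  set.seed(5)
  ors <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 600, seed = 300 + s))
    adjusted_mortality_or(coh$patients, "arm")$or
  }, numeric(1))
  expect_lt(abs(mean(log(ors))), 0.1)

  # parameter recovery: known group log-odds 1, no covariate effects
  set.seed(6)
  hits <- vapply(1:200, function(r) {
    n <- 400
    g <- rep(c(TRUE, FALSE), each = n / 2)
    pdeath <- plogis(-0.5 + 1 * g)
    p <- make_patient()[rep(1, n), ]
    p$id <- seq_len(n)
    p$sex <- sample(c("male", "female"), n, replace = TRUE)
    p$pf_ratio <- rnorm(n, 15, 5)
    p$age <- ifelse(g, 70, 50)
    death <- runif(n) < pdeath
    p$death_day <- ifelse(death, 100L, NA_integer_)
    p$alive_1yr <- !death
    res <- adjusted_mortality_or(p, "age65")
    res$ci[1] <= exp(1) && exp(1) <= res$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)

  # separation: a single-outcome group raises an explicit condition
  p <- make_patient()[rep(1, 20), ]
  p$id <- 1:20
  p$age <- rep(c(70, 50), each = 10)
  p$death_day <- c(rep(100L, 10), rep(NA_integer_, 10))
  p$alive_1yr <- is.na(p$death_day)
  expect_error(adjusted_mortality_or(p, "age65"), "separation")
})
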