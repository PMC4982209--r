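# Quality-adjusted survival over one year: partition patient histories
# into a ventilated period (weighted by the unconscious-state utility,
# -0.4) and four follow-up periods anchored at 3, 6, 9 and 12 months,
# weight the Kaplan-Meier area of each period by its utility, and sum.

DAYS_PER_YEAR <- 365.25
PERIOD_BOUNDS <- c(m3 = 91.3, m6 = 182.6, m9 = 274.0, m12 = 365)

#' Kaplan-Meier estimate of the survival curve
#'
#' Product-limit estimator with ties handled events-before-censorings.
#' Censoring at the one-year horizon is applied by the caller.
#'
#' @param times Follow-up times in days (>= 0).
#' @param events Logical event indicators (TRUE = death).
#' @param horizon Administrative horizon in days.
#' @return A list of class `km_curve` with `time` (distinct event times),
#'   `surv` (survival probability after each event time), `n_risk`,
#'   `n_event` and `horizon`.
#' @export
km_estimate <- function(times, events, horizon = 365) {
  if (length(times) == 0L) stop("no observations", call. = FALSE)
  stopifnot(length(times) == length(events), all(times >= 0),
            is.logical(events) || all(events %in% c(0, 1)))
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  if (length(et) == 0L) {
    curve <- list(time = numeric(0), surv = numeric(0),
                  n_risk = numeric(0), n_event = numeric(0),
                  horizon = horizon)
    class(curve) <- "km_curve"
    return(curve)
  }
  # ties: subjects censored exactly at an event time are still at risk
  # there (events before censorings)
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, surv = surv, n_risk = n_risk,
                 n_event = n_event, horizon = horizon), class = "km_curve")
}

km_surv_at <- function(curve, t) {
  # left-continuous step function: S(t) applies after the drop at t
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1]
}

#' Restricted mean survival over an interval
#'
#' Exact step-function integral of the Kaplan-Meier curve over `[a, b]`,
#' returned in years (365.25 days per year).
#'
#' @param curve A `km_curve`.
#' @param a,b Interval bounds in days, `0 <= a < b <= horizon`.
#' @return Area in years.
#' @export
restricted_mean <- function(curve, a, b) {
  if (!(a >= 0 && a < b && b <= curve$horizon))
    stop("interval must satisfy 0 <= a < b <= horizon (", curve$horizon,
         " days)", call. = FALSE)
  knots <- sort(unique(c(a, b, curve$time[curve$time > a & curve$time < b])))
  widths <- diff(knots)
  heights <- km_surv_at(curve, knots[-length(knots)])
  sum(widths * heights) / DAYS_PER_YEAR
}

#' Mid-point interpolation of period utilities
#'
#' Given survivor mean utilities at the 6- and 12-month assessments and
#' assuming a linear change in quality of life over time, returns the
#' utilities at the additional 3- and 9-month mid-points on that line
#' (the 3-month value is the backward extrapolation of the 6-to-12-month
#' line).
#'
#' @param u6,u12 Mean utilities at 6 and 12 months, in `[-0.594, 1]`.
#' @return Named numeric vector `c(u3 = , u9 = )`.
#' @export
interpolate_utilities <- function(u6, u12) {
  stopifnot(u6 >= -0.594, u6 <= 1, u12 >= -0.594, u12 <= 1)
  c(u3 = u6 - (u12 - u6) / 2, u9 = (u6 + u12) / 2)
}

qaly_point <- function(times, events, mean_vent_days, u, unconscious_utility) {
  curve <- km_estimate(times, events)
  bounds <- c(mean_vent_days, PERIOD_BOUNDS)
  areas <- vapply(1:4, function(k) restricted_mean(curve, bounds[k],
                                                   bounds[k + 1]),
                  numeric(1))
  names(areas) <- names(PERIOD_BOUNDS)
  vent_years <- mean_vent_days / DAYS_PER_YEAR
  list(curve = curve, areas = areas, vent_years = vent_years,
       qaly = unconscious_utility * vent_years + sum(areas * u))
}

# With no censoring before the horizon the KM curve is the empirical
# survivor function and each period area is mean((min(T,b) - a)+); this
# closed form makes the bootstrap loop cheap.
qaly_point_uncensored <- function(times, mean_vent_days, u,
                                  unconscious_utility) {
  bounds <- c(mean_vent_days, PERIOD_BOUNDS)
  areas <- vapply(1:4, function(k) {
    mean(pmax(0, pmin(times, bounds[k + 1]) - bounds[k]))
  }, numeric(1)) / DAYS_PER_YEAR
  unconscious_utility * mean_vent_days / DAYS_PER_YEAR + sum(areas * u)
}

#' One-year quality-adjusted survival by Kaplan-Meier partitioning
#'
#' Multiplies the cohort mean number of ventilated days by the
#' unconscious-state utility (-0.4), then weights the Kaplan-Meier area
#' of each follow-up period -- end of ventilation to 3 months, 3--6, 6--9
#' and 9--12 months (91.3 / 182.6 / 274 / 365 days) -- by the period
#' utility (3- and 9-month utilities from [interpolate_utilities()]).
#' The confidence interval is a seeded nonparametric bootstrap over
#' patients (percentile method).
#'
#' @param times Follow-up times in days (death day, or 365 for one-year
#'   survivors).
#' @param events Logical death indicators.
#' @param vent_days Per-patient ventilated days (its mean is the
#'   ventilated-period length), or a single precomputed cohort mean.
#' @param u6,u12 Survivor mean utilities at 6 and 12 months.
#' @param unconscious_utility Utility weight of the ventilated
#'   (unconscious) period.
#' @param boot Number of bootstrap resamples (0 skips the interval).
#' @param seed Seed for the bootstrap.
#' @return An object of class `qaly_result`: list with `qaly`, `ci`,
#'   `period_bounds`, `period_utilities`, `period_areas` (years),
#'   `vent_period_years`, `curve`, `n`, `boot`.
#' @export
quality_adjusted_survival <- function(times, events, vent_days, u6, u12,
                                      unconscious_utility = -0.4,
                                      boot = 1000, seed = 1L) {
  stopifnot(length(times) == length(events))
  if (length(vent_days) == 1L && length(times) > 1L)
    vent_days <- rep(vent_days, length(times))
  stopifnot(length(vent_days) == length(times), all(vent_days >= 0))
  mv <- mean(vent_days)
  if (mv > 365) stop("mean ventilated days exceed the one-year horizon",
                     call. = FALSE)
  if (mv >= PERIOD_BOUNDS["m3"])
    stop("mean ventilated days must fall inside the first period (< 91.3)",
         call. = FALSE)
  um <- interpolate_utilities(u6, u12)
  u <- c(m3 = unname(um["u3"]), m6 = u6, m9 = unname(um["u9"]), m12 = u12)
  pt <- qaly_point(times, events, mv, u, unconscious_utility)

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    n <- length(times)
    uncensored <- all(events | times >= 365)
    qstar <- with_substream(seed, 17L, {
      vapply(seq_len(boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        mvb <- mean(vent_days[idx])
        if (mvb >= PERIOD_BOUNDS["m3"]) mvb <- PERIOD_BOUNDS["m3"] - 1e-9
        if (uncensored)
          qaly_point_uncensored(pmin(times[idx], 365), mvb, u,
                                unconscious_utility)
        else
          qaly_point(times[idx], events[idx], mvb, u,
                     unconscious_utility)$qaly
      }, numeric(1))
    })
    ci <- unname(stats::quantile(qstar, c(0.025, 0.975), type = 7))
  }

  structure(list(qaly = pt$qaly, ci = ci,
                 period_bounds = c(vent_end = mv, PERIOD_BOUNDS),
                 period_utilities = c(vent = unconscious_utility, u),
                 period_areas = pt$areas,
                 vent_period_years = pt$vent_years,
                 curve = pt$curve, n = length(times), boot = boot),
            class = "qaly_result")
}

#' @export
print.qaly_result <- function(x, digits = 4, ...) {
  cat("One-year quality-adjusted survival (KM partitioned), n =", x$n, "\n")
  cat(sprintf("  QALY: %.*f", digits, x$qaly))
  if (!anyNA(x$ci))
    cat(sprintf("  (95%% bootstrap CI %.*f-%.*f, B = %d)", digits, x$ci[1],
                digits, x$ci[2], x$boot))
  cat("\n  period utilities:",
      paste(sprintf("%s=%.4f", names(x$period_utilities),
                    x$period_utilities), collapse = " "), "\n")
  cat("  period areas (years):",
      paste(sprintf("%s=%.4f", names(x$period_areas), x$period_areas),
            collapse = " "), "\n")
  invisible(x)
}

#' Adjusted odds ratio for one-year mortality
#'
#' Logistic regression of one-year death on a group indicator, adjusted
#' for sex and baseline PaO2:FiO2 ratio, with a Wald 95% interval.
#'
#' @param patients Patients table.
#' @param grouping One of `"age65"` (age >= 65), `"apache26"`
#'   (APACHE II > 26) or `"arm"` (HFOV vs conventional).
#' @return List with `or`, `ci`, `n`, and the fitted model in `fit`.
#' @export
adjusted_mortality_or <- function(patients,
                                  grouping = c("age65", "apache26", "arm")) {
  grouping <- match.arg(grouping)
  g <- switch(grouping,
              age65 = patients$age >= 65,
              apache26 = patients$apache2 > 26,
              arm = patients$arm == "hfov")
  death <- !patients$alive_1yr
  if (length(unique(g)) < 2L)
    stop("both groups must be non-empty", call. = FALSE)
  for (gr in c(TRUE, FALSE)) {
    if (length(unique(death[g == gr])) < 2L)
      stop("separation: group ", gr,
           " has a single outcome; the odds ratio is not identified",
           call. = FALSE)
  }
  dat <- data.frame(death = death, g = g, sex = patients$sex,
                    pf = patients$pf_ratio)
  fit <- stats::glm(death ~ g + sex + pf, family = stats::binomial(),
                    data = dat)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("separation: logistic fit did not yield finite estimates",
         call. = FALSE)
  est <- stats::coef(fit)["gTRUE"]
  se <- sqrt(stats::vcov(fit)["gTRUE", "gTRUE"])
  list(or = unname(exp(est)),
       ci = unname(exp(est + c(-1, 1) * stats::qnorm(0.975) * se)),
       n = nrow(dat), fit = fit)
}
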