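# Cohort simulation. One master seed; each table draws from its own
# sub-stream (seed + fixed offset) so regenerating the questionnaires does
# not disturb the patients.

with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Expected value of a normal latent utility after snapping to the nearest
# admissible tariff value (equivalently, quantising the normal to the 243
# state utilities).
quantised_normal_mean <- function(latent_mean, sd, values) {
  v <- sort(unique(values))
  cuts <- c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
  p <- diff(stats::pnorm(cuts, mean = latent_mean, sd = sd))
  sum(v * p)
}

# Solve for the latent mean whose quantised expectation hits the target;
# without this correction, clamping at the tariff maximum (1.0) would bias
# the realised survivor mean downward by about 0.02.
calibrate_latent_mean <- function(target, sd, values) {
  stats::uniroot(function(m) quantised_normal_mean(m, sd, values) - target,
                 interval = c(min(values) - 4 * sd, max(values) + 4 * sd),
                 tol = 1e-8)$root
}

sample_eq5d_states <- function(n, target_mean, sd, state_table) {
  if (n == 0L) return(character(0))
  m <- calibrate_latent_mean(target_mean, sd, state_table$utility)
  latent <- stats::rnorm(n, m, sd)
  ord <- order(state_table$utility)
  v <- state_table$utility[ord]
  s <- state_table$state[ord]
  cuts <- c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
  s[findInterval(latent, cuts, rightmost.closed = TRUE)]
}

# Solve the intercept of the non-response logit so the marginal
# non-response probability over the realised covariates equals the target.
calibrate_logit_intercept <- function(lp_covariates, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + lp_covariates)) - target,
                 interval = c(-30, 30), tol = 1e-8)$root
}

#' Generate a synthetic ARDS trial cohort
#'
#' Draws patient-level baseline, daily ICU case-report and follow-up
#' questionnaire tables with the statistical structure the one-year
#' economic evaluation assumes. Survival times are a two-component
#' mixture: a fraction `early_death_fraction` of deaths fall uniformly in
#' days 1--30 and the rest uniformly in days 31--365, so the Kaplan-Meier
#' curve drops steeply over the first month and flattens after day 60.
#' ICU stay is lognormal matched by moments to the configured mean and SD;
#' length of stay is drawn independently of survival time (the source
#' tables report only their marginal moments). Survivor EQ-5D states are
#' sampled by snapping a calibrated latent normal to the nearest tariff
#' value so the wave means hit their targets in expectation, and 12-month
#' non-response follows a logistic model in standardised age and APACHE II
#' (missing at random: responders are younger with lower APACHE II).
#'
#' @param config A [cohort_config()].
#' @param tariff Tariff coefficients used when sampling EQ-5D states.
#' @return A list of class `ards_cohort` with data frames `patients`,
#'   `daily_crf` and `questionnaires`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' mean(coh$patients$age)
generate_cohort <- function(config = cohort_config(),
                            tariff = uk_tto_tariff()) {
  cfg <- validate_cohort_config(config)
  n <- as.integer(cfg$n_patients)

  patients <- with_substream(cfg$seed, 1L, {
    arm <- ifelse(stats::runif(n) < cfg$allocation_ratio, "hfov",
                  "conventional")
    age <- round(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 1)
    sex <- ifelse(stats::runif(n) < cfg$prop_female, "female", "male")
    apache2 <- as.integer(pmin(71, pmax(0, round(stats::rnorm(
      n, cfg$apache_mean, cfg$apache_sd)))))
    pf_ratio <- pmax(1, round(stats::rnorm(n, cfg$pf_mean, cfg$pf_sd), 1))
    prime_condition <- ifelse(stats::runif(n) < cfg$prop_pneumonia,
                              "pneumonia", "other")
    surgery_admission <- stats::runif(n) < cfg$prop_surgery

    lp <- lnorm_pars(cfg$icu_los_mean, cfg$icu_los_sd)
    icu_days <- pmax(1L, as.integer(round(stats::rlnorm(n, lp$meanlog,
                                                        lp$sdlog))))
    extra_mean <- max(cfg$hosp_los_mean - cfg$icu_los_mean, 0.5)
    ep <- lnorm_pars(extra_mean, 2 * extra_mean)
    extra_days <- as.integer(round(stats::rlnorm(n, ep$meanlog, ep$sdlog)))
    hospital_days <- icu_days + pmax(0L, extra_days)

    vfrac_mean <- cfg$vent_days_mean / cfg$icu_los_mean
    vfrac <- stats::rbeta(n, 8 * vfrac_mean, 8 * (1 - vfrac_mean))
    vent_days <- pmax(1L, pmin(icu_days, as.integer(round(vfrac * icu_days))))

    dies <- stats::runif(n) < cfg$one_year_mortality
    early <- stats::runif(n) < cfg$early_death_fraction
    death_day <- rep(NA_integer_, n)
    death_day[dies & early] <- sample.int(30L, sum(dies & early),
                                          replace = TRUE)
    death_day[dies & !early] <- 30L + sample.int(335L, sum(dies & !early),
                                                 replace = TRUE)
    alive_1yr <- is.na(death_day) | death_day > 365L

    survived_icu <- is.na(death_day) | death_day > icu_days
    discharged_to_other_hospital <- survived_icu &
      stats::runif(n) < cfg$prop_transfer
    readmit <- survived_icu & stats::runif(n) < cfg$readmission_rate
    readmission_days <- integer(n)
    readmission_days[readmit] <- pmin(hospital_days[readmit] -
                                        icu_days[readmit],
                                      1L + stats::rpois(sum(readmit), 3))
    stepdown_level <- ifelse(stats::runif(n) < 0.63, "ward", "hdu")

    data.frame(id = seq_len(n), arm = arm, age = age, sex = sex,
               apache2 = apache2, pf_ratio = pf_ratio,
               prime_condition = prime_condition,
               surgery_admission = surgery_admission,
               icu_days = icu_days, vent_days = vent_days,
               hospital_days = hospital_days, death_day = death_day,
               alive_1yr = alive_1yr,
               discharged_to_other_hospital = discharged_to_other_hospital,
               readmission_days = readmission_days,
               stepdown_level = stepdown_level,
               stringsAsFactors = FALSE)
  })

  daily_crf <- with_substream(cfg$seed, 2L, {
    idx <- rep.int(patients$id, patients$icu_days)
    day_index <- sequence(patients$icu_days)
    m <- length(idx)
    on_vent <- day_index <= patients$vent_days[idx]
    data.frame(patient_id = idx, day_index = day_index,
               organs_supported = pmin(6L, 1L + stats::rbinom(m, 4, 0.25)),
               on_ventilation = on_vent,
               on_rrt = stats::runif(m) < 0.15,
               xray_count = stats::rpois(m, 0.3),
               chest_drain = stats::runif(m) < 0.02,
               drug_antibiotic = stats::rpois(m, 2),
               drug_sedative = stats::rpois(m, 2) * on_vent,
               drug_muscle_relaxant = stats::rpois(m, 0.5) * on_vent,
               stringsAsFactors = FALSE)
  })

  questionnaires <- with_substream(cfg$seed, 3L, {
    states <- eq5d_states(tariff)
    make_wave <- function(wave, eligible, nonresponse, target_mean) {
      ids <- patients$id[eligible]
      k <- length(ids)
      if (k == 0L) return(empty_questionnaires())
      z_age <- as.numeric(scale(patients$age[eligible]))
      z_apache <- as.numeric(scale(patients$apache2[eligible]))
      if (anyNA(z_age)) z_age <- rep(0, k)      # degenerate: constant ages
      if (anyNA(z_apache)) z_apache <- rep(0, k)
      lp_cov <- cfg$nonresponse_mar_strength * (z_age + z_apache)
      alpha <- calibrate_logit_intercept(lp_cov, nonresponse)
      p_nr <- stats::plogis(alpha + lp_cov)
      returned <- stats::runif(k) >= p_nr
      r <- sum(returned)
      q <- data.frame(patient_id = ids, wave = wave, returned = returned,
                      eq5d_state = NA_character_, gp_visits = NA_integer_,
                      outpatient_visits = NA_integer_,
                      community_visits = NA_integer_,
                      inpatient_days = NA_integer_,
                      aids_items = NA_character_,
                      travel_miles = NA_integer_, lost_earnings = NA_real_,
                      oop_expenses = NA_real_,
                      carer_travel_miles = NA_integer_,
                      carer_lost_earnings = NA_real_,
                      stringsAsFactors = FALSE)
      if (r > 0L) {
        q$eq5d_state[returned] <- sample_eq5d_states(r, target_mean,
                                                     cfg$eq5d_sd, states)
        q$gp_visits[returned] <- stats::rpois(r, 3)
        q$outpatient_visits[returned] <- stats::rpois(r, 2)
        q$community_visits[returned] <- stats::rpois(r, 2)
        q$inpatient_days[returned] <- as.integer(
          (stats::runif(r) < 0.25) * stats::rpois(r, 6))
        aids_pool <- c("wheelchair", "walking_frame", "home_adaptation",
                       "other")
        n_aids <- stats::rbinom(r, 2, 0.12)
        q$aids_items[returned] <- vapply(n_aids, function(k2) {
          if (k2 == 0L) "" else
            paste(sample(aids_pool, k2), collapse = ";")
        }, character(1))
        q$travel_miles[returned] <- as.integer(round(stats::rlnorm(
          r, log(80), 0.9)))
        q$lost_earnings[returned] <- round(
          (stats::runif(r) < 0.3) * stats::rlnorm(r, log(6000), 0.8), 2)
        q$oop_expenses[returned] <- round(
          (stats::runif(r) < 0.4) * stats::rlnorm(r, log(250), 1), 2)
        q$carer_travel_miles[returned] <- as.integer(round(stats::rlnorm(
          r, log(60), 0.9)))
        q$carer_lost_earnings[returned] <- round(
          (stats::runif(r) < 0.2) * stats::rlnorm(r, log(2500), 0.8), 2)
      }
      q
    }
    elig6 <- is.na(patients$death_day) | patients$death_day > 183L
    elig12 <- patients$alive_1yr
    rbind(make_wave("6m", elig6, cfg$nonresponse_6m, cfg$eq5d_mean_6m),
          make_wave("12m", elig12, cfg$nonresponse_12m, cfg$eq5d_mean_12m))
  })

  structure(list(patients = patients, daily_crf = daily_crf,
                 questionnaires = questionnaires, config = cfg),
            class = "ards_cohort")
}

empty_questionnaires <- function() {
  data.frame(patient_id = integer(0), wave = character(0),
             returned = logical(0), eq5d_state = character(0),
             gp_visits = integer(0), outpatient_visits = integer(0),
             community_visits = integer(0), inpatient_days = integer(0),
             aids_items = character(0), travel_miles = integer(0),
             lost_earnings = numeric(0), oop_expenses = numeric(0),
             carer_travel_miles = integer(0), carer_lost_earnings = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.ards_cohort <- function(x, ...) {
  p <- x$patients
  cat("Synthetic ARDS cohort:", nrow(p), "patients\n")
  cat(sprintf("  mean age %.1f y, %.1f%% female, APACHE II %.1f\n",
              mean(p$age), 100 * mean(p$sex == "female"), mean(p$apache2)))
  cat(sprintf("  ICU stay %.1f d, hospital stay %.1f d, vent %.1f d\n",
              mean(p$icu_days), mean(p$hospital_days), mean(p$vent_days)))
  cat(sprintf("  one-year mortality %.1f%%; %d CRF days, %d questionnaires\n",
              100 * mean(!p$alive_1yr), nrow(x$daily_crf),
              nrow(x$questionnaires)))
  invisible(x)
}
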