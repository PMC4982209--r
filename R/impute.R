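# Truncated multiple imputation of post-hospital costs by chained
# equations with predictive mean matching, pooled by Rubin's rules.
# Written from scratch: a Bayesian linear-model draw per incomplete
# variable, PMM with k nearest donors (which keeps imputations on the
# observed, non-negative support) and an explicit floor.

#' Imputation specification
#'
#' @param m Number of imputed datasets (>= 2; 10 in the source analysis).
#' @param predictors Complete covariates used in every conditional model.
#' @param truncation_floor Lower bound imposed on imputed costs (GBP).
#' @param iterations Chained-equation cycles.
#' @param k_donors Donor-pool size for predictive mean matching.
#' @param seed Seed controlling all imputation draws.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 10,
                            predictors = c("age", "sex", "apache2",
                                           "pf_ratio", "arm", "icu_days"),
                            truncation_floor = 0,
                            iterations = 10,
                            k_donors = 5,
                            seed = 1L) {
  if (m < 2) stop("imputation_spec: m must be >= 2", call. = FALSE)
  if (truncation_floor < 0)
    stop("imputation_spec: truncation_floor must be >= 0", call. = FALSE)
  if (iterations < 1)
    stop("imputation_spec: iterations must be >= 1", call. = FALSE)
  structure(list(m = m, predictors = predictors,
                 truncation_floor = truncation_floor,
                 iterations = iterations, k_donors = k_donors,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

# One proper imputation draw for variable y given design matrix X:
# draw sigma^2 and beta from their posterior (non-informative prior),
# predict observed rows with the least-squares fit and missing rows with
# the drawn beta, then match each missing row to one of the k observed
# rows with the closest prediction (type-1 PMM).
pmm_draw <- function(y, X, miss, k) {
  obs <- !miss
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qr_fit <- qr(Xo)
  rank <- qr_fit$rank
  keep <- qr_fit$pivot[seq_len(rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(yo) - rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtX_inv <- chol2inv(qr.R(qr(Xo)))
  beta_star <- beta_hat + drop(t(chol(sigma2 * XtX_inv)) %*%
                                 stats::rnorm(rank))
  eta_obs <- drop(Xo %*% beta_hat)
  eta_mis <- drop(Xm %*% beta_star)
  vapply(eta_mis, function(e) {
    d <- abs(eta_obs - e)
    donors <- order(d)[seq_len(min(k, length(d)))]
    yo[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

#' Multiply impute missing post-hospital costs
#'
#' Chained-equation imputation of the incomplete cost columns of `data`:
#' each incomplete variable is imputed from the complete covariates plus
#' the other (currently imputed) cost variables, cycling for
#' `spec$iterations` rounds, repeated independently for each of the `m`
#' datasets. Predictive mean matching keeps imputed values on the
#' observed support and the truncation floor is enforced on top, so all
#' imputed costs are `>= spec$truncation_floor`. Observed entries are
#' never modified, and results are deterministic for a fixed seed.
#'
#' @param data Data frame whose incomplete numeric columns are to be
#'   imputed (e.g. the `wave_costs` table from [cost_cohort()]).
#' @param covariates Data frame of complete predictors, same row order as
#'   `data`; columns per `spec$predictors` (character columns are treated
#'   as factors).
#' @param spec An [imputation_spec()].
#' @return A list of `m` completed data frames.
#' @export
impute_costs <- function(data, covariates, spec = imputation_spec()) {
  stopifnot(nrow(data) == nrow(covariates))
  pred <- spec$predictors[spec$predictors %in% names(covariates)]
  if (anyNA(covariates[pred]))
    stop("predictors must be complete", call. = FALSE)
  targets <- names(data)[vapply(data, function(col)
    is.numeric(col) && anyNA(col), logical(1))]
  for (v in targets) {
    if (!any(!is.na(data[[v]])))
      stop("no complete cases for '", v, "'; cannot impute", call. = FALSE)
    if (any(data[[v]] < spec$truncation_floor, na.rm = TRUE))
      stop("observed '", v, "' falls below the truncation floor",
           call. = FALSE)
  }
  if (length(targets) == 0L)
    return(replicate(spec$m, data, simplify = FALSE))

  X_cov <- stats::model.matrix(
    ~ ., data = as.data.frame(lapply(covariates[pred], function(col) {
      if (is.character(col)) factor(col) else col
    })))
  miss <- lapply(data[targets], is.na)

  with_substream(spec$seed, 29L, {
    lapply(seq_len(spec$m), function(imp) {
      cur <- data
      for (v in targets) {          # initial fill: draws from the observed
        obs_vals <- cur[[v]][!miss[[v]]]
        cur[[v]][miss[[v]]] <- sample(obs_vals, sum(miss[[v]]),
                                      replace = TRUE)
      }
      for (it in seq_len(spec$iterations)) {
        for (v in targets) {
          others <- setdiff(targets, v)
          X <- cbind(X_cov, as.matrix(cur[others]))
          cur[[v]][miss[[v]]] <- pmax(spec$truncation_floor,
                                      pmm_draw(data[[v]], X, miss[[v]],
                                               spec$k_donors))
          # keep later variables conditioned on the fresh draws
        }
      }
      cur
    })
  })
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Point estimate = mean of the per-dataset estimates; total variance =
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; interval on `point +/- t_df * sqrt(total)`
#' with the standard small-sample degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates Numeric vector of `m` point estimates.
#' @param variances Numeric vector of `m` squared standard errors.
#' @return A list of class `pooled_estimate`: `point`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m)
    stop("estimates and variances must have equal length", call. = FALSE)
  if (m < 2) stop("need at least 2 imputed datasets", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  point <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(point = point, within_var = W, between_var = B,
                 total_var = total, df = df,
                 ci = point + c(-1, 1) * crit * sqrt(total)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled estimate %.*f (95%% CI %.*f-%.*f), total var %.*f\n",
              digits, x$point, digits, x$ci[1], digits, x$ci[2], digits,
              x$total_var))
  invisible(x)
}
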