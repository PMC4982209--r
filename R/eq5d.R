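#' UK time-trade-off tariff coefficients for EQ-5D-3L
#'
#' Returns the coefficient set of the UK TTO (MVH) value set used to map
#' EQ-5D-3L health states to utility weights: a constant decrement applied
#' when any dimension is above level 1, per-dimension decrements for levels
#' 2 and 3, and an extra "N3" decrement when any dimension is at level 3.
#' The utility of an unconscious patient (-0.4, from the EQ-5D scoring
#' manual) is carried along for the ventilated-period weighting.
#'
#' @param file Optional path to a YAML file overriding the bundled
#'   coefficients. The file must provide `constant_decrement`,
#'   `level2_decrements`, `level3_decrements` (each a named list over
#'   `mobility`, `self_care`, `usual_activities`, `pain`, `anxiety`),
#'   `n3_decrement` and `unconscious_utility`.
#' @return An object of class `eq5d_tariff`: a list with elements
#'   `constant_decrement`, `level2_decrements`, `level3_decrements`
#'   (named numeric vectors of length 5), `n3_decrement` and
#'   `unconscious_utility`.
#' @export
#' @examples
#' tar <- uk_tto_tariff()
#' eq5d_utility("11111", tar)  # 1
#' eq5d_utility("33333", tar)  # -0.594
uk_tto_tariff <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "eq5d_uk_tto.yaml", package = "ardsecon",
                        mustWork = TRUE)
  }
  if (!file.exists(file))
    stop("tariff file not found: ", file, call. = FALSE)
  raw <- yaml::read_yaml(file)
  dims <- c("mobility", "self_care", "usual_activities", "pain", "anxiety")
  l2 <- unlist(raw$level2_decrements)[dims]
  l3 <- unlist(raw$level3_decrements)[dims]
  coeffs <- structure(
    list(constant_decrement = as.numeric(raw$constant_decrement),
         level2_decrements = l2,
         level3_decrements = l3,
         n3_decrement = as.numeric(raw$n3_decrement),
         unconscious_utility = as.numeric(raw$unconscious_utility)),
    class = "eq5d_tariff")
  validate_tariff(coeffs)
  coeffs
}

validate_tariff <- function(coeffs) {
  stopifnot(inherits(coeffs, "eq5d_tariff"))
  if (any(is.na(c(coeffs$level2_decrements, coeffs$level3_decrements))))
    stop("tariff file is missing a per-dimension decrement", call. = FALSE)
  if (coeffs$constant_decrement < 0 || coeffs$n3_decrement < 0 ||
      any(coeffs$level2_decrements < 0) || any(coeffs$level3_decrements < 0))
    stop("all tariff decrements must be >= 0", call. = FALSE)
  if (any(coeffs$level3_decrements < coeffs$level2_decrements))
    stop("level-3 decrements must be >= level-2 decrements", call. = FALSE)
  invisible(coeffs)
}

parse_eq5d_state <- function(state) {
  if (length(state) != 1L || is.na(state))
    stop("EQ-5D state must be a single non-missing 5-character string",
         call. = FALSE)
  state <- as.character(state)
  if (nchar(state) != 5L)
    stop("EQ-5D state must have exactly five digits, got '", state, "'",
         call. = FALSE)
  digits <- suppressWarnings(as.integer(strsplit(state, "")[[1]]))
  bad <- which(is.na(digits) | digits < 1L | digits > 3L)
  if (length(bad))
    stop("EQ-5D state '", state, "': digit at position ", bad[1],
         " is not in {1,2,3}", call. = FALSE)
  digits
}

#' Utility weight of an EQ-5D-3L health state
#'
#' Applies the additive UK TTO decrement model: starting from 1 (full
#' health), subtract the constant decrement if any dimension is above
#' level 1, the per-dimension level-2/level-3 decrements, and the N3
#' decrement if any dimension is at level 3.
#'
#' @param state Character scalar (or vector) of five digits, each in
#'   1..3, ordered mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression (e.g. `"21123"`).
#' @param coeffs Tariff coefficients from [uk_tto_tariff()].
#' @return Numeric utility weight(s); 1 for `"11111"`, minimum -0.594 for
#'   `"33333"` under the UK TTO set.
#' @export
eq5d_utility <- function(state, coeffs = uk_tto_tariff()) {
  vapply(state, function(s) {
    d <- parse_eq5d_state(s)
    u <- 1
    if (any(d > 1L)) u <- u - coeffs$constant_decrement
    u <- u - sum(coeffs$level2_decrements[d == 2L])
    u <- u - sum(coeffs$level3_decrements[d == 3L])
    if (any(d == 3L)) u <- u - coeffs$n3_decrement
    u
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate all 243 EQ-5D-3L states and their utilities
#'
#' @param coeffs Tariff coefficients from [uk_tto_tariff()].
#' @return A data frame with columns `state` (character) and `utility`,
#'   one row per admissible state, ordered lexicographically.
#' @export
eq5d_states <- function(coeffs = uk_tto_tariff()) {
  grid <- expand.grid(a = 1:3, p = 1:3, u = 1:3, s = 1:3, m = 1:3)
  states <- paste0(grid$m, grid$s, grid$u, grid$p, grid$a)
  states <- sort(states)
  data.frame(state = states, utility = eq5d_utility(states, coeffs),
             stringsAsFactors = FALSE)
}

#' Mean utility of returned questionnaires at one wave
#'
#' Scores the EQ-5D states of all returned questionnaires at the requested
#' wave and summarises them; non-returned questionnaires are excluded (all
#' available questionnaires are used, with no imputation of utilities).
#'
#' @param questionnaires Questionnaire data frame (see [generate_cohort()]).
#' @param wave `"6m"` or `"12m"`.
#' @param coeffs Tariff coefficients.
#' @return A list with `mean`, `ci` (normal-based 95% interval), `n`.
#' @export
mean_wave_utility <- function(questionnaires, wave = c("6m", "12m"),
                              coeffs = uk_tto_tariff()) {
  wave <- match.arg(wave)
  q <- questionnaires[questionnaires$wave == wave & questionnaires$returned, ,
                      drop = FALSE]
  if (nrow(q) < 2L)
    stop("need at least 2 returned questionnaires at wave ", wave,
         " to estimate a mean utility", call. = FALSE)
  u <- eq5d_utility(q$eq5d_state, coeffs)
  m <- mean(u)
  se <- stats::sd(u) / sqrt(length(u))
  list(mean = m, ci = m + c(-1, 1) * stats::qnorm(0.975) * se, n = length(u))
}

#' Compare survivor utilities with an age-matched reference population
#'
#' Welch two-sample t test of the observed band means against reference
#' population norms, one test per age band.
#'
#' @param band_stats Data frame with columns `band`, `mean`, `sd`, `n`
#'   (observed survivors per band).
#' @param reference Data frame with columns `band`, `mean`, `sd`, `n`
#'   (population norms); the bundled table is loaded by
#'   [reference_population()].
#' @return Data frame with one row per observed band: `band`, `difference`
#'   (observed minus reference), `t`, `df`, `p`.
#' @export
compare_to_reference <- function(band_stats, reference = reference_population()) {
  need <- c("band", "mean", "sd", "n")
  stopifnot(all(need %in% names(band_stats)), all(need %in% names(reference)))
  if (any(band_stats$n < 2L))
    stop("each band needs n >= 2 for a two-sample comparison", call. = FALSE)
  out <- lapply(seq_len(nrow(band_stats)), function(i) {
    b <- band_stats[i, ]
    r <- reference[reference$band == b$band, , drop = FALSE]
    if (nrow(r) != 1L)
      stop("band '", b$band, "' not found in the reference table",
           call. = FALSE)
    v1 <- b$sd^2 / b$n
    v2 <- r$sd^2 / r$n
    t_stat <- (b$mean - r$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (b$n - 1) + v2^2 / (r$n - 1))
    data.frame(band = b$band, difference = b$mean - r$mean, t = t_stat,
               df = df, p = 2 * stats::pt(-abs(t_stat), df))
  })
  do.call(rbind, out)
}

#' Age- and sex-matched reference utilities
#'
#' Loads the bundled reference-population EQ-5D norms (two age bands,
#' under 65 and 65 plus) used by [compare_to_reference()]. The bundled
#' sample sizes are illustrative; the means and SDs are population norms.
#'
#' @param file Optional path to an alternative CSV with columns
#'   `band`, `mean`, `sd`, `n`.
#' @return Data frame with columns `band`, `mean`, `sd`, `n`.
#' @export
reference_population <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "reference_population.csv",
                        package = "ardsecon", mustWork = TRUE)
  }
  utils::read.csv(file, stringsAsFactors = FALSE)
}
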