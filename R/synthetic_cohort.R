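# Seeded synthetic blunt-chest-trauma cohorts.
#
# The generator emulates the marginal structure of the original 301-patient
# study sample: demographics, mechanism of injury and the five radiographic
# findings are drawn independently from the published marginal frequencies,
# and the critical/non-critical outcome is drawn from a logistic link on
# the SA-CTS, calibrated so that the expected critical fraction and the
# population odds ratio of the high-score group match the published values
# (0.328 and 4.17). Disposition and ventilation are then assigned
# conditionally on the outcome. Findings components are independent by
# design (only marginals are published); outcome depends on findings only
# through the SA-CTS, which makes cutpoint recovery well-posed.

#' Default simulation parameters mirroring the study sample
#'
#' Marginal frequencies are those of the original cohort (N = 301):
#' 70.8% male; age bands (<45, 45-65, >65) at (0.761, 0.183, 0.056);
#' mechanism (MVA, PVA, fall, assault, unknown) at (0.601, 0.299, 0.070,
#' 0.020, 0.010); rib bands (0, 1-2, 3-5, >5) at (0.631, 0.230, 0.136,
#' 0.003); contusion grades at (0.359, 0.256, 0.123, 0.176, 0.086);
#' pneumothorax 0.086; haemothorax 0.375. The bilateral-fracture
#' probability given an eligible count (>= 2) is 0.185, reproducing the
#' published 4.7% marginal. The logistic outcome model is calibrated by
#' [calibrate_outcome_model()] to a critical fraction of 0.328 and a
#' high-SA-CTS (>= 4) odds ratio of 4.17. Ventilation conditionals are
#' 29/99 (critical) and 3/202 (non-critical).
#'
#' @param n Cohort size (default 301).
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_sim_params`.
#' @export
default_sim_params <- function(n = 301, seed = 1) {
  params <- structure(list(
    n = as.integer(n),
    seed = as.integer(seed),
    p_male = 0.708,
    age_band_probs = c("<45" = 0.761, "45-65" = 0.183, ">65" = 0.056),
    mechanism_probs = c(motor_vehicle_accident = 0.601,
                        pedestrian_vehicle_accident = 0.299,
                        fall_from_height = 0.070,
                        assault = 0.020,
                        unknown = 0.010),
    rib_band_probs = c("0" = 0.631, "1-2" = 0.230, "3-5" = 0.136,
                       ">5" = 0.003),
    p_bilateral_given_multi = 0.185,
    contusion_probs = c(none = 0.359, unilateral_minor = 0.256,
                        bilateral_minor = 0.123, unilateral_major = 0.176,
                        bilateral_major = 0.086),
    p_pneumothorax = 0.086,
    p_haemothorax = 0.375,
    outcome_model = NULL,
    p_ventilated_given_critical = 29 / 99,
    p_ventilated_given_noncritical = 3 / 202
  ), class = "cohort_sim_params")
  params$outcome_model <- calibrate_outcome_model(params)
  validate_sim_params(params)
  params
}

#' Validate simulation parameters
#' @param params A `cohort_sim_params` list.
#' @return `params`, invisibly; errors on the first violation.
#' @export
validate_sim_params <- function(params) {
  stopifnot(params$n >= 1)
  for (v in c("age_band_probs", "mechanism_probs", "rib_band_probs",
              "contusion_probs")) {
    p <- params[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(v, " must be non-negative and sum to 1")
    }
  }
  for (v in c("p_male", "p_bilateral_given_multi", "p_pneumothorax",
              "p_haemothorax", "p_ventilated_given_critical",
              "p_ventilated_given_noncritical")) {
    p <- params[[v]]
    if (is.na(p) || p < 0 || p > 1) stop(v, " must be in [0, 1]")
  }
  om <- params$outcome_model
  if (is.null(om) || !all(c("intercept", "slope") %in% names(om))) {
    stop("outcome_model must have intercept and slope")
  }
  invisible(params)
}

#' Exact SA-CTS distribution implied by simulation parameters
#'
#' Convolves the independent component distributions (rib band with its
#' within-band bilaterality eligibility, contusion grade, pneumothorax,
#' haemothorax) into the exact probability mass function of the SA-CTS
#' total on 0..11. Counts in band 1-2 are uniform on \{1, 2\} and only a
#' count of 2 is eligible for bilaterality, which the convolution tracks.
#'
#' @param params A `cohort_sim_params` list.
#' @return Numeric vector of length 12, probabilities of totals 0..11.
#' @export
sacts_pmf <- function(params) {
  rb <- params$rib_band_probs
  pb <- params$p_bilateral_given_multi
  # rib + bilaterality contribution: (score, probability)
  rib_contrib <- rbind(
    c(0, rb[["0"]]),                      # no fractures
    c(1, rb[["1-2"]] / 2),                # count 1: not eligible
    c(1, rb[["1-2"]] / 2 * (1 - pb)),     # count 2, unilateral
    c(3, rb[["1-2"]] / 2 * pb),           # count 2, bilateral (+2)
    c(2, rb[["3-5"]] * (1 - pb)),
    c(4, rb[["3-5"]] * pb),
    c(3, rb[[">5"]] * (1 - pb)),
    c(5, rb[[">5"]] * pb)
  )
  pmf <- numeric(12)  # totals 0..11
  add <- function(pmf, contrib) {
    out <- numeric(12)
    for (i in seq_len(nrow(contrib))) {
      s <- contrib[i, 1]; p <- contrib[i, 2]
      idx <- seq_along(pmf) + s
      keep <- idx <= 12
      out[idx[keep]] <- out[idx[keep]] + pmf[keep] * p
    }
    out
  }
  pmf[1] <- 1
  pmf <- add(pmf, rib_contrib)
  pmf <- add(pmf, cbind(0:4, unname(params$contusion_probs)))
  pmf <- add(pmf, rbind(c(0, 1 - params$p_pneumothorax),
                        c(1, params$p_pneumothorax)))
  pmf <- add(pmf, rbind(c(0, 1 - params$p_haemothorax),
                        c(1, params$p_haemothorax)))
  stopifnot(abs(sum(pmf) - 1) < 1e-12)
  pmf
}

# P(critical | s) under an outcome model: a logistic link either on the
# score itself ("linear") or on the high-score indicator ("step").
outcome_probability <- function(om, s) {
  link <- if (is.null(om$link)) "step" else om$link
  eta <- switch(link,
                linear = om$intercept + om$slope * s,
                step = om$intercept +
                  om$slope * as.numeric(s >= om$threshold),
                stop("unknown outcome link: ", link))
  stats::plogis(eta)
}

# Population critical fraction and high/low odds ratio implied by an
# outcome model under the score pmf.
outcome_model_targets <- function(pmf, om, cutoff = 4) {
  s <- seq_along(pmf) - 1
  pc <- outcome_probability(om, s)
  frac <- sum(pmf * pc)
  high <- s >= cutoff
  p_high <- sum(pmf[high] * pc[high]) / sum(pmf[high])
  p_low <- sum(pmf[!high] * pc[!high]) / sum(pmf[!high])
  or <- (p_high / (1 - p_high)) / (p_low / (1 - p_low))
  list(critical_fraction = frac, high_or = or)
}

#' Calibrate the logistic score-to-outcome link
#'
#' Solves for the intercept and slope of the outcome model so that, under
#' the exact score distribution implied by `params`, the expected critical
#' fraction equals `target_critical_fraction` and the population odds
#' ratio comparing the high group (`score >= cutoff`) with the low group
#' equals `target_high_or`.
#'
#' Two link shapes are supported. The default `"step"` link,
#' `plogis(intercept + slope * (s >= cutoff))`, raises the critical
#' probability once the score crosses the threshold, so the population
#' odds ratio is exactly `exp(slope)` and the threshold is recoverable
#' from simulated cohorts — the design under which cutpoint recovery is
#' well-posed. The `"linear"` link, `plogis(intercept + slope * s)`,
#' grows smoothly with the score; it matches the two calibration targets
#' equally well but spreads the association across neighbouring cutoffs,
#' so no single cutpoint is distinguished (see the methods vignette).
#' With `slope` supplied (e.g. 0 for a null model) only the intercept is
#' solved, against the fraction target.
#'
#' @param params A `cohort_sim_params` list (only the findings marginals
#'   are used).
#' @param target_critical_fraction Target expected critical fraction.
#' @param target_high_or Target population odds ratio; ignored when
#'   `slope` is supplied.
#' @param cutoff High-group threshold on the SA-CTS (default 4).
#' @param slope Optional fixed slope.
#' @param link `"step"` (default) or `"linear"`.
#' @return A list with `intercept`, `slope`, `link` and (for the step
#'   link) `threshold`.
#' @export
calibrate_outcome_model <- function(params,
                                    target_critical_fraction = 0.328,
                                    target_high_or = 4.17,
                                    cutoff = 4, slope = NULL,
                                    link = c("step", "linear")) {
  link <- match.arg(link)
  if (target_critical_fraction <= 0 || target_critical_fraction >= 1) {
    stop("target_critical_fraction must be in (0, 1)")
  }
  pmf <- sacts_pmf(params)
  om <- function(a, b) list(intercept = a, slope = b, link = link,
                            threshold = cutoff)
  solve_intercept <- function(b) {
    stats::uniroot(function(a)
      outcome_model_targets(pmf, om(a, b), cutoff)$critical_fraction -
        target_critical_fraction,
      c(-50, 50), tol = 1e-12)$root
  }
  if (!is.null(slope)) {
    if (slope == 0) {
      return(om(stats::qlogis(target_critical_fraction), 0))
    }
    return(om(solve_intercept(slope), slope))
  }
  if (is.na(target_high_or) || target_high_or <= 0) {
    stop("target_high_or must be positive")
  }
  if (link == "step") {
    # within-group probabilities are constant, so OR = exp(slope) exactly
    b <- log(target_high_or)
    return(om(solve_intercept(b), b))
  }
  or_at <- function(b) {
    outcome_model_targets(pmf, om(solve_intercept(b), b), cutoff)$high_or
  }
  b_lo <- 1e-6; b_hi <- 10
  attained <- c(or_at(b_lo), or_at(b_hi))
  if (target_high_or < attained[1] || target_high_or > attained[2]) {
    stop(sprintf(
      "target_high_or %.3g outside attainable range [%.3g, %.3g]",
      target_high_or, attained[1], attained[2]))
  }
  b <- stats::uniroot(function(b) or_at(b) - target_high_or,
                      c(b_lo, b_hi), tol = 1e-10)$root
  om(solve_intercept(b), b)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `params$seed`. Fields are drawn in a fixed order
#' (sex, age, mechanism, rib band, rib count within band, bilaterality,
#' contusion, pneumothorax, haemothorax, outcome, disposition,
#' ventilation), each as one vectorised draw, so cohorts are reproducible
#' across runs. Rib counts are uniform within bands (>5 realised as 6-8;
#' any count above 5 scores identically). Critical outcomes are assigned
#' dispositions ICU / death / poor outcome in proportions 86:11:2 and
#' non-critical ward / discharged in proportions 200:2.
#'
#' @param params A `cohort_sim_params` list; see [default_sim_params()].
#' @return A cohort data.frame in the schema of [parse_cohort_csv()].
#' @export
generate_cohort <- function(params) {
  validate_sim_params(params)
  n <- params$n
  set.seed(params$seed)
  sex <- ifelse(stats::runif(n) < params$p_male, "male", "female")
  band <- sample(names(params$age_band_probs), n, replace = TRUE,
                 prob = params$age_band_probs)
  age <- integer(n)
  age[band == "<45"] <- sample(18:44, sum(band == "<45"), replace = TRUE)
  age[band == "45-65"] <- sample(45:65, sum(band == "45-65"), replace = TRUE)
  age[band == ">65"] <- sample(66:90, sum(band == ">65"), replace = TRUE)
  mechanism <- sample(names(params$mechanism_probs), n, replace = TRUE,
                      prob = params$mechanism_probs)
  rb <- sample(names(params$rib_band_probs), n, replace = TRUE,
               prob = params$rib_band_probs)
  ribs <- integer(n)
  ribs[rb == "1-2"] <- sample(1:2, sum(rb == "1-2"), replace = TRUE)
  ribs[rb == "3-5"] <- sample(3:5, sum(rb == "3-5"), replace = TRUE)
  ribs[rb == ">5"] <- sample(6:8, sum(rb == ">5"), replace = TRUE)
  bilateral <- ribs >= 2 &
    stats::runif(n) < params$p_bilateral_given_multi
  contusion <- sample(names(params$contusion_probs), n, replace = TRUE,
                      prob = params$contusion_probs)
  pneumo <- stats::runif(n) < params$p_pneumothorax
  haemo <- stats::runif(n) < params$p_haemothorax
  f <- data.frame(rib_fracture_count = ribs,
                  bilateral_rib_fractures = bilateral,
                  contusion_grade = contusion,
                  pneumothorax = pneumo, haemothorax = haemo,
                  stringsAsFactors = FALSE)
  s <- sacts_score(f)$total
  critical <- stats::runif(n) < outcome_probability(params$outcome_model, s)
  disposition <- character(n)
  n_crit <- sum(critical)
  disposition[critical] <- sample(c("icu", "death", "poor_outcome"), n_crit,
                                  replace = TRUE, prob = c(86, 11, 2))
  disposition[!critical] <- sample(c("ward", "discharged"), n - n_crit,
                                   replace = TRUE, prob = c(200, 2))
  ventilated <- ifelse(critical,
                       stats::runif(n) < params$p_ventilated_given_critical,
                       stats::runif(n) < params$p_ventilated_given_noncritical)
  data.frame(patient_id = sprintf("SYN%05d", seq_len(n)),
             age_years = age, sex = sex, mechanism = mechanism,
             ventilated = ventilated, disposition = disposition,
             rib_fracture_count = ribs,
             bilateral_rib_fractures = bilateral,
             contusion_grade = contusion,
             pneumothorax = pneumo, haemothorax = haemo,
             stringsAsFactors = FALSE)
}

#' Write a cohort CSV plus a parameter sidecar
#'
#' @param records Cohort data.frame.
#' @param path Output CSV path; the parameters (if given) are written next
#'   to it as `<path>.params.json`.
#' @param params Optional `cohort_sim_params` used to generate the cohort.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path, params = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
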