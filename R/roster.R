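#' Predictor roster entries
#'
#' A roster describes the categorical predictors of a synthetic survey
#' cohort: category labels, marginal probabilities, the true log-time
#' coefficient of each level in the Weibull AFT outcome process, the
#' reference level, and the conditional-model type used during fully
#' conditional specification (FCS) imputation.
#'
#' @param name variable name (a valid column name).
#' @param levels character vector of category labels (>= 2), in roster
#'   order; roster order is the deterministic tie-break order for mode
#'   imputation.
#' @param probs marginal probabilities, same length as `levels`; must sum
#'   to 1 within 1e-12 (use [normalize_probs()] for raw percentages).
#' @param beta named numeric vector of true log-time coefficients for
#'   non-reference levels (missing names default to 0); the reference
#'   level always carries 0.
#' @param ref reference level label (default: first level).
#' @param type conditional-model type: `"binary"` (logistic), `"ordinal"`
#'   (proportional-odds logistic) or `"nominal"` (multinomial logistic).
#' @param condition logical; `TRUE` marks a binary chronic-condition
#'   indicator eligible for the low-prevalence deterministic fill, whose
#'   first level is the "absent" state.
#' @return An object of class `roster_entry`.
#' @export
roster_entry <- function(name, levels, probs, beta = NULL, ref = levels[1L],
                         type = c("ordinal", "nominal", "binary"),
                         condition = FALSE) {
  type <- match.arg(type)
  if (length(levels) < 2L) stopf("roster entry '%s': needs >= 2 categories", name)
  if (length(probs) != length(levels)) stopf("'%s': probs/levels length mismatch", name)
  if (abs(sum(probs) - 1) > 1e-12) stopf("'%s': probabilities must sum to 1", name)
  if (any(probs < 0)) stopf("'%s': negative probability", name)
  if (!ref %in% levels) stopf("'%s': ref level not among levels", name)
  b <- stats::setNames(rep(0, length(levels)), levels)
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% levels))
      stopf("'%s': beta must be named by category labels", name)
    b[names(beta)] <- beta
  }
  if (abs(b[[ref]]) > 0) stopf("'%s': reference level must carry coefficient 0", name)
  if (type == "binary" && length(levels) != 2L)
    stopf("'%s': binary type requires exactly 2 levels", name)
  structure(list(name = name, levels = levels, probs = probs, beta = b,
                 ref = ref, type = type, condition = condition),
            class = "roster_entry")
}

#' Rescale raw percentages to probabilities
#' @param p nonnegative numeric vector (e.g. observed percentages).
#' @return `p / sum(p)`.
#' @export
normalize_probs <- function(p) p / sum(p)

#' Convert a hazard ratio to a log-time AFT coefficient
#'
#' In a Weibull AFT model with scale `sigma`, a hazard ratio HR for a
#' level corresponds to the log-time coefficient `beta = -sigma * log(HR)`.
#'
#' @param hr hazard ratio(s), possibly named.
#' @param sigma Weibull AFT scale parameter.
#' @return named log-time coefficients.
#' @export
hr_to_beta <- function(hr, sigma) {
  stats::setNames(-sigma * log(hr), names(hr))
}

## Default rosters ---------------------------------------------------------
##
## Marginals follow the weighted baseline distribution of a pooled
## multi-cycle national health-survey cohort (observed categories
## renormalized); true coefficients are derived from published
## mode-imputation hazard ratios of a premature-mortality risk model via
## beta = -sigma log(HR) with sigma = 0.82. These are overridable defaults,
## not estimates.

#' Default predictor roster, female risk model
#'
#' Twelve-predictor female roster: household income quintile, education,
#' BMI category, self-perceived general health, smoking status, physical
#' activity, and five chronic-condition indicators (age is handled
#' separately, see [generator_config()]).
#'
#' @param sigma true AFT scale used to convert hazard ratios to log-time
#'   coefficients (default 0.82).
#' @return list of [roster_entry()] objects.
#' @export
default_roster_female <- function(sigma = 0.82) {
  list(
    roster_entry("income", c("Q1", "Q2", "Q3", "Q4", "Q5"),
                 normalize_probs(c(13.8, 14.5, 18.5, 22.0, 20.3)),
                 hr_to_beta(c(Q1 = 1.24, Q2 = 1.09, Q3 = 1.09, Q4 = 1.13), sigma),
                 ref = "Q5", type = "ordinal"),
    roster_entry("education", c("less_secondary", "secondary", "post_secondary"),
                 normalize_probs(c(7.1, 10.5, 77.9)),
                 hr_to_beta(c(less_secondary = 1.13, secondary = 1.03), sigma),
                 ref = "post_secondary", type = "ordinal"),
    roster_entry("bmi", c("under", "normal", "over", "obese1", "obese2", "obese3"),
                 normalize_probs(c(3.9, 51.1, 25.8, 10.5, 3.5, 1.8)),
                 hr_to_beta(c(under = 1.55, over = 0.74, obese1 = 0.65,
                              obese2 = 0.67, obese3 = 0.91), sigma),
                 ref = "normal", type = "ordinal"),
    roster_entry("selfhealth", c("poor", "fair", "good", "very_good", "excellent"),
                 normalize_probs(c(2.7, 8.6, 28.3, 38.0, 22.4)),
                 hr_to_beta(c(poor = 6.20, fair = 2.83, good = 1.71,
                              very_good = 1.20), sigma),
                 ref = "excellent", type = "ordinal"),
    roster_entry("smoking", c("never", "former_light", "former_heavy",
                              "current_light", "current_heavy"),
                 normalize_probs(c(54.0, 16.6, 5.0, 18.4, 2.9)),
                 hr_to_beta(c(former_light = 1.59, former_heavy = 1.93,
                              current_light = 2.34, current_heavy = 2.76), sigma),
                 ref = "never", type = "nominal"),
    roster_entry("physact", c("active", "moderate", "inactive"),
                 normalize_probs(c(22.4, 25.4, 50.6)),
                 hr_to_beta(c(moderate = 1.09, inactive = 1.40), sigma),
                 ref = "active", type = "ordinal"),
    roster_entry("copd", c("No", "Yes"), c(0.983, 0.017),
                 hr_to_beta(c(Yes = 1.23), sigma), type = "binary", condition = TRUE),
    roster_entry("heart_disease", c("No", "Yes"), c(0.967, 0.033),
                 hr_to_beta(c(Yes = 1.22), sigma), type = "binary", condition = TRUE),
    roster_entry("diabetes", c("No", "Yes"), c(0.953, 0.047),
                 hr_to_beta(c(Yes = 1.30), sigma), type = "binary", condition = TRUE),
    roster_entry("cancer", c("No", "Yes"), c(0.982, 0.018),
                 hr_to_beta(c(Yes = 5.31), sigma), type = "binary", condition = TRUE),
    roster_entry("stroke", c("No", "Yes"), c(0.992, 0.008),
                 hr_to_beta(c(Yes = 1.37), sigma), type = "binary", condition = TRUE)
  )
}

#' Default predictor roster, male risk model
#'
#' Thirteen-predictor male roster (no BMI / physical activity; adds
#' marital status, Alzheimer's disease and arthritis).
#'
#' @inheritParams default_roster_female
#' @return list of [roster_entry()] objects.
#' @export
default_roster_male <- function(sigma = 0.82) {
  list(
    roster_entry("income", c("Q1", "Q2", "Q3", "Q4", "Q5"),
                 normalize_probs(c(10.6, 12.4, 17.8, 24.5, 26.4)),
                 hr_to_beta(c(Q1 = 1.38, Q2 = 1.46, Q3 = 1.23, Q4 = 1.14), sigma),
                 ref = "Q5", type = "ordinal"),
    roster_entry("marital", c("single", "partner", "wid_sep_div"),
                 normalize_probs(c(26.8, 65.7, 7.4)),
                 hr_to_beta(c(partner = 0.56, wid_sep_div = 0.90), sigma),
                 ref = "single", type = "nominal"),
    roster_entry("education", c("less_secondary", "secondary", "post_secondary"),
                 normalize_probs(c(6.2, 10.3, 77.4)),
                 hr_to_beta(c(less_secondary = 1.10, secondary = 1.07), sigma),
                 ref = "post_secondary", type = "ordinal"),
    roster_entry("selfhealth", c("poor", "fair", "good", "very_good", "excellent"),
                 normalize_probs(c(2.4, 7.8, 28.4, 37.9, 23.4)),
                 hr_to_beta(c(poor = 5.48, fair = 2.49, good = 1.59,
                              very_good = 1.13), sigma),
                 ref = "excellent", type = "ordinal"),
    roster_entry("smoking", c("never", "former_light", "former_heavy",
                              "current_light", "current_heavy"),
                 normalize_probs(c(44.4, 16.7, 9.4, 20.3, 5.7)),
                 hr_to_beta(c(former_light = 1.17, former_heavy = 1.56,
                              current_light = 2.08, current_heavy = 2.87), sigma),
                 ref = "never", type = "nominal"),
    roster_entry("copd", c("No", "Yes"), c(0.985, 0.015),
                 hr_to_beta(c(Yes = 1.23), sigma), type = "binary", condition = TRUE),
    roster_entry("heart_disease", c("No", "Yes"), c(0.952, 0.048),
                 hr_to_beta(c(Yes = 1.25), sigma), type = "binary", condition = TRUE),
    roster_entry("diabetes", c("No", "Yes"), c(0.942, 0.058),
                 hr_to_beta(c(Yes = 1.33), sigma), type = "binary", condition = TRUE),
    roster_entry("cancer", c("No", "Yes"), c(0.985, 0.015),
                 hr_to_beta(c(Yes = 3.49), sigma), type = "binary", condition = TRUE),
    roster_entry("stroke", c("No", "Yes"), c(0.991, 0.009),
                 hr_to_beta(c(Yes = 1.27), sigma), type = "binary", condition = TRUE),
    roster_entry("alzheimers", c("No", "Yes"), c(0.998, 0.002),
                 hr_to_beta(c(Yes = 2.02), sigma), type = "binary", condition = TRUE),
    roster_entry("arthritis", c("No", "Yes"), c(0.883, 0.117),
                 hr_to_beta(c(Yes = 0.76), sigma), type = "binary", condition = TRUE)
  )
}

roster_names <- function(roster) vapply(roster, `[[`, character(1), "name")

roster_get <- function(roster, name) {
  idx <- match(name, roster_names(roster))
  if (is.na(idx)) stopf("variable '%s' not in roster", name)
  roster[[idx]]
}
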