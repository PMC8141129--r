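# Domain types for the screening model: strata, test characteristics, costs,
# utilities, risks, economic settings, and the assembled model configuration.

BMI_LEVELS <- c("underweight", "normal", "overweight", "obese")

#' Age-by-BMI stratum identifier
#'
#' The model is stratified by age band and BMI category; each stratum gets its
#' own fully parameterized state-transition model.
#'
#' @param age_low,age_high integer bounds (years) of the age band at entry.
#' @param bmi_category one of `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"` (WHO cut-offs at 18.5, 25 and 30 kg/m^2).
#' @return an object of class `stratum_key`.
#' @export
stratum_key <- function(age_low, age_high, bmi_category) {
  assert_scalar_number(age_low, "age_low", lower = 0)
  assert_scalar_number(age_high, "age_high", lower = 0)
  if (!is.character(bmi_category) || length(bmi_category) != 1L ||
      !bmi_category %in% BMI_LEVELS) {
    stop_hbs("bmi_category must be one of: ", paste(BMI_LEVELS, collapse = ", "),
             class = "validation_error")
  }
  structure(
    list(age_low = as.integer(age_low), age_high = as.integer(age_high),
         bmi_category = bmi_category),
    class = "stratum_key"
  )
}

#' @export
format.stratum_key <- function(x, ...) {
  sprintf("%s %d-%d", x$bmi_category, x$age_low, x$age_high)
}

#' @export
print.stratum_key <- function(x, ...) {
  cat("<stratum>", format(x), "\n")
  invisible(x)
}

#' Interval-specific screening test characteristics
#'
#' Sensitivity and specificity of the HbA1c test for one screening interval.
#' They are interval-dependent because the reference standard is progression
#' to diabetes over the interval, so longer intervals catch more progression
#' (higher sensitivity).
#'
#' @param label strategy label, e.g. `"3-year"`.
#' @param interval_years positive integer years between screens.
#' @param sensitivity,specificity probabilities in \[0, 1\].
#' @return an object of class `test_characteristics`.
#' @export
test_characteristics <- function(label, interval_years, sensitivity, specificity) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_hbs("label must be a non-empty string", class = "validation_error")
  }
  assert_scalar_number(interval_years, "interval_years", lower = 1)
  assert_scalar_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  assert_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  structure(
    list(label = label, interval_years = as.integer(interval_years),
         sensitivity = sensitivity, specificity = specificity),
    class = "test_characteristics"
  )
}

#' Cost parameters (USD, annual unless stated)
#'
#' @param screening_cost USD per HbA1c screen.
#' @param tx_no_comp_annual annual treatment fee, treated diabetes without
#'   complication.
#' @param tx_comp_annual annual treatment fee, diabetes with complication.
#' @param fp_annual annual follow-up fee for false positives (education only,
#'   no medication).
#' @return an object of class `cost_set`.
#' @export
cost_set <- function(screening_cost, tx_no_comp_annual, tx_comp_annual, fp_annual) {
  assert_scalar_number(screening_cost, "screening_cost", lower = 0)
  assert_scalar_number(tx_no_comp_annual, "tx_no_comp_annual", lower = 0)
  assert_scalar_number(tx_comp_annual, "tx_comp_annual", lower = 0)
  assert_scalar_number(fp_annual, "fp_annual", lower = 0)
  structure(
    list(screening_cost = screening_cost, tx_no_comp_annual = tx_no_comp_annual,
         tx_comp_annual = tx_comp_annual, fp_annual = fp_annual),
    class = "cost_set"
  )
}

#' Health-state utility weights
#'
#' @param healthy utility of full health (1 in the default preset).
#' @param t2dm_no_comp utility with diabetes, no complication (0.785).
#' @param t2dm_comp utility with diabetes and complication; an aggregate over
#'   complication types weighted by their reported proportions (0.638).
#' @return an object of class `utility_set`.
#' @export
utility_set <- function(healthy, t2dm_no_comp, t2dm_comp) {
  assert_scalar_number(healthy, "healthy", lower = 0, upper = 1)
  assert_scalar_number(t2dm_no_comp, "t2dm_no_comp", lower = 0, upper = 1)
  assert_scalar_number(t2dm_comp, "t2dm_comp", lower = 0, upper = 1)
  structure(
    list(healthy = healthy, t2dm_no_comp = t2dm_no_comp, t2dm_comp = t2dm_comp),
    class = "utility_set"
  )
}

#' Disease-progression and mortality risks
#'
#' Relative risks act on annual death (or complication) probabilities on the
#' hazard scale, `1 - (1 - q)^rr`, so adjusted probabilities stay in \[0, 1\]
#' (see [adjusted_mortality()]).
#'
#' @param annual_incidence annual probability healthy -> diabetes
#'   (stratum-specific; no built-in default exists, it must be supplied).
#' @param annual_comp_rate annual complication probability while untreated.
#' @param rr_comp_treated relative risk of complication under treatment
#'   (0.79 in the default preset).
#' @param rr_mort_comp relative mortality risk with complication (5.22).
#' @param rr_mort_untreated relative mortality risk with untreated,
#'   complication-free diabetes (2.61).
#' @param rr_mort_treated relative mortality risk under treatment without
#'   complication; 1 by default (treated patients assumed to match background
#'   mortality).
#' @return an object of class `risk_set`.
#' @export
risk_set <- function(annual_incidence, annual_comp_rate, rr_comp_treated,
                     rr_mort_comp, rr_mort_untreated, rr_mort_treated = 1.0) {
  assert_scalar_number(annual_incidence, "annual_incidence", lower = 0, upper = 1)
  assert_scalar_number(annual_comp_rate, "annual_comp_rate", lower = 0, upper = 1)
  assert_scalar_number(rr_comp_treated, "rr_comp_treated", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rr_mort_comp, "rr_mort_comp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rr_mort_untreated, "rr_mort_untreated", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rr_mort_treated, "rr_mort_treated", lower = 0, strict_lower = TRUE)
  structure(
    list(annual_incidence = annual_incidence, annual_comp_rate = annual_comp_rate,
         rr_comp_treated = rr_comp_treated, rr_mort_comp = rr_mort_comp,
         rr_mort_untreated = rr_mort_untreated, rr_mort_treated = rr_mort_treated),
    class = "risk_set"
  )
}

#' Economic and simulation settings
#'
#' @param discount_rate annual discount rate applied to both costs and QALYs
#'   (0.02 in the default preset).
#' @param wtp willingness-to-pay threshold, USD per QALY (50,000).
#' @param cohort_size default number of simulated individuals (50,000).
#' @param max_age simulation horizon: individuals are followed to death or
#'   this age, whichever comes first.
#' @param seed default integer seed.
#' @param entry_age optional fixed entry age; `NULL` (default) samples entry
#'   ages uniformly over the stratum's age band.
#' @return an object of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate = 0.02, wtp = 50000, cohort_size = 50000,
                          max_age = 110, seed = 1L, entry_age = NULL) {
  assert_scalar_number(discount_rate, "discount_rate", lower = 0)
  assert_scalar_number(wtp, "wtp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cohort_size, "cohort_size", lower = 1)
  assert_scalar_number(max_age, "max_age", lower = 1)
  assert_scalar_number(seed, "seed")
  if (!is.null(entry_age)) assert_scalar_number(entry_age, "entry_age", lower = 0)
  structure(
    list(discount_rate = discount_rate, wtp = wtp,
         cohort_size = as.integer(cohort_size), max_age = as.integer(max_age),
         seed = as.integer(seed),
         entry_age = if (is.null(entry_age)) NULL else as.integer(entry_age)),
    class = "econ_settings"
  )
}

# Scalar parameters that a PSA distribution may target, with their location in
# the config and the legal domain used for rejection sampling.
psa_parameter_table <- function() {
  data.frame(
    name = c("screening_cost", "tx_no_comp_annual", "tx_comp_annual", "fp_annual",
             "annual_incidence", "annual_comp_rate",
             "rr_comp_treated", "rr_mort_comp", "rr_mort_untreated", "rr_mort_treated",
             "u_healthy", "u_t2dm_no_comp", "u_t2dm_comp"),
    component = c(rep("costs", 4), rep("risks", 6), rep("utilities", 3)),
    field = c("screening_cost", "tx_no_comp_annual", "tx_comp_annual", "fp_annual",
              "annual_incidence", "annual_comp_rate",
              "rr_comp_treated", "rr_mort_comp", "rr_mort_untreated", "rr_mort_treated",
              "healthy", "t2dm_no_comp", "t2dm_comp"),
    lower = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    upper = c(Inf, Inf, Inf, Inf, 1, 1, Inf, Inf, Inf, Inf, 1, 1, 1),
    strict_lower = c(rep(FALSE, 6), rep(TRUE, 4), rep(FALSE, 3)),
    stringsAsFactors = FALSE
  )
}

#' Assemble a full model configuration
#'
#' Bundles one stratum's complete parameterization: screening strategies,
#' costs, utilities, risks, economic settings, and (optionally) PSA
#' distributions.  Construction does not enforce the cross-field invariants;
#' use [validate_config()] (as [load_config()] does) to check them.
#'
#' @param stratum a [stratum_key()].
#' @param strategies list of [test_characteristics()] (at least 2 for any
#'   comparative analysis).
#' @param costs a [cost_set()].
#' @param utilities a [utility_set()].
#' @param risks a [risk_set()].
#' @param settings an [econ_settings()].
#' @param psa named list of [dist_spec()] objects, keyed by parameter name
#'   (see the `name` column of the table in [check_psa_consistency()] docs).
#' @return an object of class `model_config`.
#' @export
model_config <- function(stratum, strategies, costs, utilities, risks,
                         settings = econ_settings(), psa = list()) {
  stopifnot(inherits(stratum, "stratum_key"), inherits(costs, "cost_set"),
            inherits(utilities, "utility_set"), inherits(risks, "risk_set"),
            inherits(settings, "econ_settings"), is.list(strategies), is.list(psa))
  for (s in strategies) stopifnot(inherits(s, "test_characteristics"))
  for (d in psa) stopifnot(inherits(d, "dist_spec"))
  names(strategies) <- vapply(strategies, `[[`, "", "label")
  structure(
    list(stratum = stratum, strategies = strategies, costs = costs,
         utilities = utilities, risks = risks, settings = settings, psa = psa),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> stratum:", format(x$stratum), "\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  incidence:", x$risks$annual_incidence,
      " comp rate:", x$risks$annual_comp_rate, "\n")
  cat("  discount:", x$settings$discount_rate, " WTP:", x$settings$wtp,
      " max age:", x$settings$max_age, "\n")
  if (length(x$psa)) cat("  PSA parameters:", paste(names(x$psa), collapse = ", "), "\n")
  invisible(x)
}

finding <- function(field, message) {
  data.frame(field = field, finding = message, stringsAsFactors = FALSE)
}

#' Validate a model configuration
#'
#' Checks every cross-field invariant of a structurally complete
#' configuration and returns the violations as findings rather than raising.
#'
#' @param cfg a [model_config()].
#' @return a data frame with columns `field` and `finding`; zero rows iff the
#'   configuration is valid.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  out <- finding(character(), character())

  if (cfg$stratum$age_low >= cfg$stratum$age_high) {
    out <- rbind(out, finding("stratum.age_low", "age_low must be < age_high"))
  }
  if (length(cfg$strategies) < 2L) {
    out <- rbind(out, finding("strategies", "at least 2 strategies are required"))
  }
  labels <- vapply(cfg$strategies, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    out <- rbind(out, finding(
      "strategies.label",
      paste0("duplicate strategy labels: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))))
  }
  if (cfg$costs$tx_comp_annual < cfg$costs$tx_no_comp_annual) {
    out <- rbind(out, finding(
      "costs.tx_comp_annual",
      "tx_comp_annual must be >= tx_no_comp_annual"))
  }
  u <- cfg$utilities
  if (u$healthy < u$t2dm_no_comp) {
    out <- rbind(out, finding("utilities.t2dm_no_comp",
                              "healthy must be >= t2dm_no_comp"))
  }
  if (u$t2dm_no_comp < u$t2dm_comp) {
    out <- rbind(out, finding("utilities.t2dm_comp",
                              "t2dm_no_comp must be >= t2dm_comp"))
  }
  r <- cfg$risks
  if (r$rr_mort_comp < r$rr_mort_untreated) {
    out <- rbind(out, finding("risks.rr_mort_comp",
                              "rr_mort_comp must be >= rr_mort_untreated"))
  }
  if (r$rr_mort_untreated < r$rr_mort_treated) {
    out <- rbind(out, finding("risks.rr_mort_untreated",
                              "rr_mort_untreated must be >= rr_mort_treated"))
  }
  if (cfg$settings$max_age <= cfg$stratum$age_high) {
    out <- rbind(out, finding("settings.max_age",
                              "max_age must exceed the stratum's age_high"))
  }
  known <- psa_parameter_table()$name
  bad <- setdiff(names(cfg$psa), known)
  if (length(bad)) {
    out <- rbind(out, finding(
      "psa", paste0("unknown PSA parameter(s): ", paste(bad, collapse = ", "))))
  }
  out
}

#' Aggregate several utility weights into one
#'
#' Proportion-weighted mean, used to collapse per-complication utilities into
#' a single complication-state utility: `sum(w * u)`.
#'
#' @param utilities numeric vector of utility weights.
#' @param weights numeric vector of proportions, same length, non-negative,
#'   summing to 1 within `1e-9`.
#' @return the aggregated utility; always within `range(utilities)`.
#' @export
aggregate_utility <- function(utilities, weights) {
  if (length(utilities) != length(weights)) {
    stop_hbs("utilities and weights must have equal length",
             class = "validation_error")
  }
  if (any(weights < 0)) {
    stop_hbs("weights must be non-negative", class = "normalization_error")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_hbs("weights must sum to 1 (got ", format(sum(weights), digits = 12), ")",
             class = "normalization_error")
  }
  sum(weights * utilities)
}
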