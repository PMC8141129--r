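# Synthetic inputs and the built-in parameter preset.
#
# Two inputs of the published Japanese screening analysis are not public: the
# national period life table and the per-stratum annual incidence of type 2
# diabetes.  This module generates statistically plausible stand-ins for both
# (clearly labelled synthetic), and packages the published stratum-specific
# test characteristics and cost/utility/risk estimates as a preset so every
# pipeline stage runs end-to-end without external data.

AGE_BANDS <- list(c(30L, 44L), c(45L, 59L), c(60L, 74L))

#' The twelve age-by-BMI strata
#'
#' @return list of 12 [stratum_key()] objects (3 age bands x 4 BMI
#'   categories).
#' @export
all_strata <- function() {
  out <- list()
  for (band in AGE_BANDS) {
    for (bmi in BMI_LEVELS) {
      out[[length(out) + 1L]] <- stratum_key(band[1], band[2], bmi)
    }
  }
  out
}

age_band_index <- function(stratum) {
  for (i in seq_along(AGE_BANDS)) {
    if (AGE_BANDS[[i]][1] == stratum$age_low && AGE_BANDS[[i]][2] == stratum$age_high) {
      return(i - 1L)
    }
  }
  stop_hbs("unknown age band: ", stratum$age_low, "-", stratum$age_high,
           class = "lookup_error")
}

bmi_index <- function(stratum) match(stratum$bmi_category, BMI_LEVELS) - 1L

#' Settings for the synthetic input generator
#'
#' The incidence rule is multiplicative on the ordinal stratum indices:
#' `incidence_base * incidence_age_slope^a * incidence_bmi_slope^b` with age
#' band index a in 0..2 and BMI index b in 0..3, clipped to \[0, 0.5\] —
#' incidence rises with age and BMI, matching the epidemiology the model is
#' built around, but the default magnitudes are synthetic, not estimates.
#'
#' @param seed integer seed.
#' @param n_strata number of strata (12; informational).
#' @param incidence_base annual incidence in the youngest underweight stratum.
#' @param incidence_age_slope multiplicative increase per age band.
#' @param incidence_bmi_slope multiplicative increase per BMI category.
#' @param sens_range,spec_range intervals from which generated test
#'   sensitivities/specificities are drawn.
#' @return an object of class `generator_settings`.
#' @export
generator_settings <- function(seed = 1L, n_strata = 12L,
                               incidence_base = 0.003,
                               incidence_age_slope = 1.6,
                               incidence_bmi_slope = 1.8,
                               sens_range = c(0.3, 0.9),
                               spec_range = c(0.97, 1.0)) {
  assert_scalar_number(incidence_base, "incidence_base", lower = 0, upper = 1)
  assert_scalar_number(incidence_age_slope, "incidence_age_slope",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(incidence_bmi_slope, "incidence_bmi_slope",
                       lower = 0, strict_lower = TRUE)
  stopifnot(length(sens_range) == 2L, length(spec_range) == 2L,
            all(sens_range >= 0 & sens_range <= 1),
            all(spec_range >= 0 & spec_range <= 1),
            sens_range[1] <= sens_range[2], spec_range[1] <= spec_range[2])
  structure(
    list(seed = as.integer(seed), n_strata = as.integer(n_strata),
         incidence_base = incidence_base,
         incidence_age_slope = incidence_age_slope,
         incidence_bmi_slope = incidence_bmi_slope,
         sens_range = sens_range, spec_range = spec_range),
    class = "generator_settings"
  )
}

#' Synthetic annual T2DM incidence for a stratum
#'
#' @param stratum a [stratum_key()] from [all_strata()].
#' @param gs a [generator_settings()].
#' @return annual incidence probability, increasing in age band and BMI
#'   category when both slopes exceed 1; clipped to \[0, 0.5\].
#' @export
gen_incidence <- function(stratum, gs = generator_settings()) {
  v <- gs$incidence_base *
    gs$incidence_age_slope^age_band_index(stratum) *
    gs$incidence_bmi_slope^bmi_index(stratum)
  min(max(v, 0), 0.5)
}

#' Generate a complete synthetic model configuration
#'
#' Uses the preset costs/utilities/risks, a synthetic incidence from
#' [gen_incidence()], and three screening strategies (annual, 3-year, 6-year)
#' whose sensitivities are drawn from `sens_range` and sorted ascending in
#' interval length — longer intervals catch more progression — with
#' specificities drawn from `spec_range` sorted descending.  Deterministic
#' given `gs$seed`; always passes [validate_config()] with zero findings.
#'
#' @inheritParams gen_incidence
#' @return a `model_config`.
#' @export
gen_config <- function(stratum, gs = generator_settings()) {
  set.seed(derive_seed(gs$seed, "gen-config", format(stratum)))
  intervals <- c(1L, 3L, 6L)
  sens <- sort(stats::runif(3, gs$sens_range[1], gs$sens_range[2]))
  spec <- sort(stats::runif(3, gs$spec_range[1], gs$spec_range[2]),
               decreasing = TRUE)
  strategies <- lapply(seq_along(intervals), function(i) {
    test_characteristics(strategy_label(intervals[i]), intervals[i], sens[i], spec[i])
  })
  preset_config(stratum, annual_incidence = gen_incidence(stratum, gs),
                strategies = strategies, seed = gs$seed)
}

strategy_label <- function(interval) {
  if (interval == 1L) "annual" else paste0(interval, "-year")
}

# Published interval-specific HbA1c test characteristics, one block per
# stratum (sensitivities/specificities as fractions; "approximately zero"
# annual sensitivities encoded as exactly 0).  Single source of truth for the
# preset.
preset_test_table <- function() {
  rows <- list(
    # age_low, bmi, interval, sens, spec
    list(30L, "underweight", c(1L, 3L, 10L), c(0.0, 0.500, 0.818), c(1.000, 1.000, 0.999)),
    list(30L, "normal",      c(1L, 3L, 6L),  c(0.0, 0.475, 0.681), c(1.000, 0.999, 0.999)),
    list(30L, "overweight",  c(1L, 3L, 4L),  c(0.0, 0.545, 0.578), c(1.000, 0.997, 0.996)),
    list(30L, "obese",       c(1L, 2L, 3L),  c(0.0, 0.375, 0.622), c(1.000, 0.991, 0.986)),
    list(45L, "underweight", c(1L, 3L, 10L), c(0.0, 0.667, 0.700), c(1.000, 0.998, 0.997)),
    list(45L, "normal",      c(1L, 3L, 6L),  c(0.0, 0.560, 0.735), c(1.000, 0.997, 0.995)),
    list(45L, "overweight",  c(1L, 3L, 4L),  c(0.025, 0.611, 0.668), c(1.000, 0.991, 0.990)),
    list(45L, "obese",       c(1L, 3L, 4L),  c(0.0, 0.620, 0.714), c(1.000, 0.980, 0.980)),
    list(60L, "underweight", c(1L, 3L, 6L),  c(0.0, 0.500, 0.875), c(1.000, 0.995, 0.993)),
    list(60L, "normal",      c(1L, 3L, 7L),  c(0.0, 0.503, 0.727), c(1.000, 0.993, 0.991)),
    list(60L, "overweight",  c(1L, 3L, 5L),  c(0.0, 0.523, 0.645), c(1.000, 0.991, 0.987)),
    list(60L, "obese",       c(1L, 3L, 4L),  c(0.0, 0.600, 0.700), c(1.000, 0.975, 0.975))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(age_low = r[[1]],
               age_high = r[[1]] + 14L,
               bmi_category = r[[2]],
               interval_years = r[[3]], sensitivity = r[[4]], specificity = r[[5]],
               stringsAsFactors = FALSE)
  }))
}

#' Preset test characteristics for one stratum
#'
#' @param stratum a [stratum_key()] from [all_strata()].
#' @return list of three [test_characteristics()] (annual plus two longer
#'   intervals, stratum-specific).
#' @export
preset_strategies <- function(stratum) {
  tab <- preset_test_table()
  block <- tab[tab$age_low == stratum$age_low &
                 tab$age_high == stratum$age_high &
                 tab$bmi_category == stratum$bmi_category, ]
  if (!nrow(block)) {
    stop_hbs("no preset for stratum ", format(stratum), class = "lookup_error")
  }
  lapply(seq_len(nrow(block)), function(i) {
    test_characteristics(strategy_label(block$interval_years[i]),
                         block$interval_years[i],
                         block$sensitivity[i], block$specificity[i])
  })
}

#' Built-in model parameterization for one stratum
#'
#' Assembles the published parameterization of the Japanese HbA1c screening
#' model: stratum-specific interval/sensitivity/specificity triplets, the
#' point-estimate costs (screening 100, treatment 3,500 / 8,000,
#' false-positive follow-up 1,400 USD), utilities (1 / 0.785 / 0.638),
#' risks (complication rate 0.014, mortality relative risks 5.22 / 2.61 / 1,
#' treated complication relative risk 0.79), settings (2% discount, $50,000
#' WTP, 50,000 individuals, horizon age 110), and the PSA distributions as
#' printed (gamma costs, lognormal relative risks, beta complication rate).
#' Published variants exist for three parameters and can be selected via the
#' arguments: screening cost 80 instead of 100, `rr_mort_comp` 5.61 instead
#' of 5.22, `rr_comp_treated` 0.78 instead of 0.79.
#'
#' The stratum-specific annual incidence was never published; it has no
#' default and must be supplied (e.g. from [gen_incidence()]).
#'
#' @param stratum a [stratum_key()] from [all_strata()].
#' @param annual_incidence required annual probability healthy -> T2DM.
#' @param screening_cost USD per screen (default 100; published alternate 80).
#' @param rr_mort_comp mortality relative risk with complication (default
#'   5.22; published alternate 5.61).
#' @param rr_comp_treated treated complication relative risk (default 0.79;
#'   published alternate 0.78).
#' @param strategies optional replacement strategy list (default: the
#'   stratum's preset strategies).
#' @param seed integer seed stored in the settings.
#' @return a validated `model_config`.
#' @export
preset_config <- function(stratum, annual_incidence,
                          screening_cost = 100, rr_mort_comp = 5.22,
                          rr_comp_treated = 0.79,
                          strategies = preset_strategies(stratum),
                          seed = 1L) {
  if (missing(annual_incidence)) {
    stop_hbs("annual_incidence has no published value and must be supplied ",
             "(see gen_incidence() for a synthetic one)",
             class = "validation_error")
  }
  psa <- list(
    screening_cost = dist_spec("gamma", screening_cost, shape = 27.3, scale = 292),
    tx_no_comp_annual = dist_spec("gamma", 3500, shape = 84146, scale = 3),
    tx_comp_annual = dist_spec("gamma", 8000, shape = 26540, scale = 22),
    fp_annual = dist_spec("gamma", 1400, shape = 1752, scale = 60),
    rr_mort_comp = dist_spec("lognormal", rr_mort_comp,
                             log_mean = 1.65, log_sd = 0.08),
    rr_mort_untreated = dist_spec("lognormal", 2.61,
                                  log_mean = 0.95, log_sd = 0.14),
    annual_comp_rate = dist_spec("beta", 0.014, alpha = 2.27, beta = 160.3),
    rr_comp_treated = dist_spec("lognormal", rr_comp_treated,
                                log_mean = -0.23, log_sd = 0.09)
  )
  cfg <- model_config(
    stratum = stratum,
    strategies = strategies,
    costs = cost_set(screening_cost = screening_cost, tx_no_comp_annual = 3500,
                     tx_comp_annual = 8000, fp_annual = 1400),
    utilities = utility_set(healthy = 1, t2dm_no_comp = 0.785, t2dm_comp = 0.638),
    risks = risk_set(annual_incidence = annual_incidence,
                     annual_comp_rate = 0.014,
                     rr_comp_treated = rr_comp_treated,
                     rr_mort_comp = rr_mort_comp,
                     rr_mort_untreated = 2.61,
                     rr_mort_treated = 1.0),
    settings = econ_settings(discount_rate = 0.02, wtp = 50000,
                             cohort_size = 50000, max_age = 110, seed = seed),
    psa = psa
  )
  bad <- validate_config(cfg)
  if (nrow(bad)) {
    stop_hbs("preset configuration invalid: ",
             paste(bad$finding, collapse = "; "), class = "validation_error")
  }
  cfg
}

#' Published per-strategy outcomes for the twelve strata
#'
#' The discounted mean (QALY, cost) pairs reported for every stratum and
#' interval by the original 50,000-person microsimulation of this model, as
#' printed (2 decimals).  Shipped as reference inputs for the incremental
#' analysis: feeding them to [build_cea_table()] reproduces the published
#' dominance structure and recommended intervals wherever the rounded values
#' are self-consistent.
#'
#' @return data frame with columns `age_low`, `age_high`, `bmi_category`,
#'   `label`, `qaly`, `cost`.
#' @export
reference_outcomes <- function() {
  rows <- list(
    list(30L, "underweight", c("annual", "3-year", "10-year"),
         c(30.12, 30.16, 30.16), c(2467.16, 963.10, 405.92)),
    list(30L, "normal", c("annual", "3-year", "6-year"),
         c(30.13, 30.15, 30.14), c(2489.28, 1112.80, 726.86)),
    list(30L, "overweight", c("annual", "3-year", "4-year"),
         c(29.86, 29.97, 29.97), c(2894.63, 2678.14, 2477.31)),
    list(30L, "obese", c("annual", "2-year", "3-year"),
         c(28.88, 29.18, 29.19), c(4313.80, 8965.05, 8948.87)),
    list(45L, "underweight", c("annual", "3-year", "10-year"),
         c(23.54, 23.55, 23.55), c(1949.99, 879.01, 408.86)),
    list(45L, "normal", c("annual", "3-year", "6-year"),
         c(23.45, 23.48, 23.49), c(2081.91, 1445.89, 1107.16)),
    list(45L, "overweight", c("annual", "3-year", "4-year"),
         c(23.17, 23.20, 23.26), c(2763.11, 2753.06, 2908.66)),
    list(45L, "obese", c("annual", "3-year", "4-year"),
         c(22.27, 22.66, 22.63), c(3024.01, 7647.58, 7348.82)),
    list(60L, "underweight", c("annual", "3-year", "6-year"),
         c(15.74, 15.77, 15.75), c(1325.15, 651.84, 453.10)),
    list(60L, "normal", c("annual", "3-year", "7-year"),
         c(15.69, 15.72, 15.70), c(1379.50, 1039.23, 719.29)),
    list(60L, "overweight", c("annual", "3-year", "5-year"),
         c(15.47, 15.56, 15.54), c(1481.22, 1829.22, 1553.58)),
    list(60L, "obese", c("annual", "3-year", "4-year"),
         c(15.01, 15.23, 15.21), c(1617.53, 3552.88, 3363.21))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(age_low = r[[1]], age_high = r[[1]] + 14L, bmi_category = r[[2]],
               label = r[[3]], qaly = r[[4]], cost = r[[5]],
               stringsAsFactors = FALSE)
  }))
}

#' Published recommended screening intervals
#'
#' The 4 x 3 matrix of intervals recommended at the $50,000/QALY threshold in
#' the original analysis, in long form.
#'
#' @return data frame with columns `age_low`, `age_high`, `bmi_category`,
#'   `label`.
#' @export
reference_recommendations <- function() {
  rec <- c(
    underweight = "10-year", normal = "6-year", overweight = "4-year", obese = "3-year",
    underweight = "10-year", normal = "6-year", overweight = "3-year", obese = "3-year",
    underweight = "3-year", normal = "3-year", overweight = "3-year", obese = "3-year"
  )
  data.frame(
    age_low = rep(c(30L, 45L, 60L), each = 4L),
    age_high = rep(c(44L, 59L, 74L), each = 4L),
    bmi_category = rep(BMI_LEVELS, 3L),
    label = unname(rec), stringsAsFactors = FALSE
  )
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits one YAML configuration per stratum (synthetic incidence, preset
#' costs/utilities/risks, preset strategies) plus a synthetic Gompertz-Makeham
#' life table CSV; the files are consumed unchanged by [load_config()],
#' [read_life_table()], and the report drivers.
#'
#' @param dir output directory (created if needed).
#' @param gs a [generator_settings()].
#' @param use_preset_strategies if `TRUE` (default) use the published
#'   stratum-specific test characteristics; otherwise generate them too.
#' @return invisibly, the paths written (`configs` and `life_table`).
#' @export
write_fixtures <- function(dir, gs = generator_settings(),
                           use_preset_strategies = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (st in all_strata()) {
    cfg <- if (use_preset_strategies) {
      preset_config(st, annual_incidence = gen_incidence(st, gs), seed = gs$seed)
    } else {
      gen_config(st, gs)
    }
    p <- file.path(dir, sprintf("config_%s_%d_%d.yaml", st$bmi_category,
                                st$age_low, st$age_high))
    write_config(cfg, p)
    paths <- c(paths, p)
  }
  ltp <- file.path(dir, "life_table.csv")
  write_life_table(make_gompertz_lifetable(), ltp)
  invisible(list(configs = paths, life_table = ltp))
}
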