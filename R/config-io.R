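# Reading and writing model configurations as YAML.
#
# Schema (one stratum per file):
#   stratum:    {age_low, age_high, bmi_category}
#   strategies: [{label, interval_years, sensitivity, specificity}, ...]
#   costs:      {screening_cost, tx_no_comp_annual, tx_comp_annual, fp_annual}
#   utilities:  {healthy, t2dm_no_comp, t2dm_comp}
#   risks:      {annual_incidence, annual_comp_rate, rr_comp_treated,
#                rr_mort_comp, rr_mort_untreated, rr_mort_treated}
#   settings:   {discount_rate, wtp, cohort_size, max_age, seed[, entry_age]}
#   psa:        {<parameter>: {family, point_estimate, <family params>}, ...}
# Unknown keys are rejected everywhere; `psa` and `settings.entry_age` are the
# only optional pieces.

schema_error <- function(...) stop_hbs(..., class = "schema_error")

check_keys <- function(x, required, optional = character(), where) {
  if (!is.list(x)) schema_error("section '", where, "' must be a mapping")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    schema_error("missing required field '", paste0(where, ".", missing[1]), "'")
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    schema_error("unknown field '", paste0(where, ".", unknown[1]), "'")
  }
  invisible(x)
}

parse_dist_spec <- function(x, where) {
  check_keys(x, required = c("family", "point_estimate"),
             optional = c("shape", "scale", "log_mean", "log_sd", "alpha", "beta"),
             where = where)
  do.call(dist_spec, x)
}

#' Read a model configuration file
#'
#' Parses and fully validates a YAML configuration (schema in the package
#' source and the methods vignette).  Unknown keys, missing fields,
#' out-of-range values, and cross-field invariant violations all raise.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [model_config()].
#' @seealso [write_config()], [validate_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_hbs("config file not found: ", path, class = "io_error")
  }
  raw <- yaml::read_yaml(path)
  cfg <- config_from_list(raw)
  bad <- validate_config(cfg)
  if (nrow(bad)) {
    stop_hbs("invalid configuration: ",
             paste(sprintf("[%s] %s", bad$field, bad$finding), collapse = "; "),
             class = "validation_error")
  }
  cfg
}

# Build a model_config from a plain nested list (already-parsed YAML).
config_from_list <- function(raw) {
  check_keys(raw, required = c("stratum", "strategies", "costs", "utilities",
                               "risks", "settings"),
             optional = "psa", where = "config")
  check_keys(raw$stratum, c("age_low", "age_high", "bmi_category"), where = "stratum")
  if (!is.list(raw$strategies) || !length(raw$strategies)) {
    schema_error("missing required field 'strategies'")
  }
  strategies <- lapply(seq_along(raw$strategies), function(i) {
    s <- check_keys(raw$strategies[[i]],
                    c("label", "interval_years", "sensitivity", "specificity"),
                    where = sprintf("strategies[%d]", i))
    do.call(test_characteristics, s)
  })
  check_keys(raw$costs, c("screening_cost", "tx_no_comp_annual",
                          "tx_comp_annual", "fp_annual"), where = "costs")
  check_keys(raw$utilities, c("healthy", "t2dm_no_comp", "t2dm_comp"),
             where = "utilities")
  check_keys(raw$risks, c("annual_incidence", "annual_comp_rate",
                          "rr_comp_treated", "rr_mort_comp", "rr_mort_untreated"),
             optional = "rr_mort_treated", where = "risks")
  check_keys(raw$settings, c("discount_rate", "wtp", "cohort_size", "max_age", "seed"),
             optional = "entry_age", where = "settings")
  psa <- list()
  if (!is.null(raw$psa)) {
    if (!is.list(raw$psa) || is.null(names(raw$psa))) {
      schema_error("'psa' must be a mapping of parameter name to distribution")
    }
    psa <- lapply(names(raw$psa), function(nm) {
      parse_dist_spec(raw$psa[[nm]], where = paste0("psa.", nm))
    })
    names(psa) <- names(raw$psa)
  }
  model_config(
    stratum = do.call(stratum_key, raw$stratum),
    strategies = strategies,
    costs = do.call(cost_set, raw$costs),
    utilities = do.call(utility_set, raw$utilities),
    risks = do.call(risk_set, raw$risks),
    settings = do.call(econ_settings, raw$settings),
    psa = psa
  )
}

config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  out <- list(
    stratum = unclass(cfg$stratum),
    strategies = lapply(unname(cfg$strategies), unclass),
    costs = unclass(cfg$costs),
    utilities = unclass(cfg$utilities),
    risks = unclass(cfg$risks),
    settings = Filter(Negate(is.null), unclass(cfg$settings))
  )
  if (length(cfg$psa)) {
    out$psa <- lapply(cfg$psa, function(d) {
      c(list(family = d$family, point_estimate = d$point_estimate), d$params)
    })
  }
  out
}

#' Write a model configuration file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces an identical configuration.
#'
#' @param cfg a [model_config()].
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 15)
  invisible(path)
}

#' Export validation or consistency findings as CSV
#'
#' @param findings a data frame of findings, e.g. from [validate_config()]
#'   (a `suggested_fix` column is added if absent) or
#'   `check_psa_consistency()$findings`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_findings_csv <- function(findings, path) {
  if (is.null(findings$suggested_fix)) findings$suggested_fix <- ""
  utils::write.csv(findings[, c("field", "finding", "suggested_fix")],
                   path, row.names = FALSE)
  invisible(path)
}
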