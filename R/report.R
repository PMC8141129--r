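# Pipeline drivers: run the base-case analysis or the PSA over a bundle of
# stratum configurations and write the table-style CSV outputs plus a run
# manifest sufficient for bit-identical reproduction.

write_manifest <- function(out_dir, command, config_paths, life_table_path,
                           seed, sizes, mode) {
  manifest <- list(
    command = command,
    configs = as.character(config_paths),
    life_table = life_table_path,
    seed = seed,
    sizes = sizes,
    mode = mode,
    package_version = as.character(utils::packageVersion("hbscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Build the recommendation matrix from CEA tables
#'
#' @param tabs list of `cea_table` objects whose `stratum` fields are set.
#' @return data frame: rows = BMI categories, one column per age band,
#'   entries = recommended strategy labels.
#' @export
recommendation_matrix <- function(tabs) {
  bands <- vapply(tabs, function(x) sprintf("%d-%d", x$stratum$age_low,
                                            x$stratum$age_high), "")
  bmis <- vapply(tabs, function(x) x$stratum$bmi_category, "")
  recs <- vapply(tabs, function(x) x$recommendation, "")
  ub <- unique(bands)
  um <- unique(bmis)
  m <- matrix(NA_character_, length(um), length(ub), dimnames = list(um, ub))
  for (i in seq_along(tabs)) m[bmis[i], bands[i]] <- recs[i]
  data.frame(bmi_category = um, m, check.names = FALSE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the base-case analysis over a configuration bundle
#'
#' For every stratum configuration: evaluates each strategy with the
#' microsimulation (per-strategy sub-seeds derived from the global seed) and
#' with the deterministic cohort expectation, builds the incremental CEA
#' table from the chosen engine's outcomes, and writes: a combined CEA table
#' CSV, a full-precision raw results CSV
#' (`stratum,strategy,n,seed,mean_cost,se_cost,mean_qaly,se_qaly,engine`),
#' the recommendation matrix CSV, and a run manifest.
#'
#' @param config_paths character vector of YAML configuration paths.
#' @param life_table_path life-table CSV path.
#' @param out_dir output directory (created if needed).
#' @param n individuals per strategy for the microsimulation (default: each
#'   config's `cohort_size`).
#' @param seed global seed (sub-seeds derived per stratum and strategy).
#' @param mode engine whose outcomes feed the CEA tables: `"microsim"`
#'   (default) or `"cohort"`.
#' @return invisibly, a list with the per-stratum `cea_table`s, the
#'   recommendation matrix, and the output paths.
#' @export
report_basecase <- function(config_paths, life_table_path, out_dir,
                            n = NULL, seed = 1L, mode = c("microsim", "cohort")) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lt <- read_life_table(life_table_path)
  tabs <- list()
  raw <- list()
  for (path in config_paths) {
    cfg <- load_config(path)
    n_i <- if (is.null(n)) cfg$settings$cohort_size else n
    stratum_id <- format(cfg$stratum)
    sseed <- derive_seed(seed, stratum_id)
    t0 <- proc.time()[["elapsed"]]
    for (engine in c("cohort", "microsim")) {
      res <- evaluate_strategies(cfg, lt, mode = engine, n = n_i, seed = sseed)
      res$engine <- engine
      res$stratum <- stratum_id
      res$seed <- if (engine == "microsim") sseed else NA_integer_
      raw[[length(raw) + 1L]] <- res
      if (engine == mode) {
        tabs[[length(tabs) + 1L]] <- build_cea_table(
          res, wtp = cfg$settings$wtp, stratum = cfg$stratum)
      }
    }
    message(sprintf("[basecase] %s: %.1fs (seed %d)", stratum_id,
                    proc.time()[["elapsed"]] - t0, sseed))
  }
  raw <- do.call(rbind, raw)
  raw <- raw[, c("stratum", "label", "n", "seed", "cost", "se_cost",
                 "qaly", "se_qaly", "engine")]
  names(raw) <- c("stratum", "strategy", "n", "seed", "mean_cost", "se_cost",
                  "mean_qaly", "se_qaly", "engine")
  utils::write.csv(raw, file.path(out_dir, "raw_results.csv"), row.names = FALSE)
  write_cea_csv(tabs, file.path(out_dir, "cea_table.csv"))
  rec <- recommendation_matrix(tabs)
  utils::write.csv(rec, file.path(out_dir, "recommendations.csv"), row.names = FALSE)
  write_manifest(out_dir, "basecase", config_paths, life_table_path, seed,
                 list(n = n, mode = mode), mode)
  invisible(list(tables = tabs, recommendations = rec, out_dir = out_dir))
}

#' Run the PSA over one configuration and write its outputs
#'
#' Writes the per-draw scatter CSV (`draw,strategy,cost,qaly`), the
#' acceptability CSV (`wtp,strategy,probability`), an incremental summary
#' JSON (highest-QALY base-case frontier strategy vs the cheapest), and a
#' run manifest.
#'
#' @param config_path YAML configuration path.
#' @param life_table_path life-table CSV path.
#' @param out_dir output directory.
#' @param n_draws parameter draws.
#' @param n_individuals individuals per strategy in microsim mode.
#' @param seed global seed.
#' @param wtp_grid WTP grid for the acceptability curve (default 0 to
#'   100,000 USD/QALY in 2,000 steps).
#' @param mode `"cohort"` (default) or `"microsim"`.
#' @return invisibly, a list with the `psa_result`, the
#'   `acceptability_curve`, and the output paths.
#' @export
report_psa <- function(config_path, life_table_path, out_dir,
                       n_draws = 1000L, n_individuals = 1000L, seed = 1L,
                       wtp_grid = seq(0, 100000, by = 2000),
                       mode = c("cohort", "microsim")) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- load_config(config_path)
  lt <- read_life_table(life_table_path)
  res <- run_psa(cfg, lt, n_draws = n_draws, n_individuals = n_individuals,
                 seed = seed, mode = mode)
  curve <- acceptability(res, wtp_grid)
  write_psa_csvs(res, curve,
                 scatter_path = file.path(out_dir, "psa_scatter.csv"),
                 curve_path = file.path(out_dir, "acceptability.csv"))
  base <- evaluate_strategies(cfg, lt, mode = "cohort")
  tab <- build_cea_table(base, wtp = cfg$settings$wtp, stratum = cfg$stratum)
  front <- tab$rows$label[tab$rows$status %in% c("frontier", "dominant")]
  smry <- psa_summary(res, comparator = front[1], target = front[length(front)])
  jsonlite::write_json(
    c(list(comparator = front[1], target = front[length(front)]), smry),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, "psa", config_path, life_table_path, seed,
                 list(n_draws = n_draws, n_individuals = n_individuals), mode)
  invisible(list(psa = res, curve = curve, summary = smry, out_dir = out_dir))
}
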