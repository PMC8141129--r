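# Probabilistic sensitivity analysis: draw parameter sets from their
# distributions, re-evaluate every strategy per draw, and summarize decision
# uncertainty (acceptability curves, incremental scatter, interval summaries).

# Effective PSA specs: printed distributions re-centered on their point
# estimates wherever check_psa_consistency flags them (gamma scale rescaled,
# etc.), so sampled parameters are centered on the base case.
effective_psa_specs <- function(cfg, rel_tol = 0.05) {
  specs <- cfg$psa
  fixes <- check_psa_consistency(cfg, rel_tol = rel_tol)$corrected
  specs[names(fixes)] <- fixes
  specs
}

#' Sample one PSA parameter set
#'
#' Draws every PSA parameter independently from its (consistency-corrected,
#' see [check_psa_consistency()]) distribution using the current R random
#' stream.  Draws outside a parameter's legal domain (probabilities outside
#' \[0, 1\], non-positive relative risks, negative costs) are rejected and
#' re-drawn.
#'
#' @param cfg a [model_config()] with a non-empty `psa` list.
#' @param rel_tol consistency tolerance passed to [check_psa_consistency()].
#' @param max_reject maximum consecutive rejections per parameter before a
#'   misspecification error is raised.
#' @return a named list: `values` (named numeric vector on the natural
#'   scale) and `rejections` (named integer vector of re-draw counts).
#' @export
sample_draw <- function(cfg, rel_tol = 0.05, max_reject = 1000L) {
  stopifnot(inherits(cfg, "model_config"))
  if (!length(cfg$psa)) {
    stop_hbs("configuration has no PSA distributions", class = "validation_error")
  }
  specs <- effective_psa_specs(cfg, rel_tol = rel_tol)
  ptab <- psa_parameter_table()
  values <- numeric(length(specs))
  rejections <- integer(length(specs))
  names(values) <- names(rejections) <- names(specs)
  for (nm in names(specs)) {
    row <- ptab[ptab$name == nm, ]
    ok <- function(v) {
      v >= row$lower && v <= row$upper && (!row$strict_lower || v > row$lower)
    }
    v <- sample_dist(specs[[nm]], 1L)
    r <- 0L
    while (!ok(v)) {
      r <- r + 1L
      if (r > max_reject) {
        stop_hbs("PSA distribution for '", nm, "' rejected ", max_reject,
                 " consecutive draws; distribution misspecified",
                 class = "distribution_misspecification_error")
      }
      v <- sample_dist(specs[[nm]], 1L)
    }
    values[nm] <- v
    rejections[nm] <- r
  }
  list(values = values, rejections = rejections)
}

#' Substitute sampled parameter values into a configuration
#'
#' @param cfg a [model_config()].
#' @param values named numeric vector as produced by [sample_draw()].
#' @return a `model_config` with the named scalar parameters replaced.
#' @export
apply_draw <- function(cfg, values) {
  ptab <- psa_parameter_table()
  for (nm in names(values)) {
    row <- ptab[ptab$name == nm, ]
    if (!nrow(row)) stop_hbs("unknown PSA parameter: ", nm, class = "lookup_error")
    cfg[[row$component]][[row$field]] <- unname(values[[nm]])
  }
  cfg
}

#' Run a probabilistic sensitivity analysis
#'
#' For each of `n_draws` parameter draws, substitutes the sampled values into
#' the configuration and evaluates every strategy, either with the
#' deterministic cohort expectation (default: removes first-order Monte Carlo
#' noise, leaving pure parameter uncertainty) or with the microsimulation at
#' `n_individuals` per strategy.  Fully reproducible from `seed`: per-draw
#' and per-strategy random streams are derived with [derive_seed()].
#'
#' @param cfg a [model_config()] with PSA distributions.
#' @param lt a `life_table`.
#' @param n_draws number of parameter draws (second-order samples).
#' @param n_individuals individuals per strategy in microsim mode.
#' @param seed global integer seed.
#' @param mode `"cohort"` or `"microsim"`.
#' @param rel_tol consistency tolerance for [check_psa_consistency()].
#' @return an object of class `psa_result`: list with `draws`, `results`
#'   (data frame `draw, strategy, cost, qaly`), `params` (data frame of
#'   sampled values, one row per draw), `seed`, `mode`.
#' @export
run_psa <- function(cfg, lt, n_draws = 1000L, n_individuals = 1000L,
                    seed = cfg$settings$seed, mode = c("cohort", "microsim"),
                    rel_tol = 0.05) {
  mode <- match.arg(mode)
  stopifnot(n_draws >= 1L, n_individuals >= 1L)
  strategies <- cfg$strategies
  res <- vector("list", n_draws)
  params <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(derive_seed(seed, "psa-draw", i))
    dr <- sample_draw(cfg, rel_tol = rel_tol)
    params[[i]] <- as.data.frame(as.list(dr$values))
    cfg_i <- apply_draw(cfg, dr$values)
    rows <- lapply(strategies, function(tc) {
      r <- if (mode == "cohort") {
        run_cohort_expectation(cfg_i, tc, lt)
      } else {
        run_microsim(cfg_i, tc, lt, n = n_individuals,
                     seed = derive_seed(seed, "psa-sim", i, tc$label))
      }
      data.frame(draw = i, strategy = r$strategy_label,
                 cost = r$mean_cost, qaly = r$mean_qaly, stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(
    list(draws = as.integer(n_draws), results = out,
         params = do.call(rbind, params), seed = as.integer(seed), mode = mode),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws x %d strategies (%s mode, seed %d)\n",
              x$draws, length(unique(x$results$strategy)), x$mode, x$seed))
  invisible(x)
}

psa_matrices <- function(res) {
  labs <- unique(res$results$strategy)
  cost <- matrix(NA_real_, res$draws, length(labs), dimnames = list(NULL, labs))
  qaly <- cost
  for (j in seq_along(labs)) {
    d <- res$results[res$results$strategy == labs[j], ]
    if (nrow(d) != res$draws) {
      stop_hbs("PSA result is not rectangular for strategy ", labs[j],
               class = "validation_error")
    }
    cost[d$draw, j] <- d$cost
    qaly[d$draw, j] <- d$qaly
  }
  list(cost = cost, qaly = qaly, labels = labs)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which each
#' strategy has the maximum net monetary benefit (exact ties split equally).
#'
#' @param res a `psa_result`.
#' @param wtp_grid sorted numeric vector of WTP values (USD/QALY).
#' @return an object of class `acceptability_curve`: list with `wtp_grid` and
#'   `probabilities` (matrix, rows = WTP values, columns = strategies; each
#'   row sums to 1).
#' @export
acceptability <- function(res, wtp_grid = seq(0, 100000, by = 2000)) {
  stopifnot(inherits(res, "psa_result"), length(wtp_grid) >= 1L,
            !is.unsorted(wtp_grid))
  m <- psa_matrices(res)
  probs <- matrix(0, length(wtp_grid), length(m$labels),
                  dimnames = list(NULL, m$labels))
  for (w in seq_along(wtp_grid)) {
    b <- wtp_grid[w] * m$qaly - m$cost
    best <- apply(b, 1L, max)
    win <- b == best
    probs[w, ] <- colSums(win / rowSums(win)) / res$draws
  }
  structure(list(wtp_grid = wtp_grid, probabilities = probs),
            class = "acceptability_curve")
}

#' @export
print.acceptability_curve <- function(x, ...) {
  cat(sprintf("<acceptability_curve> %d WTP points, strategies: %s\n",
              length(x$wtp_grid), paste(colnames(x$probabilities), collapse = ", ")))
  invisible(x)
}

#' @export
plot.acceptability_curve <- function(x, ...) {
  graphics::matplot(x$wtp_grid, x$probabilities, type = "l", lty = 1,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "P(cost-effective)", ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x$probabilities),
                   col = seq_len(ncol(x$probabilities)), lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  m <- psa_matrices(x)
  cols <- seq_along(m$labels)
  graphics::plot(as.vector(m$qaly), as.vector(m$cost),
                 col = rep(cols, each = x$draws), pch = 20,
                 xlab = "QALYs", ylab = "Cost (USD)", ...)
  graphics::legend("topleft", legend = m$labels, col = cols, pch = 20, bty = "n")
  invisible(x)
}

#' Summarize incremental PSA results between two strategies
#'
#' Per-draw deltas of `target` minus `comparator`, their means, the ICER of
#' the mean deltas (not the mean of per-draw ratios, which is unstable when
#' a delta-QALY crosses zero), and empirical 2.5/97.5 percentile intervals.
#'
#' @param res a `psa_result`.
#' @param comparator,target strategy labels present in `res`.
#' @param probs interval probabilities (default `c(0.025, 0.975)`).
#' @return list with `mean_delta_cost`, `mean_delta_qaly`, `icer`,
#'   `ci_delta_cost`, `ci_delta_qaly`, `n_draws`.
#' @export
psa_summary <- function(res, comparator, target, probs = c(0.025, 0.975)) {
  m <- psa_matrices(res)
  for (lab in c(comparator, target)) {
    if (!lab %in% m$labels) {
      stop_hbs("unknown strategy label: ", lab, class = "lookup_error")
    }
  }
  dc <- m$cost[, target] - m$cost[, comparator]
  dq <- m$qaly[, target] - m$qaly[, comparator]
  list(
    mean_delta_cost = mean(dc),
    mean_delta_qaly = mean(dq),
    icer = if (mean(dq) != 0) mean(dc) / mean(dq) else NA_real_,
    ci_delta_cost = stats::quantile(dc, probs, names = FALSE),
    ci_delta_qaly = stats::quantile(dq, probs, names = FALSE),
    n_draws = res$draws
  )
}

#' Export PSA scatter and acceptability CSVs
#'
#' @param res a `psa_result`.
#' @param curve an `acceptability_curve`.
#' @param scatter_path,curve_path output CSV paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
write_psa_csvs <- function(res, curve = NULL, scatter_path = NULL, curve_path = NULL) {
  written <- character()
  if (!is.null(scatter_path)) {
    utils::write.csv(res$results, scatter_path, row.names = FALSE)
    written <- c(written, scatter_path)
  }
  if (!is.null(curve_path)) {
    stopifnot(inherits(curve, "acceptability_curve"))
    long <- data.frame(
      wtp = rep(curve$wtp_grid, ncol(curve$probabilities)),
      strategy = rep(colnames(curve$probabilities), each = length(curve$wtp_grid)),
      probability = as.vector(curve$probabilities), stringsAsFactors = FALSE
    )
    utils::write.csv(long, curve_path, row.names = FALSE)
    written <- c(written, curve_path)
  }
  invisible(written)
}
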