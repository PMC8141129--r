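# Construct a psa_result by hand for the summarization oracles.
fake_psa <- function(draws, labels, seed = 1) {
  set.seed(seed)
  res <- expand.grid(draw = seq_len(draws), strategy = labels,
                     stringsAsFactors = FALSE)
  res$cost <- runif(nrow(res), 0, 5000)
  res$qaly <- runif(nrow(res), 5, 30)
  structure(list(draws = as.integer(draws), results = res,
                 params = NULL, seed = 1L, mode = "cohort"),
            class = "psa_result")
}

test_that("sample moments match analytic values for every family", {
  n <- 1e5
  set.seed(13)

  g <- dist_spec("gamma", 6, shape = 2, scale = 3)
  x <- sample_dist(g, n)
  se <- sqrt(2 * 3^2 / n)  # var = shape * scale^2
  expect_lt(abs(mean(x) - 6), 3 * se)

  b <- dist_spec("beta", 0.014, alpha = 2.27, beta = 160.3)
  x <- sample_dist(b, n)
  m <- 2.27 / 162.57
  se <- sqrt(m * (1 - m) / (162.57 + 1) / n)
  expect_lt(abs(mean(x) - m), 3 * se)

  ln <- dist_spec("lognormal", 0.79, log_mean = -0.23, log_sd = 0.09)
  x <- sample_dist(ln, n)
  # median via the log-scale mean: log(X) ~ N(-0.23, 0.09^2)
  expect_lt(abs(median(x) - exp(-0.23)), 3 * exp(-0.23) * 0.09 * sqrt(pi / (2 * n)))
  mu <- exp(-0.23 + 0.09^2 / 2)
  sdv <- sqrt((exp(0.09^2) - 1) * exp(2 * -0.23 + 0.09^2))
  expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(n))

  expect_identical(sample_dist(dist_spec("fixed", 7), 5), rep(7, 5))
})

test_that("sample_draw centers on point estimates and respects domains", {
  cfg <- preset_config(stratum_key(60, 74, "obese"), annual_incidence = 0.02)

  set.seed(17)
  n <- 2000
  draws <- replicate(n, sample_draw(cfg)$values)
  # gamma costs are re-centered on the point estimates before sampling
  se_scr <- 100 / sqrt(27.3) / sqrt(n)
  expect_lt(abs(mean(draws["screening_cost", ]) - 100), 4 * se_scr)
  expect_lt(abs(mean(draws["tx_comp_annual", ]) - 8000),
            4 * 8000 / sqrt(26540) / sqrt(n))
  # probabilities stay in [0, 1], relative risks positive
  expect_true(all(draws["annual_comp_rate", ] >= 0 &
                    draws["annual_comp_rate", ] <= 1))
  expect_true(all(draws["rr_mort_comp", ] > 0))

  # degenerate: all-fixed specs reproduce the point estimates exactly
  cfg_fix <- cfg
  cfg_fix$psa <- lapply(cfg$psa, function(d) dist_spec("fixed", d$point_estimate))
  expect_identical(unname(sample_draw(cfg_fix)$values),
                   vapply(cfg$psa, `[[`, 0, "point_estimate", USE.NAMES = FALSE))

  # an impossible domain raises a misspecification error
  cfg_bad <- cfg
  cfg_bad$psa <- list(annual_comp_rate = dist_spec("gamma", 100, shape = 100,
                                                   scale = 1))
  expect_error(sample_draw(cfg_bad),
               class = "distribution_misspecification_error")
})

test_that("apply_draw substitutes sampled values into the right fields", {
  cfg <- preset_config(stratum_key(60, 74, "obese"), annual_incidence = 0.02)
  cfg2 <- apply_draw(cfg, c(screening_cost = 55, rr_mort_comp = 4.4,
                            annual_comp_rate = 0.02))
  expect_identical(cfg2$costs$screening_cost, 55)
  expect_identical(cfg2$risks$rr_mort_comp, 4.4)
  expect_identical(cfg2$risks$annual_comp_rate, 0.02)
  expect_error(apply_draw(cfg, c(bogus = 1)), class = "lookup_error")
})

test_that("run_psa is reproducible and degenerates correctly under fixed specs", {
  cfg <- toy_config(entry_age = 60L, max_age = 72L)
  cfg$psa <- list(screening_cost = dist_spec("fixed", 100),
                  annual_comp_rate = dist_spec("fixed", 0.05))
  lt <- flat_life_table(0.02, max_age = 72)

  res <- run_psa(cfg, lt, n_draws = 3, seed = 5, mode = "cohort")
  base <- evaluate_strategies(cfg, lt, mode = "cohort")
  for (i in 1:3) {
    d <- res$results[res$results$draw == i, ]
    expect_equal(d$cost, base$cost, tolerance = 1e-12)
    expect_equal(d$qaly, base$qaly, tolerance = 1e-12)
  }

  a <- run_psa(cfg, lt, n_draws = 2, n_individuals = 200, seed = 5,
               mode = "microsim")
  b <- run_psa(cfg, lt, n_draws = 2, n_individuals = 200, seed = 5,
               mode = "microsim")
  expect_identical(a, b)
})

test_that("acceptability probabilities are exact win fractions summing to one", {
  res <- fake_psa(50, c("annual", "3-year", "6-year"), seed = 23)
  grid <- seq(0, 100000, by = 10000)
  curve <- acceptability(res, grid)
  expect_true(all(abs(rowSums(curve$probabilities) - 1) < 1e-9))

  # brute-force per-draw argmax tally
  for (w in seq_along(grid)) {
    tally <- setNames(numeric(3), colnames(curve$probabilities))
    for (i in 1:50) {
      d <- res$results[res$results$draw == i, ]
      bnf <- grid[w] * d$qaly - d$cost
      win <- d$strategy[which(bnf == max(bnf))]
      tally[win] <- tally[win] + 1 / length(win)
    }
    expect_equal(curve$probabilities[w, ], tally / 50, tolerance = 1e-12)
  }

  # single strategy: probability one everywhere
  one <- fake_psa(10, "only")
  c1 <- acceptability(one, grid)
  expect_true(all(c1$probabilities == 1))
})

test_that("fixed distributions give a degenerate acceptability curve", {
  cfg <- toy_config(entry_age = 60L, max_age = 72L)
  cfg$psa <- list(screening_cost = dist_spec("fixed", 100))
  lt <- flat_life_table(0.02, max_age = 72)
  res <- run_psa(cfg, lt, n_draws = 4, seed = 3, mode = "cohort")
  grid <- c(0, 25000, 50000, 100000)
  curve <- acceptability(res, grid)
  base <- evaluate_strategies(cfg, lt, mode = "cohort")
  for (w in seq_along(grid)) {
    winner <- base$label[which.max(grid[w] * base$qaly - base$cost)]
    expect_identical(unname(curve$probabilities[w, winner]), 1)
  }
})

test_that("psa_summary matches sorting-based percentile and delta oracles", {
  res <- fake_psa(40, c("annual", "3-year"), seed = 29)
  s <- psa_summary(res, comparator = "annual", target = "3-year")
  a <- res$results[res$results$strategy == "annual", ]
  b <- res$results[res$results$strategy == "3-year", ]
  dc <- b$cost[order(b$draw)] - a$cost[order(a$draw)]
  dq <- b$qaly[order(b$draw)] - a$qaly[order(a$draw)]
  expect_equal(s$mean_delta_cost, mean(dc), tolerance = 1e-12)
  expect_equal(s$icer, mean(dc) / mean(dq), tolerance = 1e-12)
  expect_equal(s$ci_delta_cost, quantile(dc, c(0.025, 0.975), names = FALSE),
               tolerance = 1e-12)
  expect_equal(s$ci_delta_qaly, quantile(dq, c(0.025, 0.975), names = FALSE),
               tolerance = 1e-12)

  s0 <- psa_summary(res, comparator = "annual", target = "annual")
  expect_identical(s0$mean_delta_cost, 0)
  expect_true(is.na(s0$icer))
  expect_error(psa_summary(res, "annual", "nope"), class = "lookup_error")
})
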