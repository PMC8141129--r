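test_that("published incremental analyses reproduce from their outcome pairs", {
  # obese 30-44: 2-year dominated; 3-year vs annual increments
  tab <- build_cea_table(stratum_outcomes(30, "obese"), wtp = 50000)
  rows <- tab$rows
  expect_identical(rows$status[rows$label == "2-year"], "dominated")
  i3 <- which(rows$label == "3-year")
  expect_identical(rows$comparator[i3], "annual")
  expect_equal(rows$delta_cost[i3], 4635.07, tolerance = 1e-9)
  expect_equal(rows$delta_qaly[i3], 0.31, tolerance = 1e-9)

  # overweight 30-44: 4-year weakly dominates everything
  tab <- build_cea_table(stratum_outcomes(30, "overweight"), wtp = 50000)
  expect_identical(tab$rows$status[tab$rows$label == "4-year"], "dominant")
  expect_setequal(tab$rows$status[tab$rows$label != "4-year"],
                  c("dominated", "dominated"))

  # obese 45-59: 4-year extended-dominated, 3-year vs annual increment
  tab <- build_cea_table(stratum_outcomes(45, "obese"), wtp = 50000)
  expect_identical(tab$rows$status[tab$rows$label == "4-year"],
                   "extended_dominated")
  expect_equal(tab$rows$delta_cost[tab$rows$label == "3-year"], 4623.57,
               tolerance = 1e-9)

  # overweight 60-74: full three-point frontier with increasing ICERs
  tab <- build_cea_table(stratum_outcomes(60, "overweight"), wtp = 50000)
  rows <- tab$rows
  expect_true(all(rows$status == "frontier"))
  expect_equal(rows$delta_cost[rows$label == "5-year"], 72.36, tolerance = 1e-9)
  expect_equal(rows$delta_qaly[rows$label == "5-year"], 0.07, tolerance = 1e-9)
  expect_equal(rows$delta_cost[rows$label == "3-year"], 275.64, tolerance = 1e-9)
  icers <- rows$icer[!is.na(rows$icer)]
  expect_true(all(diff(icers) > 0))
})

test_that("published recommendations reproduce for the self-consistent strata", {
  # two strata are excluded: their printed 2-decimal outcomes round a
  # decision-relevant QALY difference the wrong way, so no method can recover
  # the published entry from them (normal 30-44) or the published tables
  # contradict each other outright (overweight 45-59)
  inconsistent <- list(c(30L, "normal"), c(45L, "overweight"))
  ref <- reference_recommendations()
  n_checked <- 0L
  for (i in seq_len(nrow(ref))) {
    if (any(vapply(inconsistent, function(x)
      x[1] == ref$age_low[i] && x[2] == ref$bmi_category[i], logical(1)))) next
    o <- stratum_outcomes(ref$age_low[i], ref$bmi_category[i])
    expect_identical(recommend(o, 50000), ref$label[i])
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 10L)
})

test_that("interior points above the frontier segment are extended-dominated", {
  o <- data.frame(label = c("A", "B", "C", "D"),
                  cost = c(0, 10, 11, 9), qaly = c(0, 1, 1.05, 0.2))
  tab <- build_cea_table(o, wtp = 50000)
  expect_identical(tab$rows$status[tab$rows$label == "D"], "extended_dominated")
  expect_true(all(tab$rows$status[tab$rows$label != "D"] %in%
                    c("frontier", "dominant")))
  expect_true(is.na(tab$rows$icer[tab$rows$label == "D"]))
})

test_that("the frontier equals the convex-hull oracle on random instances", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    o <- data.frame(label = LETTERS[1:n],
                    cost = round(runif(n, 0, 100), 4),
                    qaly = round(runif(n, 0, 10), 4))
    tab <- build_cea_table(o, wtp = 50000)
    got <- sort(tab$rows$label[tab$rows$status %in% c("frontier", "dominant")])
    expect_identical(got, oracle_frontier(o))
    # frontier ICERs strictly increase
    icers <- tab$rows$icer[order(tab$rows$cost)]
    icers <- icers[!is.na(icers)]
    expect_true(all(diff(icers) > 0))
  }
})

test_that("recommendation equals argmax net monetary benefit without ties", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    o <- data.frame(label = LETTERS[1:n],
                    cost = runif(n, 0, 5000), qaly = runif(n, 0, 30))
    expect_identical(recommend(o, 50000), oracle_recommend(o, 50000))
  }
  # worked NMB example from the published obese 60-74 outcome pair
  expect_equal(nmb(strategy_outcome("3-year", 3552.88, 15.23), 50000),
               757947.12, tolerance = 1e-9)
  expect_identical(nmb(strategy_outcome("x", 0, 0), 50000), 0)
  # at WTP 0 the cheapest strategy wins
  o <- data.frame(label = c("cheap", "rich"), cost = c(10, 20), qaly = c(1, 5))
  expect_identical(recommend(o, 1e-9), "cheap")
})

test_that("dominated strategies never perturb the analysis", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    o <- data.frame(label = LETTERS[1:n],
                    cost = runif(n, 0, 100), qaly = runif(n, 0, 10))
    tab <- build_cea_table(o, wtp = 40000)
    # add a strategy strictly dominated by the first frontier point
    f <- tab$rows[tab$rows$status %in% c("frontier", "dominant"), ][1, ]
    o2 <- rbind(o, data.frame(label = "Z", cost = f$cost + 1,
                              qaly = max(f$qaly - 0.1, 0)))
    tab2 <- build_cea_table(o2, wtp = 40000)
    expect_identical(tab2$recommendation, tab$recommendation)
    keep <- tab2$rows$label != "Z"
    expect_equal(tab2$rows[keep, c("label", "delta_cost", "delta_qaly", "icer")],
                 tab$rows[, c("label", "delta_cost", "delta_qaly", "icer")],
                 ignore_attr = TRUE)
  }
})

test_that("recommended QALY is monotone in willingness to pay", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    o <- data.frame(label = LETTERS[1:n],
                    cost = runif(n, 0, 100), qaly = runif(n, 0, 10))
    qalys <- vapply(c(0, 1, 5, 20, 100, 1e4), function(w) {
      o$qaly[o$label == recommend(o, w)]
    }, 0)
    expect_true(all(diff(qalys) >= 0))
  }
})

test_that("ICERs scale with costs; dominance statuses do not", {
  set.seed(95)
  o <- data.frame(label = LETTERS[1:5],
                  cost = runif(5, 0, 100), qaly = runif(5, 0, 10))
  t1 <- build_cea_table(o, wtp = 1e6)
  o2 <- o
  o2$cost <- o2$cost * 7
  t2 <- build_cea_table(o2, wtp = 7e6)
  expect_identical(t2$rows$status, t1$rows$status)
  expect_equal(t2$rows$icer, 7 * t1$rows$icer, tolerance = 1e-9)
})

test_that("exact ties and duplicate labels follow the documented rules", {
  o <- data.frame(label = c("A", "B", "C"),
                  cost = c(5, 5, 10), qaly = c(1, 1, 0.5))
  tab <- build_cea_table(o, wtp = 50000)
  expect_setequal(tab$rows$status[tab$rows$label %in% c("A", "B")],
                  c("dominant", "dominant"))
  expect_identical(tab$rows$status[tab$rows$label == "C"], "dominated")
  expect_true(all(is.na(tab$rows$icer)))

  expect_error(build_cea_table(
    data.frame(label = c("A", "A"), cost = c(1, 2), qaly = c(1, 2)), 50000),
    class = "validation_error")
  expect_error(build_cea_table(o[1, ], 50000), class = "validation_error")
})
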