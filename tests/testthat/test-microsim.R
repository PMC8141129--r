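test_that("discounting follows (1+d)^-t", {
  expect_identical(discount_factor(0, 0.02), 1)
  expect_equal(discount_factor(1, 0.02), 1 / 1.02, tolerance = 1e-15)
  # 55-year discounted annuity, geometric-series closed form
  expect_equal(sum(discount_factor(0:54, 0.02)),
               (1 - 1.02^-55) / (1 - 1.02^-1), tolerance = 1e-12)
  # multiplicative over cycle splits
  expect_equal(discount_factor(7, 0.03),
               discount_factor(3, 0.03) * discount_factor(4, 0.03),
               tolerance = 1e-15)
})

test_that("accrual maps states to the configured costs and utilities", {
  cfg <- preset_config(stratum_key(60, 74, "obese"), annual_incidence = 0.02)
  expect_equal(accrue("DEAD", cfg), list(cost = 0, utility = 0))
  expect_equal(accrue("COMPLICATION", cfg), list(cost = 8000, utility = 0.638))
  expect_equal(accrue("FALSE_POSITIVE", cfg), list(cost = 1400, utility = 1))
  expect_equal(accrue("UNDETECTED_T2DM", cfg), list(cost = 0, utility = 0.785))
  expect_equal(accrue("TREATED_T2DM", cfg), list(cost = 3500, utility = 0.785))
})

test_that("screening_event honors sensitivity/specificity and its contract", {
  perfect <- test_characteristics("t", 1, 1, 1)
  set.seed(1)
  expect_identical(screening_event("UNDETECTED_T2DM", perfect), "TREATED_T2DM")
  expect_identical(screening_event("HEALTHY", perfect), "HEALTHY")
  expect_identical(screening_event("FALSE_POSITIVE", perfect), "HEALTHY")
  expect_error(screening_event("TREATED_T2DM", perfect),
               class = "contract_violation")

  # binomial oracle: healthy flagged positive at rate 1 - specificity
  tc <- test_characteristics("3-year", 3, 0.523, 0.991)
  set.seed(33)
  n <- 1e5
  flags <- vapply(seq_len(n),
                  function(i) screening_event("HEALTHY", tc) == "FALSE_POSITIVE",
                  logical(1))
  se <- sqrt(0.009 * 0.991 / n)
  expect_lt(abs(mean(flags) - 0.009), 3 * se)
})

test_that("annual_transition draws incidence, complication, and death in order", {
  lt0 <- flat_life_table(0, max_age = 90)
  risks0 <- risk_set(0, 0, 1, 5.22, 2.61, 1)
  set.seed(2)
  for (st in setdiff(health_states(), "DEAD")) {
    out <- annual_transition(st, risks0, lt0, 50)
    expect_identical(out$state, st)
    expect_identical(out$age, 51L)
  }
  expect_error(annual_transition("DEAD", risks0, lt0, 50),
               class = "contract_violation")

  # binomial oracle: untreated complication rate 0.014
  risks <- risk_set(0.01, 0.014, 0.79, 5.22, 2.61, 1)
  set.seed(5)
  n <- 1e5
  comp <- vapply(seq_len(n), function(i) {
    annual_transition("UNDETECTED_T2DM", risks, lt0, 50)$state == "COMPLICATION"
  }, logical(1))
  se <- sqrt(0.014 * 0.986 / n)
  expect_lt(abs(mean(comp) - 0.014), 3 * se)

  # closed form + binomial oracle: death with complication at rr 5.22
  lt01 <- flat_life_table(0.01, max_age = 90)
  p_expected <- 1 - 0.99^5.22
  set.seed(6)
  dead <- vapply(seq_len(n), function(i) {
    annual_transition("COMPLICATION", risks, lt01, 50)$state == "DEAD"
  }, logical(1))
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(dead) - p_expected), 3 * se)
})

test_that("risk-free undiscounted lifetimes give exact annuity QALYs and screen counts", {
  # incidence 0, qx 0 until the horizon, utility 1, discount 0
  cfg <- toy_config(incidence = 0, comp_rate = 0, discount = 0,
                    intervals = c(1L, 3L), sens = c(0, 0), spec = c(1, 1),
                    entry_age = 60L, max_age = 80L)
  lt <- flat_life_table(0, max_age = 80)
  for (k in 1:2) {
    r <- run_microsim(cfg, cfg$strategies[[k]], lt, n = 50, seed = 1)
    expect_equal(r$mean_qaly, 20)
    expect_equal(r$se_qaly, 0)
    n_screens <- length(seq(0, 19, by = cfg$strategies[[k]]$interval_years))
    expect_equal(r$mean_cost, 100 * n_screens)
  }
  # scalar reference engine agrees exactly on the deterministic case
  set.seed(1)
  ind <- simulate_individual(cfg, cfg$strategies[[2]], lt, 60)
  expect_equal(ind$discounted_qaly, 20)
  expect_equal(ind$discounted_cost, 100 * 7)
})

test_that("immediate death accrues only the first screen", {
  cfg <- toy_config(entry_age = 60L, max_age = 80L)
  lt <- flat_life_table(c(rep(0, 60), 1), max_age = 80) # qx = 1 from age 60
  r <- run_microsim(cfg, cfg$strategies[[1]], lt, n = 30, seed = 3)
  expect_equal(r$mean_qaly, 0)
  expect_equal(r$mean_cost, 100)
})

test_that("perfect specificity forbids false positives; zero sensitivity forbids treatment", {
  lt <- flat_life_table(0.01, max_age = 80)
  # a prohibitive false-positive fee leaves expected cost untouched when
  # specificity is 1, proving the false-positive state is never occupied
  cfg <- toy_config(sens = c(1, 1), spec = c(1, 1), intervals = c(1L, 2L),
                    incidence = 0.2, comp_rate = 0.02, fp_cost = 1e9)
  r <- run_cohort_expectation(cfg, cfg$strategies[[1]], lt)
  expect_lt(r$mean_cost, 1e6)
  # zero sensitivity: nobody is treated before a complication occurs, so a
  # prohibitive uncomplicated-treatment fee never accrues
  cfg0 <- toy_config(sens = c(0, 0), spec = c(0.98, 0.98), intervals = c(1L, 2L),
                     incidence = 0.2, comp_rate = 0.05, tx_no_comp = 1e9)
  r0 <- run_cohort_expectation(cfg0, cfg0$strategies[[1]], lt)
  expect_lt(r0$mean_cost, 1e6)
  sim <- run_microsim(cfg0, cfg0$strategies[[1]], lt, n = 500, seed = 11)
  expect_lt(sim$mean_cost, 1e6)
})

test_that("microsimulation is seed-deterministic and seed-robust", {
  cfg <- random_toy_config(7)
  lt <- make_gompertz_lifetable(max_age = cfg$settings$max_age)
  a <- run_microsim(cfg, cfg$strategies[[2]], lt, n = 4000, seed = 42)
  b <- run_microsim(cfg, cfg$strategies[[2]], lt, n = 4000, seed = 42)
  expect_identical(a, b)
  c_ <- run_microsim(cfg, cfg$strategies[[2]], lt, n = 4000, seed = 43)
  expect_lt(abs(a$mean_qaly - c_$mean_qaly),
            6 * sqrt(a$se_qaly^2 + c_$se_qaly^2))
  expect_lt(abs(a$mean_cost - c_$mean_cost),
            6 * sqrt(a$se_cost^2 + c_$se_cost^2))
})

test_that("a two-cycle model matches exhaustive path enumeration", {
  cfg <- toy_config(incidence = 0.3, comp_rate = 0.2, sens = c(0.7, 0.7),
                    spec = c(0.9, 0.9), intervals = c(1L, 2L),
                    discount = 0.02, entry_age = 60L, max_age = 62L)
  lt <- flat_life_table(0.05, max_age = 62)
  for (k in 1:2) {
    expected <- oracle_expectation(cfg, cfg$strategies[[k]], lt, 60)
    got <- run_cohort_expectation(cfg, cfg$strategies[[k]], lt)
    expect_equal(got$mean_cost, expected$cost, tolerance = 1e-12)
    expect_equal(got$mean_qaly, expected$qaly, tolerance = 1e-12)
  }
})

test_that("longer horizons still match path enumeration", {
  cfg <- toy_config(incidence = 0.15, comp_rate = 0.1, sens = c(0.6, 0.8),
                    spec = c(0.95, 0.9), intervals = c(1L, 2L),
                    discount = 0.03, entry_age = 60L, max_age = 65L)
  lt <- flat_life_table(c(rep(0.02, 61), 0.04, 0.06, 0.08, 0.1), max_age = 65)
  expected <- oracle_expectation(cfg, cfg$strategies[[2]], lt, 60)
  got <- run_cohort_expectation(cfg, cfg$strategies[[2]], lt)
  expect_equal(got$mean_cost, expected$cost, tolerance = 1e-10)
  expect_equal(got$mean_qaly, expected$qaly, tolerance = 1e-10)
})
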