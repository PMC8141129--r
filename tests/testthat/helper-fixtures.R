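# Shared fixtures and independent oracles.  Everything here is built in code
# at test time; the oracles deliberately avoid the production code paths they
# check.

# Life table with constant (or per-age) qx up to max_age; terminal qx = 1.
flat_life_table <- function(qx, max_age = 80L, min_age = 0L) {
  ages <- min_age:max_age
  q <- rep_len(qx, length(ages))
  q[length(q)] <- 1
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age = ages, qx = q), path, row.names = FALSE)
  suppressMessages(read_life_table(path))
}

# Small, fast configuration with a short horizon and fixed entry age.
toy_config <- function(incidence = 0.05, comp_rate = 0.05,
                       sens = c(0, 0.6), spec = c(1, 0.98),
                       intervals = c(1L, 3L),
                       screening_cost = 100, tx_no_comp = 3500, tx_comp = 8000,
                       fp_cost = 1400, discount = 0.02,
                       rr_comp_treated = 0.79, rr_mort_comp = 5.22,
                       rr_mort_untreated = 2.61, rr_mort_treated = 1,
                       entry_age = 60L, age_low = 60L, age_high = 62L,
                       max_age = 80L, seed = 1L) {
  strategies <- lapply(seq_along(intervals), function(i) {
    lab <- if (intervals[i] == 1L) "annual" else paste0(intervals[i], "-year")
    test_characteristics(lab, intervals[i], sens[i], spec[i])
  })
  model_config(
    stratum = stratum_key(age_low, age_high, "overweight"),
    strategies = strategies,
    costs = cost_set(screening_cost, tx_no_comp, tx_comp, fp_cost),
    utilities = utility_set(1, 0.785, 0.638),
    risks = risk_set(incidence, comp_rate, rr_comp_treated, rr_mort_comp,
                     rr_mort_untreated, rr_mort_treated),
    settings = econ_settings(discount_rate = discount, wtp = 50000,
                             cohort_size = 1000, max_age = max_age,
                             seed = seed, entry_age = entry_age)
  )
}

# Randomized small configuration for property checks.
random_toy_config <- function(seed) {
  set.seed(seed)
  toy_config(
    incidence = runif(1, 0.01, 0.1),
    comp_rate = runif(1, 0.005, 0.05),
    sens = sort(runif(2, 0.2, 0.9)),
    spec = sort(runif(2, 0.95, 1), decreasing = TRUE),
    intervals = sort(sample(1:5, 2)),
    discount = runif(1, 0, 0.04),
    entry_age = 60L, max_age = sample(75:85, 1), seed = seed
  )
}

# Table-3-style reference outcomes for one stratum as a data frame.
stratum_outcomes <- function(age_low, bmi) {
  ref <- reference_outcomes()
  ref[ref$age_low == age_low & ref$bmi_category == bmi,
      c("label", "cost", "qaly")]
}

# --- independent CEA oracles -------------------------------------------------

# Frontier oracle: a strategy is on the cost-effectiveness frontier iff it is
# the unique maximizer of qaly*lambda - cost for some lambda >= 0 (candidate
# lambdas: all pairwise slopes, plus 0 and a huge value).  Valid for
# instances without collinear or duplicated points.
oracle_frontier <- function(o) {
  slopes <- numeric()
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(nrow(o))) {
      dq <- o$qaly[i] - o$qaly[j]
      if (dq != 0) {
        l <- (o$cost[i] - o$cost[j]) / dq
        if (is.finite(l) && l >= 0) slopes <- c(slopes, l)
      }
    }
  }
  ls <- sort(unique(c(0, slopes)))
  # interior of every linear segment of lambda, plus beyond the largest slope:
  # there the argmax of lambda*qaly - cost is a unique frontier vertex
  test_l <- c((ls[-length(ls)] + ls[-1]) / 2, max(ls) * 2 + 1)
  on_frontier <- rep(FALSE, nrow(o))
  for (l in test_l) {
    b <- l * o$qaly - o$cost
    mx <- which(b == max(b))
    if (length(mx) == 1L) on_frontier[mx] <- TRUE
  }
  sort(o$label[on_frontier])
}

# NMB recommendation oracle: plain argmax of wtp*qaly - cost.
oracle_recommend <- function(o, wtp) {
  b <- wtp * o$qaly - o$cost
  o$label[which.max(b)]
}

# Exhaustive path-enumeration oracle for the expected discounted cost/QALY of
# one individual: recursively branches every Bernoulli event with the same
# event order as the engine, but coded independently (no matrices).
oracle_expectation <- function(cfg, strategy, lt, entry_age) {
  d <- cfg$settings$discount_rate
  max_age <- cfg$settings$max_age
  cost_of <- c(0, cfg$costs$fp_annual, 0, cfg$costs$tx_no_comp_annual,
               cfg$costs$tx_comp_annual, 0)
  util_of <- c(cfg$utilities$healthy, cfg$utilities$healthy,
               cfg$utilities$t2dm_no_comp, cfg$utilities$t2dm_no_comp,
               cfg$utilities$t2dm_comp, 0)
  rr_of <- c(1, 1, cfg$risks$rr_mort_untreated, cfg$risks$rr_mort_treated,
             cfg$risks$rr_mort_comp, NA)
  comp_treated <- 1 - (1 - cfg$risks$annual_comp_rate)^cfg$risks$rr_comp_treated

  total <- c(cost = 0, qaly = 0)
  recurse <- function(state, age, t, prob) {
    if (state == 6L || age >= max_age || prob == 0) return(invisible())
    df <- (1 + d)^(-t)
    branches <- list(list(state = state, p = 1, scr = 0))
    if (t %% strategy$interval_years == 0L && state <= 3L) {
      branches <- if (state == 3L) {
        list(list(state = 4L, p = strategy$sensitivity, scr = 1),
             list(state = 3L, p = 1 - strategy$sensitivity, scr = 1))
      } else {
        list(list(state = 2L, p = 1 - strategy$specificity, scr = 1),
             list(state = 1L, p = strategy$specificity, scr = 1))
      }
    }
    for (br in branches) {
      p0 <- prob * br$p
      if (br$scr) total["cost"] <<- total["cost"] +
          p0 * cfg$costs$screening_cost * df
      # incidence branch
      inc_branches <- if (br$state <= 2L) {
        list(list(state = 3L, p = cfg$risks$annual_incidence),
             list(state = br$state, p = 1 - cfg$risks$annual_incidence))
      } else list(list(state = br$state, p = 1))
      for (ib in inc_branches) {
        p1 <- p0 * ib$p
        comp_branches <- if (ib$state == 3L) {
          list(list(state = 5L, p = cfg$risks$annual_comp_rate),
               list(state = 3L, p = 1 - cfg$risks$annual_comp_rate))
        } else if (ib$state == 4L) {
          list(list(state = 5L, p = comp_treated),
               list(state = 4L, p = 1 - comp_treated))
        } else list(list(state = ib$state, p = 1))
        for (cb in comp_branches) {
          p2 <- p1 * cb$p
          qx <- lt$qx[lt$age == age]
          pdie <- 1 - (1 - qx)^rr_of[cb$state]
          for (db in list(list(state = 6L, p = pdie),
                          list(state = cb$state, p = 1 - pdie))) {
            p3 <- p2 * db$p
            if (p3 == 0) next
            total["cost"] <<- total["cost"] + p3 * cost_of[db$state] * df
            total["qaly"] <<- total["qaly"] + p3 * util_of[db$state] * df
            recurse(db$state, age + 1L, t + 1L, p3)
          }
        }
      }
    }
  }
  recurse(1L, as.integer(entry_age), 0L, 1)
  as.list(total)
}
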