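# First-order Monte Carlo engine: individuals move through annual cycles of
# screening, diabetes incidence, complication, and death, accruing discounted
# costs and QALYs.
#
# Health states (integer codes used internally):
#   1 HEALTHY          no diabetes, last screen negative
#   2 FALSE_POSITIVE   no diabetes, last screen positive (follow-up fees)
#   3 UNDETECTED_T2DM  diabetes, not detected (false negative / pre-screen)
#   4 TREATED_T2DM     diabetes, detected and treated, no complication
#   5 COMPLICATION     diabetes with complication (absorbing among the living)
#   6 DEAD             absorbing
#
# Cycle order (t = 0, 1, 2, ...): screening (on screening cycles, states 1-3
# only) -> incidence -> complication -> death -> accrual of the
# post-transition state's cost and utility, discounted by (1+d)^-t.  No
# half-cycle correction.

#' Health-state labels
#'
#' @return character vector of the six state names in internal code order.
#' @export
health_states <- function() {
  c("HEALTHY", "FALSE_POSITIVE", "UNDETECTED_T2DM",
    "TREATED_T2DM", "COMPLICATION", "DEAD")
}

state_code <- function(state) {
  i <- match(state, health_states())
  if (any(is.na(i))) {
    stop_hbs("unknown health state: ", paste(state[is.na(i)], collapse = ", "),
             class = "domain_error")
  }
  i
}

#' Discount factor for a cycle
#'
#' @param t cycle index (0 = first cycle).
#' @param d annual discount rate.
#' @return `(1 + d)^(-t)`.
#' @export
discount_factor <- function(t, d) {
  stopifnot(all(t >= 0), d >= 0)
  (1 + d)^(-t)
}

# Per-state annual cost and utility vectors in state-code order.
state_cost_vector <- function(cfg) {
  c(0, cfg$costs$fp_annual, 0, cfg$costs$tx_no_comp_annual,
    cfg$costs$tx_comp_annual, 0)
}

state_utility_vector <- function(cfg) {
  u <- cfg$utilities
  c(u$healthy, u$healthy, u$t2dm_no_comp, u$t2dm_no_comp, u$t2dm_comp, 0)
}

# Per-state mortality relative risks in state-code order (DEAD unused).
state_mort_rr <- function(risks) {
  c(1, 1, risks$rr_mort_untreated, risks$rr_mort_treated, risks$rr_mort_comp, NA)
}

#' Annual cost and utility accrued in a health state
#'
#' False positives accrue the follow-up fee at full-health utility; undetected
#' diabetes accrues no treatment cost but the diseased utility; a complication
#' implies diagnosis, so it accrues the treated-complication fee regardless of
#' prior detection; the dead accrue nothing.
#'
#' @param state a state name from [health_states()].
#' @param cfg a [model_config()].
#' @return list with `cost` (USD/year) and `utility`.
#' @export
accrue <- function(state, cfg) {
  i <- state_code(state)
  list(cost = state_cost_vector(cfg)[i], utility = state_utility_vector(cfg)[i])
}

#' Apply one screening test to an individual
#'
#' Uses the current R random stream.  Undetected diabetes is detected (and
#' treated) with probability `sensitivity`; a healthy individual is flagged
#' false positive with probability `1 - specificity`; an existing false
#' positive is re-classified as if healthy, reverting on a true-negative
#' result.  Treated, complicated, and dead individuals are outside the
#' screening schedule and may not be passed here.
#'
#' @param state `"HEALTHY"`, `"FALSE_POSITIVE"`, or `"UNDETECTED_T2DM"`.
#' @param tc a [test_characteristics()].
#' @return the post-screen state name.
#' @export
screening_event <- function(state, tc) {
  i <- state_code(state)
  if (i > 3L) {
    stop_hbs("screening_event called on non-screenable state ", state,
             class = "contract_violation")
  }
  u <- stats::runif(1)
  if (i == 3L) {
    if (u < tc$sensitivity) "TREATED_T2DM" else "UNDETECTED_T2DM"
  } else {
    if (u < 1 - tc$specificity) "FALSE_POSITIVE" else "HEALTHY"
  }
}

#' Apply one year of disease progression and mortality
#'
#' Event order within the cycle: (i) incidence (healthy or false positive ->
#' undetected diabetes), (ii) complication (undetected at the untreated rate;
#' treated at the rate adjusted by `rr_comp_treated` on the hazard scale),
#' (iii) death at the life-table qx adjusted by the current state's mortality
#' relative risk.  Events are sequential, so a new case can reach the
#' complication state, and die at its relative risk, within one cycle.  Uses
#' the current R random stream.
#'
#' @param state a live state name.
#' @param risks a [risk_set()].
#' @param lt a `life_table`.
#' @param age current age (years); death uses qx at this age.
#' @return list with `state` (post-transition) and `age` (incremented by 1).
#' @export
annual_transition <- function(state, risks, lt, age) {
  i <- state_code(state)
  if (i == 6L) stop_hbs("annual_transition called on DEAD", class = "contract_violation")
  qx <- lt_lookup(lt, age)
  # incidence
  if (i <= 2L && stats::runif(1) < risks$annual_incidence) i <- 3L
  # complication
  if (i == 3L && stats::runif(1) < risks$annual_comp_rate) i <- 5L
  else if (i == 4L &&
           stats::runif(1) < adjusted_mortality(risks$annual_comp_rate,
                                                risks$rr_comp_treated)) i <- 5L
  # death
  if (stats::runif(1) < adjusted_mortality(qx, state_mort_rr(risks)[i])) i <- 6L
  list(state = health_states()[i], age = as.integer(age) + 1L)
}

#' Simulate one individual's lifetime
#'
#' Scalar reference implementation of the per-cycle schedule (screening on
#' cycles where `t %% interval_years == 0` while in a screenable state, then
#' [annual_transition()], then accrual).  Uses the current R random stream;
#' [run_microsim()] is the vectorized cohort driver.
#'
#' @param cfg a [model_config()].
#' @param strategy a [test_characteristics()].
#' @param lt a `life_table`.
#' @param entry_age entry age in years.
#' @return list with `discounted_cost` and `discounted_qaly`.
#' @export
simulate_individual <- function(cfg, strategy, lt, entry_age) {
  d <- cfg$settings$discount_rate
  max_age <- cfg$settings$max_age
  scost <- state_cost_vector(cfg)
  sutil <- state_utility_vector(cfg)
  state <- "HEALTHY"
  age <- as.integer(entry_age)
  cost <- 0
  qaly <- 0
  t <- 0L
  while (state != "DEAD" && age < max_age) {
    df <- discount_factor(t, d)
    if (t %% strategy$interval_years == 0L && state_code(state) <= 3L) {
      state <- screening_event(state, strategy)
      cost <- cost + cfg$costs$screening_cost * df
    }
    tr <- annual_transition(state, cfg$risks, lt, age)
    state <- tr$state
    age <- tr$age
    i <- state_code(state)
    cost <- cost + scost[i] * df
    qaly <- qaly + sutil[i] * df
    t <- t + 1L
  }
  list(discounted_cost = cost, discounted_qaly = qaly)
}

new_strategy_result <- function(label, mean_cost, mean_qaly, se_cost, se_qaly,
                                n, seed) {
  structure(
    list(strategy_label = label, mean_cost = mean_cost, mean_qaly = mean_qaly,
         se_cost = se_cost, se_qaly = se_qaly, n = n, seed = seed),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost %.2f (SE %.2f), QALY %.4f (SE %.4f), n = %d\n",
              x$strategy_label, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly, x$n))
  invisible(x)
}

#' Run the microsimulation for one strategy
#'
#' Simulates `n` independent individuals through annual cycles to death or
#' `max_age` and returns mean discounted cost and QALYs with their Monte
#' Carlo standard errors.  The engine is vectorized over individuals but
#' draws the same per-event Bernoulli variables as
#' [simulate_individual()]; identical `(cfg, strategy, lt, n, seed)` give
#' bit-identical results.
#'
#' @param cfg a [model_config()].
#' @param strategy a [test_characteristics()], normally one of
#'   `cfg$strategies`.
#' @param lt a `life_table` covering all ages from the stratum band to
#'   `max_age`.
#' @param n number of individuals (default `cfg$settings$cohort_size`).
#' @param seed integer seed (default `cfg$settings$seed`).
#' @return a `strategy_result`.
#' @export
run_microsim <- function(cfg, strategy, lt, n = cfg$settings$cohort_size,
                         seed = cfg$settings$seed) {
  stopifnot(inherits(cfg, "model_config"), inherits(strategy, "test_characteristics"),
            inherits(lt, "life_table"), n >= 1)
  set.seed(seed)
  d <- cfg$settings$discount_rate
  max_age <- cfg$settings$max_age
  if (max_age > max(lt$age)) {
    stop_hbs("life table must extend to max_age", class = "domain_error")
  }
  pool <- entry_age_pool(cfg)
  age <- if (length(pool) == 1L) rep(pool, n) else sample(pool, n, replace = TRUE)
  if (any(age < lt$age[1])) stop_hbs("entry age below life table", class = "domain_error")

  scost <- state_cost_vector(cfg)
  sutil <- state_utility_vector(cfg)
  rr <- state_mort_rr(cfg$risks)
  inc <- cfg$risks$annual_incidence
  comp <- cfg$risks$annual_comp_rate
  compT <- adjusted_mortality(comp, cfg$risks$rr_comp_treated)
  sens <- strategy$sensitivity
  spec <- strategy$specificity
  k <- strategy$interval_years

  state <- rep(1L, n)
  cost <- numeric(n)
  qaly <- numeric(n)
  t <- 0L
  repeat {
    active <- state != 6L & age < max_age
    if (!any(active)) break
    df <- (1 + d)^(-t)

    if (t %% k == 0L) {
      scr <- which(active & state <= 3L)
      if (length(scr)) {
        u <- stats::runif(length(scr))
        s <- state[scr]
        undet <- s == 3L
        s[undet] <- ifelse(u[undet] < sens, 4L, 3L)
        s[!undet] <- ifelse(u[!undet] < 1 - spec, 2L, 1L)
        state[scr] <- s
        cost[scr] <- cost[scr] + cfg$costs$screening_cost * df
      }
    }

    idx <- which(active)
    s <- state[idx]
    # incidence
    sus <- s <= 2L
    if (any(sus)) {
      s[sus][stats::runif(sum(sus)) < inc] <- 3L
    }
    # complication
    und <- s == 3L
    if (any(und)) s[und][stats::runif(sum(und)) < comp] <- 5L
    trt <- s == 4L
    if (any(trt)) s[trt][stats::runif(sum(trt)) < compT] <- 5L
    # death
    qx <- lt_lookup(lt, age[idx])
    pdie <- 1 - (1 - qx)^rr[s]
    s[stats::runif(length(s)) < pdie] <- 6L
    state[idx] <- s
    age[idx] <- age[idx] + 1L

    cost[idx] <- cost[idx] + scost[s] * df
    qaly[idx] <- qaly[idx] + sutil[s] * df
    t <- t + 1L
  }

  new_strategy_result(
    label = strategy$label,
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    n = as.integer(n), seed = as.integer(seed)
  )
}

#' Trace one simulated individual cycle by cycle
#'
#' Debugging aid: replays [simulate_individual()] and records, per cycle, the
#' post-transition state and the undiscounted cost and utility accrued.
#'
#' @inheritParams simulate_individual
#' @param seed integer seed.
#' @return data frame with columns `cycle`, `age`, `state`, `cost`, `utility`.
#' @export
simulate_trace <- function(cfg, strategy, lt, entry_age, seed = 1L) {
  set.seed(seed)
  d <- cfg$settings$discount_rate
  max_age <- cfg$settings$max_age
  scost <- state_cost_vector(cfg)
  sutil <- state_utility_vector(cfg)
  state <- "HEALTHY"
  age <- as.integer(entry_age)
  t <- 0L
  rows <- list()
  while (state != "DEAD" && age < max_age) {
    cycle_cost <- 0
    if (t %% strategy$interval_years == 0L && state_code(state) <= 3L) {
      state <- screening_event(state, strategy)
      cycle_cost <- cfg$costs$screening_cost
    }
    tr <- annual_transition(state, cfg$risks, lt, age)
    state <- tr$state
    age <- tr$age
    i <- state_code(state)
    rows[[length(rows) + 1L]] <- data.frame(
      cycle = t, age = age, state = state,
      cost = cycle_cost + scost[i], utility = sutil[i])
    t <- t + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Integer entry ages an individual can enter with (fixed or uniform over the
# stratum band).
entry_age_pool <- function(cfg) {
  if (!is.null(cfg$settings$entry_age)) return(cfg$settings$entry_age)
  seq(cfg$stratum$age_low, cfg$stratum$age_high)
}
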