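# Background (non-diabetic) mortality: period life tables as age-indexed
# annual death probabilities qx, synthetic Gompertz-Makeham tables, and
# hazard-scale relative-risk adjustment.

new_life_table <- function(age, qx) {
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

validate_life_table <- function(lt) {
  if (any(diff(lt$age) != 1L)) {
    miss <- lt$age[which(diff(lt$age) != 1L)[1]] + 1L
    stop_hbs("life table ages must be contiguous; missing age ", miss,
             class = "format_error")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop_hbs("life table qx values must lie in [0, 1]",
             class = "validation_error")
  }
  lt
}

#' Read a life table from CSV
#'
#' Expects a header `age,qx` and one row per integer age.  The terminal age's
#' qx is coerced to 1 (with a message) if it is not already, so that life
#' expectancy is finite.
#'
#' @param path CSV path.
#' @return a `life_table` (data frame with columns `age`, `qx`).
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_hbs("life table not found: ", path, class = "io_error")
  d <- utils::read.csv(path)
  if (!identical(names(d), c("age", "qx"))) {
    stop_hbs("life table CSV must have header 'age,qx'", class = "format_error")
  }
  d <- d[order(d$age), ]
  lt <- validate_life_table(new_life_table(d$age, d$qx))
  n <- nrow(lt)
  if (lt$qx[n] != 1) {
    message("read_life_table: coercing qx at terminal age ", lt$age[n], " to 1")
    lt$qx[n] <- 1
  }
  lt
}

#' Write a life table to CSV
#'
#' @param lt a `life_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d, qx %.3g-%.3g\n",
              min(x$age), max(x$age), min(x$qx), max(x$qx)))
  invisible(x)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probability `qx(age) = 1 - exp(-(c + a * exp(b * age)))` for
#' ages 0 to `max_age - 1`, with `qx(max_age) = 1`.  The default parameters
#' give a life expectancy at age 30 in the low 50s, plausible for a
#' high-income country, but this is an explicitly synthetic stand-in, not any
#' national table.
#'
#' @param a baseline Gompertz hazard per year (at age 0).
#' @param b log-hazard slope per year of age.
#' @param c Makeham (age-independent) hazard per year.
#' @param max_age terminal age.
#' @return a `life_table`.
#' @export
make_gompertz_lifetable <- function(a = 2e-5, b = 0.1, c = 5e-4, max_age = 110) {
  assert_scalar_number(a, "a", lower = 0)
  assert_scalar_number(b, "b", lower = 0)
  assert_scalar_number(c, "c", lower = 0)
  assert_scalar_number(max_age, "max_age", lower = 1)
  if (a == 0 && c == 0) {
    stop_hbs("at least one of a, c must be positive", class = "domain_error")
  }
  age <- 0:max_age
  qx <- 1 - exp(-(c + a * exp(b * age)))
  qx[length(qx)] <- 1
  new_life_table(age, qx)
}

lt_lookup <- function(lt, ages) {
  idx <- ages - lt$age[1] + 1L
  if (any(idx < 1L | idx > nrow(lt))) {
    stop_hbs("age outside life table range [", lt$age[1], ", ",
             lt$age[nrow(lt)], "]", class = "domain_error")
  }
  lt$qx[idx]
}

#' Period life expectancy at a given age
#'
#' Curtate expectation `sum_{t>=1} S(t)` with
#' `S(t) = prod_{k=0}^{t-1} (1 - q_{age+k})`, i.e. expected whole years of
#' life remaining; finite because the terminal qx is 1.
#'
#' @param lt a `life_table`.
#' @param entry_age age at which to evaluate, within the table's range.
#' @return expected remaining whole years of life.
#' @export
life_expectancy <- function(lt, entry_age) {
  if (entry_age < lt$age[1] || entry_age > lt$age[nrow(lt)]) {
    stop_hbs("entry_age outside life table range", class = "domain_error")
  }
  q <- lt$qx[lt$age >= entry_age]
  sum(cumprod(1 - q))
}

#' Adjust an annual death probability by a relative risk
#'
#' Hazard-scale adjustment `1 - (1 - qx)^rr`, which keeps the result in
#' \[0, 1\] for any rr > 0 (a plain product `rr * qx` would not, for large rr
#' at old ages).  Equals `qx` at rr = 1 and approaches `rr * qx` when
#' `rr * qx` is small.
#'
#' @param qx annual death probability (vectorized).
#' @param rr relative risk, > 0.
#' @return adjusted annual death probability.
#' @export
adjusted_mortality <- function(qx, rr) {
  if (any(rr <= 0)) stop_hbs("rr must be > 0", class = "domain_error")
  if (any(qx < 0 | qx > 1)) stop_hbs("qx must lie in [0, 1]", class = "domain_error")
  1 - (1 - qx)^rr
}
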