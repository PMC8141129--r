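# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

stop_hbs <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hbscreen_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hbs(name, " must be a single finite number", class = "validation_error")
  }
  if (strict_lower) {
    if (x <= lower) {
      stop_hbs(name, " must be > ", lower, class = "validation_error")
    }
  } else if (x < lower) {
    stop_hbs(name, " must be >= ", lower, class = "validation_error")
  }
  if (x > upper) {
    stop_hbs(name, " must be <= ", upper, class = "validation_error")
  }
  invisible(x)
}

#' Derive a reproducible sub-seed from a global seed
#'
#' Deterministic integer mixing so that per-stratum / per-strategy / per-draw
#' random streams can be derived from one global seed and run in any order
#' with identical results.  Uses 64-bit-safe modular arithmetic on doubles and
#' returns an integer in [1, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param ... one or more integers or strings identifying the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    # multiplicative hash; 48271 is the classic Lehmer multiplier
    h <- (h * 48271 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}
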