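# Incremental cost-effectiveness analysis: dominance, extended dominance,
# ICERs along the efficiency frontier, and the willingness-to-pay decision.

#' One strategy's discounted outcome pair
#'
#' @param label strategy label.
#' @param cost mean discounted cost (USD).
#' @param qaly mean discounted QALYs.
#' @return one-row data frame with columns `label`, `cost`, `qaly`.
#' @export
strategy_outcome <- function(label, cost, qaly) {
  stopifnot(is.character(label), length(label) == 1L, cost >= 0, qaly >= 0)
  data.frame(label = label, cost = cost, qaly = qaly, stringsAsFactors = FALSE)
}

as_outcomes <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    stopifnot(all(c("label", "cost", "qaly") %in% names(outcomes)))
    return(outcomes[, c("label", "cost", "qaly")])
  }
  do.call(rbind, lapply(outcomes, function(o) {
    if (inherits(o, "strategy_result")) {
      strategy_outcome(o$strategy_label, o$mean_cost, o$mean_qaly)
    } else {
      as_outcomes(o)
    }
  }))
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; maximizing NMB over strategies is equivalent to the
#' frontier/ICER decision rule in the absence of ties.
#'
#' @param outcome a data frame of outcomes (columns `cost`, `qaly`) or
#'   anything [build_cea_table()] accepts.
#' @param wtp willingness to pay, USD per QALY, >= 0.
#' @return numeric vector of NMB values, one per strategy.
#' @export
nmb <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  o <- as_outcomes(outcome)
  wtp * o$qaly - o$cost
}

#' Incremental cost-effectiveness table
#'
#' Reproduces the standard incremental analysis over one stratum's
#' strategies:
#' \enumerate{
#'   \item sort by cost ascending (ties: QALY descending, then label);
#'   \item mark strictly dominated strategies (another has cost <= and
#'     QALY >=, at least one strict; exact cost-and-QALY ties dominate
#'     neither way and are both kept);
#'   \item remove extended dominance from the remainder: repeatedly drop any
#'     interior strategy whose ICER against the previous frontier point is
#'     at least the ICER of the next point against it, so frontier ICERs
#'     strictly increase;
#'   \item compute incremental cost, incremental QALY, and ICER between
#'     consecutive frontier strategies;
#'   \item label a strategy \code{"dominant"} if it weakly dominates every
#'     other strategy;
#'   \item recommend the highest-QALY frontier strategy whose chain of ICERs
#'     up from the cheapest frontier strategy stays within \code{wtp}.
#' }
#'
#' @param outcomes >= 2 strategy outcomes: a data frame with columns
#'   `label`, `cost`, `qaly`, a list of [strategy_outcome()] rows, or a list
#'   of `strategy_result` objects.
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @param stratum optional [stratum_key()] carried into the table.
#' @return an object of class `cea_table`: list with `rows` (data frame
#'   `label, qaly, delta_qaly, cost, delta_cost, icer, status, comparator`,
#'   sorted by cost ascending), `recommendation`, `wtp`, `stratum`.
#' @export
build_cea_table <- function(outcomes, wtp, stratum = NULL) {
  o <- as_outcomes(outcomes)
  if (nrow(o) < 2L) {
    stop_hbs("at least 2 strategies are required", class = "validation_error")
  }
  if (anyDuplicated(o$label)) {
    stop_hbs("duplicate strategy labels: ",
             paste(unique(o$label[duplicated(o$label)]), collapse = ", "),
             class = "validation_error")
  }
  if (any(o$cost < 0) || any(o$qaly < 0)) {
    stop_hbs("costs and QALYs must be non-negative", class = "validation_error")
  }
  o <- o[order(o$cost, -o$qaly, o$label), , drop = FALSE]
  m <- nrow(o)

  # strict dominance
  dominated <- vapply(seq_len(m), function(i) {
    any(o$cost <= o$cost[i] & o$qaly >= o$qaly[i] &
          (o$cost < o$cost[i] | o$qaly > o$qaly[i]))
  }, logical(1))

  # extended dominance among the non-dominated, on distinct (cost, qaly)
  # points; exact ties travel together
  nd <- which(!dominated)
  key <- paste(o$cost[nd], o$qaly[nd])
  groups <- split(nd, factor(key, levels = unique(key)))
  ext <- logical(m)
  repeat {
    g <- length(groups)
    if (g < 3L) break
    cost_g <- vapply(groups, function(ix) o$cost[ix[1]], 0)
    qaly_g <- vapply(groups, function(ix) o$qaly[ix[1]], 0)
    icer_g <- diff(cost_g) / diff(qaly_g)   # length g - 1
    drop <- which(icer_g[-(g - 1)] >= icer_g[-1])[1] + 1L
    if (is.na(drop)) break
    ext[groups[[drop]]] <- TRUE
    groups <- groups[-drop]
  }
  frontier_idx <- unlist(groups, use.names = FALSE)

  status <- ifelse(dominated, "dominated",
                   ifelse(ext, "extended_dominated", "frontier"))
  weak_dom <- vapply(seq_len(m), function(i) {
    all(o$cost[i] <= o$cost & o$qaly[i] >= o$qaly)
  }, logical(1))
  status[status == "frontier" & weak_dom] <- "dominant"

  rows <- data.frame(
    label = o$label, qaly = o$qaly, delta_qaly = NA_real_,
    cost = o$cost, delta_cost = NA_real_, icer = NA_real_,
    status = status, comparator = NA_character_, stringsAsFactors = FALSE
  )
  fi <- sort(frontier_idx)
  if (length(fi) > 1L) {
    for (j in 2:length(fi)) {
      i <- fi[j]; prev <- fi[j - 1]
      dq <- o$qaly[i] - o$qaly[prev]
      dc <- o$cost[i] - o$cost[prev]
      if (dq == 0 && dc == 0) next   # exact tie: ICER undefined, skipped
      rows$comparator[i] <- o$label[prev]
      rows$delta_cost[i] <- dc
      rows$delta_qaly[i] <- dq
      rows$icer[i] <- if (dq > 0) dc / dq else NA_real_
    }
  }

  rec <- o$label[fi[1]]
  if (length(fi) > 1L) {
    for (j in 2:length(fi)) {
      ic <- rows$icer[fi[j]]
      if (is.na(ic) || ic <= wtp) {
        if (!is.na(ic)) rec <- rows$label[fi[j]]
      } else break
    }
  }

  structure(list(rows = rows, recommendation = rec, wtp = wtp, stratum = stratum),
            class = "cea_table")
}

#' @export
print.cea_table <- function(x, ...) {
  hdr <- if (!is.null(x$stratum)) paste0(" [", format(x$stratum), "]") else ""
  cat("<cea_table>", hdr, " WTP = ", format(x$wtp, big.mark = ","), "/QALY\n", sep = "")
  d <- x$rows
  fmt <- function(v, digits = 2) ifelse(is.na(v), "-", formatC(v, format = "f", digits = digits))
  show <- data.frame(
    strategy = d$label, QALY = fmt(d$qaly), incr.QALY = fmt(d$delta_qaly),
    cost = fmt(d$cost), incr.cost = fmt(d$delta_cost), ICER = fmt(d$icer),
    status = ifelse(is.na(d$comparator) | d$status %in% c("dominated", "extended_dominated", "dominant"),
                    d$status, paste0(d$status, " (vs ", d$comparator, ")")),
    stringsAsFactors = FALSE
  )
  print(show, row.names = FALSE)
  cat("recommended:", x$recommendation, "\n")
  invisible(x)
}

#' @export
summary.cea_table <- function(object, ...) {
  f <- object$rows[object$rows$status %in% c("frontier", "dominant"), ]
  cat("Frontier strategies:", paste(f$label, collapse = " -> "), "\n")
  cat("Recommended at WTP", format(object$wtp, big.mark = ","), ":",
      object$recommendation, "\n")
  invisible(object)
}

#' Recommended strategy at a willingness-to-pay threshold
#'
#' @inheritParams build_cea_table
#' @return the recommended strategy's label.
#' @export
recommend <- function(outcomes, wtp) {
  build_cea_table(outcomes, wtp)$recommendation
}

#' Export a CEA table as CSV
#'
#' Columns: `stratum, strategy, qaly, incr_qaly, cost, incr_cost, icer,
#' status, comparator`.
#'
#' @param tab a `cea_table` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(tab, path) {
  tabs <- if (inherits(tab, "cea_table")) list(tab) else tab
  rows <- do.call(rbind, lapply(tabs, function(x) {
    d <- x$rows
    data.frame(
      stratum = if (is.null(x$stratum)) "" else format(x$stratum),
      strategy = d$label, qaly = d$qaly, incr_qaly = d$delta_qaly,
      cost = d$cost, incr_cost = d$delta_cost, icer = round(d$icer, 2),
      status = d$status, comparator = d$comparator, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}
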