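#' Incremental cost-effectiveness outputs
#'
#' Pairs two cohort traces into incremental cost, incremental QALYs, the
#' ICER (computed on unrounded totals; display rounding is left to report
#' time), dominance flags and the net monetary benefit at a
#' willingness-to-pay threshold.
#'
#' @name economics
NULL

#' Compute the ICER and NMB for intervention vs. comparator
#'
#' @param comparator,intervention `cohort_trace` objects from identical
#'   settings (same horizon, discounting, life table).
#' @param wtp Willingness-to-pay threshold (CNY/QALY) for the NMB.
#' @return A `ce_result` list: per-arm totals, `inc_cost`, `inc_qaly`,
#'   `icer` (NA when undefined or dominance applies), `status` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`), `nmb`, `wtp`.
#' @export
compute_icer <- function(comparator, intervention, wtp = NULL) {
  inc_cost <- intervention$total_cost - comparator$total_cost
  inc_qaly <- intervention$total_qaly - comparator$total_qaly
  status <- "icer"
  icer <- NA_real_
  if (inc_qaly == 0) {
    status <- "undefined"
  } else if (inc_qaly > 0 && inc_cost < 0) {
    status <- "dominant"
  } else if (inc_qaly < 0 && inc_cost > 0) {
    status <- "dominated"
  } else {
    icer <- inc_cost / inc_qaly
  }
  nmb <- if (!is.null(wtp)) wtp * inc_qaly - inc_cost else NA_real_
  structure(list(
    cost_comparator = comparator$total_cost,
    qaly_comparator = comparator$total_qaly,
    cost_intervention = intervention$total_cost,
    qaly_intervention = intervention$total_qaly,
    inc_cost = inc_cost, inc_qaly = inc_qaly,
    icer = icer, status = status, nmb = nmb, wtp = wtp
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%-12s %14s %10s\n", "strategy", "cost (CNY)", "QALYs"))
  cat(sprintf("%-12s %14.2f %10.2f\n", "comparator",
              x$cost_comparator, x$qaly_comparator))
  cat(sprintf("%-12s %14.2f %10.2f\n", "intervention",
              x$cost_intervention, x$qaly_intervention))
  cat(sprintf("incremental cost %.2f CNY, incremental QALYs %.2f\n",
              x$inc_cost, x$inc_qaly))
  if (x$status == "icer") {
    cat(sprintf("ICER %.2f CNY/QALY\n", x$icer))
  } else {
    cat("ICER:", x$status, "\n")
  }
  if (!is.null(x$wtp)) {
    cat(sprintf("NMB at WTP %.0f: %.2f CNY\n", x$wtp, x$nmb))
  }
  invisible(x)
}

#' Willingness-to-pay decision rule
#'
#' The intervention is cost-effective if it dominates, or if its ICER is
#' defined with a QALY gain and falls below the threshold.
#'
#' @param result `ce_result` object.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @return Logical.
#' @export
is_cost_effective <- function(result, wtp) {
  if (result$status == "dominant") return(TRUE)
  if (result$status %in% c("dominated", "undefined")) return(FALSE)
  result$inc_qaly > 0 && result$icer < wtp
}

#' Run the base-case comparison for a parameter set
#'
#' Simulates both arms and computes the incremental result at the
#' configured WTP.
#'
#' @param p Validated `ascvd_params` object.
#' @param lt `life_table`.
#' @return A `ce_result`.
#' @export
run_base_case <- function(p, lt) {
  arms <- model_arms(p)
  compute_icer(run_cohort(p, arms$comparator, lt),
               run_cohort(p, arms$intervention, lt),
               wtp = p$settings$wtp)
}

#' Results table in publication layout
#'
#' @param result `ce_result` object.
#' @param digits Display rounding (default 2).
#' @return `data.frame` with one row per strategy plus incremental columns.
#' @export
ce_table <- function(result, digits = 2) {
  data.frame(
    strategy = c("comparator", "intervention"),
    total_cost = round(c(result$cost_comparator, result$cost_intervention), digits),
    total_qaly = round(c(result$qaly_comparator, result$qaly_intervention), digits),
    inc_cost = c(NA, round(result$inc_cost, digits)),
    inc_qaly = c(NA, round(result$inc_qaly, digits)),
    icer = c(NA, round(result$icer, digits))
  )
}
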