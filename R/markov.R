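#' Six-state Markov cohort engine
#'
#' Annual-cycle cohort simulation over the states baseline ASCVD, acute
#' (year-of-event) MI, acute IS, post-MI, post-IS, CV death and non-CV
#' death. Event transitions derive from calibrated annual rates via the
#' exponential conversion; death combines the model's own CV-death channel
#' with life-table background (non-CV) mortality. Costs and QALYs are
#' accumulated per cycle, half-cycle corrected and discounted.
#'
#' Structural rules: only one CV event per cycle; survivors of an acute
#' state move to the matching post state in the following cycle; recurrences
#' from post states re-enter the acute state (memoryless process); dead
#' states are absorbing.
#'
#' @name markov_engine
NULL

#' Model health states
#'
#' @return Character vector of the seven state labels in canonical order.
#' @export
health_states <- function() {
  c("BASELINE_ASCVD", "ACUTE_MI", "ACUTE_IS", "POST_MI", "POST_IS",
    "DEAD_CV", "DEAD_NONCV")
}

#' Define a treatment arm
#'
#' @param name Arm label.
#' @param on_inclisiran Whether the arm receives inclisiran on top of
#'   statin therapy.
#' @param delta_ldl Absolute LDL-C reduction applied (mmol/L); 0 for the
#'   comparator arm.
#' @return An `arm_spec` list.
#' @export
arm_spec <- function(name, on_inclisiran, delta_ldl) {
  if (delta_ldl < 0) stop("arm_spec: delta_ldl must be non-negative")
  structure(list(name = name, on_inclisiran = on_inclisiran,
                 delta_ldl = delta_ldl), class = "arm_spec")
}

#' Comparator and intervention arms from a parameter set
#'
#' The comparator is statin therapy alone (`delta_ldl = 0`); the
#' intervention adds inclisiran with the configured absolute LDL-C
#' reduction.
#'
#' @param p Validated `ascvd_params` object.
#' @return List with elements `comparator` and `intervention`.
#' @export
model_arms <- function(p) {
  list(
    comparator   = arm_spec("statin", FALSE, 0),
    intervention = arm_spec("inclisiran", TRUE, p$effects$ldl_reduction_abs$point)
  )
}

# Per-person-year event rates for an arm, after treatment-effect mapping.
.arm_rates <- function(p, arm) {
  d <- arm$delta_ldl
  list(
    mi  = treated_rate(p$baseline$mi$point / 100, p$effects$rr_mi$point, d),
    is_ = treated_rate(p$baseline$is_$point / 100, p$effects$rr_is$point, d),
    cv_death = treated_rate(p$baseline$cv_death$point / 100,
                            p$effects$rr_cv_death$point, d),
    bg_mult = if (isTRUE(p$settings$apply_all_cause_effect)) {
      p$effects$rr_all_cause$point^d
    } else 1
  )
}

#' Annual transition-probability matrix at an age
#'
#' Builds the full state-by-state matrix for one cycle. Event probabilities
#' come from the arm's treated (or baseline) rates via `1 - exp(-r)`; the
#' MI rate from post-MI and the IS rate from post-IS carry the
#' recurrent-event hazard ratio; CV death from the acute states carries the
#' first-year post-event mortality hazard ratio; background non-CV death is
#' the life-table all-cause minus CV rate (all-cause treatment effect
#' applied in the intervention arm when enabled). Remaining probability
#' stays in (or, for acute states, feeds) the destination dictated by the
#' structure.
#'
#' @param p Validated `ascvd_params` object.
#' @param arm `arm_spec` for the arm being simulated.
#' @param lt `life_table` covering `floor(age)`.
#' @param age Cohort age at the start of the cycle.
#' @return 7x7 row-stochastic matrix with dimnames [health_states()].
#' @export
transition_matrix <- function(p, arm, lt, age) {
  st <- health_states()
  r <- .arm_rates(p, arm)
  bg <- mortality_split(lt, age)$non_cv_rate * r$bg_mult

  p_mi  <- rate_to_prob(r$mi)
  p_is  <- rate_to_prob(r$is_)
  p_cvd <- rate_to_prob(r$cv_death)
  p_bg  <- rate_to_prob(bg)
  p_cvd_acute <- rate_to_prob(r$cv_death * p$effects$hr_post_event_death$point)
  p_mi_rec <- rate_to_prob(r$mi * p$effects$hr_recurrent_mi$point)
  p_is_rec <- rate_to_prob(r$is_ * p$effects$hr_recurrent_is$point)

  M <- matrix(0, 7, 7, dimnames = list(st, st))
  set_row <- function(M, from, to_probs, residual_to) {
    tot <- sum(to_probs)
    if (tot > 1) {
      stop("transition_matrix: probabilities from ", from, " sum to ",
           format(tot), " > 1 at age ", floor(age))
    }
    M[from, names(to_probs)] <- to_probs
    M[from, residual_to] <- M[from, residual_to] + (1 - tot)
    M
  }
  M <- set_row(M, "BASELINE_ASCVD",
               c(ACUTE_MI = p_mi, ACUTE_IS = p_is,
                 DEAD_CV = p_cvd, DEAD_NONCV = p_bg),
               "BASELINE_ASCVD")
  # acute-state survivors move on deterministically; one event per cycle
  M <- set_row(M, "ACUTE_MI",
               c(DEAD_CV = p_cvd_acute, DEAD_NONCV = p_bg), "POST_MI")
  M <- set_row(M, "ACUTE_IS",
               c(DEAD_CV = p_cvd_acute, DEAD_NONCV = p_bg), "POST_IS")
  M <- set_row(M, "POST_MI",
               c(ACUTE_MI = p_mi_rec, ACUTE_IS = p_is,
                 DEAD_CV = p_cvd, DEAD_NONCV = p_bg),
               "POST_MI")
  M <- set_row(M, "POST_IS",
               c(ACUTE_MI = p_mi, ACUTE_IS = p_is_rec,
                 DEAD_CV = p_cvd, DEAD_NONCV = p_bg),
               "POST_IS")
  M["DEAD_CV", "DEAD_CV"] <- 1
  M["DEAD_NONCV", "DEAD_NONCV"] <- 1
  if (any(M < 0) || any(M > 1)) {
    bad <- which(M < 0 | M > 1, arr.ind = TRUE)[1, ]
    stop("transition_matrix: probability out of [0, 1] in cell [",
         st[bad[1]], ", ", st[bad[2]], "]")
  }
  M
}

#' Per-cycle discount factor
#'
#' `1/(1+rate)^(cycle-0.5)` under the half-cycle correction (costs and
#' QALYs valued at the cycle midpoint), else `1/(1+rate)^cycle`.
#'
#' @param rate Annual discount rate, >= 0.
#' @param cycle Cycle index, 1-based.
#' @param half_cycle Apply midpoint discounting?
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle, half_cycle = TRUE) {
  stopifnot(rate >= 0, all(cycle >= 1))
  expo <- if (half_cycle) cycle - 0.5 else cycle
  (1 + rate)^(-expo)
}

#' Run the cohort simulation for one arm
#'
#' Starts the whole cohort in baseline ASCVD at the population mean age and
#' evolves it for `settings$horizon_years` annual cycles with age-varying
#' background mortality. Per cycle, costs are the occupancy-weighted state
#' costs (acute-year vs. later-year event management costs; drug costs for
#' all alive states, with the higher first-year inclisiran schedule in
#' cycle 1) plus one-off death costs charged to the fraction newly dead
#' that cycle; QALYs are occupancy-weighted state utilities. State
#' occupancy is evaluated at cycle start; both streams are discounted at
#' the cycle midpoint when the half-cycle correction is on.
#'
#' @param p Validated `ascvd_params` object.
#' @param arm `arm_spec`.
#' @param lt `life_table` covering the whole age span of the run.
#' @return A `cohort_trace` list: `occupancy` ((horizon+1) x 7 matrix, row
#'   1 = initial state), `cycle_costs` and `cycle_qalys` (discounted, per
#'   cycle), `total_cost`, `total_qaly`, `arm`.
#' @export
run_cohort <- function(p, arm, lt) {
  st <- health_states()
  H <- p$settings$horizon_years
  age0 <- p$population$mean_age
  if (floor(age0 + H - 1) > max(lt$age)) {
    stop("run_cohort: life table ends at age ", max(lt$age),
         " but horizon needs age ", floor(age0 + H - 1))
  }

  u <- c(p$utilities$baseline_ascvd$point, p$utilities$mi_year1$point,
         p$utilities$is_year1$point, p$utilities$mi_later$point,
         p$utilities$is_later$point, 0, 0)
  state_cost <- c(0, p$costs$mi_year1$point, p$costs$is_year1$point,
                  p$costs$mi_later$point, p$costs$is_later$point, 0, 0)
  drug_later <- p$costs$statin_annual$point +
    if (arm$on_inclisiran) p$costs$inclisiran_later$point else 0
  drug_first <- p$costs$statin_annual$point +
    if (arm$on_inclisiran) p$costs$inclisiran_year1$point else 0

  occ <- matrix(0, H + 1, 7, dimnames = list(0:H, st))
  occ[1, "BASELINE_ASCVD"] <- 1
  cycle_costs <- cycle_qalys <- numeric(H)
  alive_idx <- 1:5

  for (k in seq_len(H)) {
    now <- occ[k, ]
    M <- transition_matrix(p, arm, lt, age0 + k - 1)
    nxt <- as.vector(now %*% M)
    names(nxt) <- st
    occ[k + 1, ] <- nxt

    df <- discount_factor(p$settings$discount_rate, k, p$settings$half_cycle)
    drug <- if (k == 1) drug_first else drug_later
    new_cv  <- nxt["DEAD_CV"] - now["DEAD_CV"]
    new_ncv <- nxt["DEAD_NONCV"] - now["DEAD_NONCV"]
    cost_k <- sum(now * state_cost) + sum(now[alive_idx]) * drug +
      new_cv * p$costs$cv_death$point + new_ncv * p$costs$non_cv_death$point
    cycle_costs[k] <- df * cost_k
    cycle_qalys[k] <- df * sum(now * u)
  }

  structure(list(
    occupancy = occ,
    cycle_costs = cycle_costs,
    cycle_qalys = cycle_qalys,
    total_cost = sum(cycle_costs),
    total_qaly = sum(cycle_qalys),
    arm = arm
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("cohort trace: arm '%s', %d cycles\n", x$arm$name,
              length(x$cycle_costs)))
  cat(sprintf("  total discounted cost: %.2f\n", x$total_cost))
  cat(sprintf("  total discounted QALY: %.4f\n", x$total_qaly))
  invisible(x)
}

#' Export a cohort trace as a per-cycle data frame
#'
#' One row per cycle with start-of-cycle occupancy and the discounted cost
#' and QALY accrued in that cycle.
#'
#' @param trace `cohort_trace` object.
#' @return `data.frame` with columns `cycle`, one per health state,
#'   `disc_cost`, `disc_qaly`.
#' @export
trace_table <- function(trace) {
  H <- length(trace$cycle_costs)
  df <- as.data.frame(trace$occupancy[seq_len(H), , drop = FALSE])
  cbind(data.frame(cycle = seq_len(H)), df,
        data.frame(disc_cost = trace$cycle_costs,
                   disc_qaly = trace$cycle_qalys))
}
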