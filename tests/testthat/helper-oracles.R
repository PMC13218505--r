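# Independent oracles and shared fixtures for the test suite.

# One synthetic world for the whole suite; regenerating is cheap but this
# keeps every test on the identical table.
test_life_table <- function() generate_life_table()

# Individual-level microsimulation using the same per-cycle transition
# matrices as the cohort engine, as an independent check of the cohort
# arithmetic (costs/QALYs accrued per walker exactly as the cohort engine
# accrues them in expectation).
microsim_run <- function(p, arm, lt, n_walkers, seed) {
  set.seed(seed)
  st <- health_states()
  H <- p$settings$horizon_years
  age0 <- p$population$mean_age
  u <- c(p$utilities$baseline_ascvd$point, p$utilities$mi_year1$point,
         p$utilities$is_year1$point, p$utilities$mi_later$point,
         p$utilities$is_later$point, 0, 0)
  state_cost <- c(0, p$costs$mi_year1$point, p$costs$is_year1$point,
                  p$costs$mi_later$point, p$costs$is_later$point, 0, 0)
  drug_later <- p$costs$statin_annual$point +
    if (arm$on_inclisiran) p$costs$inclisiran_later$point else 0
  drug_first <- p$costs$statin_annual$point +
    if (arm$on_inclisiran) p$costs$inclisiran_year1$point else 0
  death_cost <- c(rep(0, 5), p$costs$cv_death$point, p$costs$non_cv_death$point)

  state <- rep(1L, n_walkers)
  qaly <- cost <- numeric(n_walkers)
  for (k in seq_len(H)) {
    M <- transition_matrix(p, arm, lt, age0 + k - 1)
    df <- discount_factor(p$settings$discount_rate, k, p$settings$half_cycle)
    drug <- if (k == 1) drug_first else drug_later
    qaly <- qaly + df * u[state]
    cost <- cost + df * (state_cost[state] + drug * (state <= 5))
    nxt <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      nxt[idx] <- sample.int(7, length(idx), replace = TRUE, prob = M[s, ])
    }
    newly_dead <- state <= 5 & nxt >= 6
    cost[newly_dead] <- cost[newly_dead] + df * death_cost[nxt[newly_dead]]
    state <- nxt
  }
  list(
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n_walkers),
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n_walkers),
    final_occupancy = tabulate(state, 7) / n_walkers
  )
}

# Manually assembled cohort_trace stand-in for economics tests.
fake_trace <- function(total_cost, total_qaly, name = "arm") {
  structure(list(total_cost = total_cost, total_qaly = total_qaly,
                 arm = arm_spec(name, FALSE, 0)), class = "cohort_trace")
}
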