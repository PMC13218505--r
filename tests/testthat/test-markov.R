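# Parameter helpers used to build degenerate worlds for closed-form checks.
zero_event_params <- function(p = default_parameters()) {
  for (f in c("mi", "is_", "cv_death")) p <- set_param(p, paste0("baseline.", f), 0)
  p <- set_param(p, "baseline.composite", 0)
  p
}
flat_table <- function(rate, cv = 0) {
  data.frame(age = 40:100, all_cause_rate = rate, cv_rate = cv)
}

test_that("discount factors follow midpoint/end-of-cycle closed forms", {
  expect_equal(discount_factor(0, 1:30, TRUE), rep(1, 30))
  expect_equal(discount_factor(0.045, 1, FALSE), 1 / 1.045)
  expect_equal(discount_factor(0.045, 1, TRUE), 0.978231976089037,
               tolerance = 1e-12)
  expect_equal(discount_factor(0.045, 7, TRUE),
               1.045^-(6.5), tolerance = 1e-15)
})

test_that("no-risk transition matrix is identity up to the acute->post feed", {
  # with zero rates everywhere, every state holds except the acute states,
  # which still hand survivors to their post state the following cycle
  p <- zero_event_params()
  arms <- model_arms(p)
  M <- transition_matrix(p, arms$comparator, flat_table(0), 60)
  expect_equal(unname(diag(M)[c(1, 4, 5, 6, 7)]), rep(1, 5))
  expect_equal(M["ACUTE_MI", "POST_MI"], 1)
  expect_equal(M["ACUTE_IS", "POST_IS"], 1)
  expect_equal(sum(M), 7)
})

test_that("baseline-row event probabilities follow the exponential formula", {
  p <- default_parameters()
  arms <- model_arms(p)
  lt <- test_life_table()
  M <- transition_matrix(p, arms$comparator, lt, 59.5)
  expect_equal(M["BASELINE_ASCVD", "ACUTE_MI"], 1 - exp(-0.0353), tolerance = 1e-12)
  expect_equal(M["BASELINE_ASCVD", "ACUTE_IS"], 1 - exp(-0.0172), tolerance = 1e-12)
  expect_equal(M["BASELINE_ASCVD", "DEAD_CV"], 1 - exp(-0.0070), tolerance = 1e-12)
  expect_equal(rowSums(M), rep(1, 7), ignore_attr = TRUE, tolerance = 1e-12)

  # treated arm reduces each event probability when rr < 1
  Mi <- transition_matrix(p, arms$intervention, lt, 59.5)
  for (ev in c("ACUTE_MI", "ACUTE_IS", "DEAD_CV")) {
    expect_lt(Mi["BASELINE_ASCVD", ev], M["BASELINE_ASCVD", ev])
  }
  # structural rules: acute states feed post states, no acute->acute events
  expect_equal(M["ACUTE_MI", "ACUTE_IS"], 0)
  expect_equal(M["ACUTE_IS", "ACUTE_MI"], 0)
  expect_gt(M["ACUTE_MI", "POST_MI"], 0.9)
  # recurrent-event and post-event-death multipliers
  expect_equal(M["POST_MI", "ACUTE_MI"], 1 - exp(-0.0353 * 1.13), tolerance = 1e-12)
  expect_equal(M["POST_IS", "ACUTE_IS"], 1 - exp(-0.0172 * 1.13), tolerance = 1e-12)
  expect_equal(M["ACUTE_MI", "DEAD_CV"], 1 - exp(-0.0070 * 1.31), tolerance = 1e-12)
  # absorbing death
  expect_equal(M["DEAD_CV", "DEAD_CV"], 1)
  expect_equal(M["DEAD_NONCV", "DEAD_NONCV"], 1)
})

test_that("impossible probability mass is reported with the offending row", {
  p <- default_parameters()
  p <- set_param(p, "baseline.mi", 90)
  p <- set_param(p, "baseline.is_", 90)
  p <- set_param(p, "baseline.cv_death", 90)
  p <- set_param(p, "baseline.composite", 270)
  expect_error(
    transition_matrix(p, model_arms(p)$comparator, flat_table(0.5), 60),
    "BASELINE_ASCVD")
})

test_that("constant-occupancy cohort gives QALYs = u * H undiscounted", {
  p <- zero_event_params()
  p$settings$discount_rate <- 0
  p$settings$horizon_years <- 12L
  tr <- run_cohort(p, model_arms(p)$comparator, flat_table(0))
  expect_equal(tr$total_qaly, 0.824 * 12, tolerance = 1e-12)
  # only drug costs accrue: statin every year
  expect_equal(tr$total_cost, 3645 * 12, tolerance = 1e-12)
})

test_that("two-state toy matches the geometric closed form", {
  p_die <- 0.07
  rate <- prob_to_rate(p_die)
  p <- zero_event_params()
  p$settings$discount_rate <- 0
  p$settings$horizon_years <- 20L
  tr <- run_cohort(p, model_arms(p)$comparator, flat_table(rate))
  occ <- tr$occupancy
  for (k in 0:20) {
    expect_equal(occ[k + 1, "BASELINE_ASCVD"], (1 - p_die)^k, tolerance = 1e-12)
  }
  # undiscounted QALYs equal the partial geometric sum of survivors
  expect_equal(tr$total_qaly,
               0.824 * sum((1 - p_die)^(0:19)), tolerance = 1e-12)
})

test_that("trace invariants hold across arms, horizons and random draws", {
  lt <- test_life_table()
  set.seed(303)
  for (rep in 1:8) {
    p <- default_parameters()
    p$settings$horizon_years <- sample(c(5L, 17L, 30L), 1)
    if (rep > 2) {  # perturb a few inputs
      p <- set_param(p, "effects.rr_all_cause", stats::runif(1, 0.87, 0.93))
      p <- set_param(p, "effects.ldl_reduction_abs", stats::runif(1, 1.5, 1.63))
      p <- set_param(p, "utilities.is_year1", stats::runif(1, 0.264, 0.390))
    }
    for (arm in model_arms(p)) {
      tr <- run_cohort(p, arm, lt)
      expect_equal(rowSums(tr$occupancy),
                   rep(1, p$settings$horizon_years + 1),
                   ignore_attr = TRUE, tolerance = 1e-9)
      expect_true(all(tr$occupancy >= -1e-15 & tr$occupancy <= 1 + 1e-15))
      dead <- tr$occupancy[, "DEAD_CV"] + tr$occupancy[, "DEAD_NONCV"]
      expect_true(all(diff(dead) >= -1e-15))
    }
  }
})

test_that("intervention dominates in QALYs and costs at every horizon", {
  p <- default_parameters()
  lt <- test_life_table()
  arms <- model_arms(p)
  for (h in c(1L, 5L, 15L, 30L)) {
    p$settings$horizon_years <- h
    trc <- run_cohort(p, arms$comparator, lt)
    tri <- run_cohort(p, arms$intervention, lt)
    expect_gte(tri$total_qaly, trc$total_qaly)
    expect_gte(tri$total_cost, trc$total_cost)
  }
})

test_that("total QALYs strictly decrease as the discount rate rises", {
  lt <- test_life_table()
  qalys <- vapply(c(0, 0.02, 0.045, 0.08), function(r) {
    p <- default_parameters()
    p$settings$discount_rate <- r
    run_cohort(p, model_arms(p)$comparator, lt)$total_qaly
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("horizon beyond life-table coverage is refused", {
  p <- default_parameters()
  p$settings$horizon_years <- 60L
  expect_error(run_cohort(p, model_arms(p)$comparator, test_life_table()),
               "life table ends")
})

test_that("trace export has one row per cycle with occupancy and accumulators", {
  p <- default_parameters()
  p$settings$horizon_years <- 4L
  tr <- run_cohort(p, model_arms(p)$comparator, test_life_table())
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 4)
  expect_true(all(health_states() %in% names(tab)))
  expect_equal(sum(tab$disc_qaly), tr$total_qaly)
})
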