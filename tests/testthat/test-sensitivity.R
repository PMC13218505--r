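test_that("distribution fitting matches the stated moment formulas", {
  rr <- fit_distribution(uparam(0.78, 0.76, 0.80, "lognormal"), "rr_mace")
  expect_equal(rr$meanlog, log(0.78), tolerance = 1e-12)
  expect_equal(rr$sdlog, 0.0130850240784568, tolerance = 1e-12)

  nm <- fit_distribution(uparam(57.2, 51.3, 63.1, "normal"), "ldl_pct")
  expect_equal(nm$mean, 57.2)
  expect_equal(nm$sd, 3.01020408163265, tolerance = 1e-12)

  gm <- fit_distribution(uparam(23567.4, 18853.9, 28280.9, "gamma"), "mi_cost")
  sd <- (28280.9 - 18853.9) / 3.92
  expect_equal(gm$shape / gm$rate, 23567.4, tolerance = 1e-9)       # mean
  expect_equal(gm$shape / gm$rate^2, sd^2, tolerance = 1e-6)        # variance

  bt <- fit_distribution(uparam(0.824, 0.800, 0.848, "beta"), "u_base")
  m <- bt$shape1 / (bt$shape1 + bt$shape2)
  v <- bt$shape1 * bt$shape2 /
    ((bt$shape1 + bt$shape2)^2 * (bt$shape1 + bt$shape2 + 1))
  expect_equal(m, 0.824, tolerance = 1e-12)
  expect_equal(sqrt(v), (0.848 - 0.800) / 3.92, tolerance = 1e-9)

  expect_error(fit_distribution(uparam(1, 1, 1, "normal"), "x"), "degenerate")
  expect_error(fit_distribution(uparam(5, 4, 6, "fixed"), "x"), "fixed")
  expect_error(fit_distribution(uparam(0.5, 0.5 - 1.2, 0.5 + 1.2, "beta"), "u"),
               "infeasible")
})

test_that("sampled means converge to the point estimates", {
  set.seed(99)
  n <- 1e5
  cases <- list(
    list(u = uparam(0.78, 0.76, 0.80, "lognormal"), tol = 0.01),
    list(u = uparam(57.2, 51.3, 63.1, "normal"), tol = 0.01),
    list(u = uparam(23567.4, 18853.9, 28280.9, "gamma"), tol = 0.01),
    list(u = uparam(0.327, 0.264, 0.390, "beta"), tol = 0.01)
  )
  for (cs in cases) {
    x <- sample_distribution(fit_distribution(cs$u, "p"), n)
    expect_equal(mean(x), cs$u$point, tolerance = cs$tol)
  }
})

test_that("one-way analysis reproduces the base ICER for collapsed ranges", {
  p <- default_parameters()
  lt <- test_life_table()
  # collapse one range to a point: both ends must return the base ICER
  p$effects$rr_mi <- uparam(0.73, 0.73, 0.73, "lognormal")
  tor <- run_owsa(p, lt, "effects.rr_mi")
  expect_equal(tor$icer_low, tor$icer_high, tolerance = 1e-12)
  expect_equal(tor$icer_low, attr(tor, "base_icer"), tolerance = 1e-12)
  expect_equal(tor$spread, 0)
  expect_error(run_owsa(p, lt, "effects.not_a_param"), "unknown parameter")
})

test_that("one-way analysis is sorted by spread and handles linked rows", {
  p <- default_parameters()
  lt <- test_life_table()
  tor <- run_owsa(p, lt, c("settings.discount_rate",
                           "inclisiran_price_per_dose",
                           "utilities.is_later",
                           "costs.non_cv_death"))
  expect_true(all(diff(tor$spread) <= 0))
  # discount-rate row brackets the base ICER
  drow <- tor[tor$parameter == "settings.discount_rate", ]
  base <- attr(tor, "base_icer")
  expect_lt(drow$icer_low, base)
  expect_gt(drow$icer_high, base)
  # cheaper inclisiran lowers the ICER; upper bound is current price = base
  prow <- tor[tor$parameter == "inclisiran_price_per_dose", ]
  expect_lt(prow$icer_low, base)
  expect_equal(prow$icer_high, base, tolerance = 1e-12)
})

test_that("PSA is reproducible, respects bounds, and centres on the base", {
  p <- default_parameters()
  p$settings$horizon_years <- 10L  # keep the small-draw checks cheap
  lt <- test_life_table()
  a <- run_psa(p, lt, draws = 40, seed = 7)
  b <- run_psa(p, lt, draws = 40, seed = 7)
  expect_equal(a$draws, b$draws)
  expect_equal(a$results, b$results)
  c2 <- run_psa(p, lt, draws = 40, seed = 8)
  expect_false(isTRUE(all.equal(a$results$inc_cost, c2$results$inc_cost)))

  expect_equal(nrow(a$results), 40)
  expect_true(all(is.finite(as.matrix(a$draws))))
  ucols <- grep("^utilities\\.", names(a$draws), value = TRUE)
  expect_true(all(a$draws[ucols] > 0 & a$draws[ucols] < 1))
})

test_that("CEAC limits, grid behaviour and tie handling are exact", {
  psa <- structure(list(
    results = data.frame(inc_cost = c(100, 200, 300),
                         inc_qaly = c(0.01, 0.02, 0.03)),
    seed = 1, n_resampled = 0L,
    draws = data.frame()), class = "psa_draws")
  expect_equal(prob_cost_effective(psa, 0), 0)       # all costs positive
  expect_equal(prob_cost_effective(psa, 1e9), 1)     # all gains positive
  # a threshold equal to a draw's realized ICER is not counted (strict >)
  expect_equal(prob_cost_effective(psa, 10000), 0)
  expect_equal(prob_cost_effective(psa, 10000 + 1e-6), 1)
  cc <- ceac(psa, c(0, 10000, 20000))
  expect_equal(cc$prob_cost_effective, c(0, 0, 1))
  expect_error(ceac(psa, numeric(0)), "empty")
})

test_that("horizon sweep shows the limiting short-horizon behaviour", {
  p <- default_parameters()
  lt <- test_life_table()
  sw <- horizon_sweep(p, lt, c(1, 2, 10))
  # with start-of-cycle occupancy accrual a 1-cycle run has identical
  # occupancy in both arms: zero QALY gain, ICER undefined
  expect_equal(sw$inc_qaly[1], 0)
  expect_true(is.na(sw$icer[1]))
  expect_lt(sw$inc_qaly[2], 0.01)
  expect_gt(sw$icer[2], 1e6)         # near-zero gain, drug cost fully loaded
  expect_lt(sw$icer[3], sw$icer[2])
})
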