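#' Sensitivity analyses
#'
#' Deterministic one-way (tornado) analysis over parameter ranges,
#' probabilistic sensitivity analysis sampling every non-fixed parameter
#' from its assigned distribution family, cost-effectiveness acceptability
#' curves, and time-horizon scenario sweeps.
#'
#' @name sensitivity
NULL

#' Fit a sampling distribution to an uncertain parameter
#'
#' Interprets `(low, high)` as a 95% interval. Lognormal: location
#' `log(point)`, scale `(log(high) - log(low)) / (2 * 1.96)`. Normal: mean
#' `point`, sd `(high - low) / (2 * 1.96)`. Gamma and beta: method-of-
#' moments match to mean `point` and that same sd (beta requires the
#' moments to be feasible on (0, 1)).
#'
#' @param param A non-fixed [uparam()].
#' @param name Parameter label used in error messages.
#' @return A `dist_spec` list with `family` and the fitted parameters
#'   (`meanlog`/`sdlog`, `mean`/`sd`, `shape`/`rate`, or `shape1`/`shape2`).
#' @export
fit_distribution <- function(param, name = "parameter") {
  if (param$family == "fixed") {
    stop("fit_distribution: '", name, "' is fixed and has no distribution")
  }
  if (param$low >= param$high) {
    stop("fit_distribution: '", name, "' has a degenerate interval [",
         param$low, ", ", param$high, "]")
  }
  m <- param$point
  sd <- (param$high - param$low) / (2 * 1.96)
  spec <- switch(param$family,
    lognormal = {
      if (m <= 0 || param$low <= 0) {
        stop("fit_distribution: lognormal '", name, "' needs positive support")
      }
      list(meanlog = log(m), sdlog = (log(param$high) - log(param$low)) / (2 * 1.96))
    },
    normal = list(mean = m, sd = sd),
    gamma = {
      if (m <= 0) stop("fit_distribution: gamma '", name, "' needs positive mean")
      list(shape = (m / sd)^2, rate = m / sd^2)
    },
    beta = {
      if (m <= 0 || m >= 1 || sd^2 >= m * (1 - m)) {
        stop("fit_distribution: beta moments infeasible for '", name,
             "' (mean ", m, ", sd ", sd, ")")
      }
      nu <- m * (1 - m) / sd^2 - 1
      list(shape1 = m * nu, shape2 = (1 - m) * nu)
    }
  )
  structure(c(list(family = param$family, name = name), spec),
            class = "dist_spec")
}

#' Sample from a fitted distribution
#'
#' @param spec `dist_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  switch(spec$family,
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    normal    = stats::rnorm(n, spec$mean, spec$sd),
    gamma     = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    beta      = stats::rbeta(n, spec$shape1, spec$shape2)
  )
}

# Bounds a sampled value must respect for the model to accept it.
.sample_bounds <- function(name) {
  if (startsWith(name, "utilities.")) c(0, 1) else c(0, Inf)
}

#' Default tornado parameter list
#'
#' Every uncertain parameter with a non-degenerate range that enters the
#' base-case computation, plus three linked/structural rows: the baseline
#' composite event rate (components rescaled proportionally), the per-dose
#' inclisiran price (year-1 and subsequent-year annual costs move
#' together), and the discount rate (varied 0% to 5%).
#'
#' @param p Validated `ascvd_params` object.
#' @return Character vector of parameter labels accepted by [run_owsa()].
#' @export
owsa_default_params <- function(p) {
  tab <- param_table(p)
  used <- tab$name[tab$family != "fixed" & tab$low < tab$high]
  # not in the base-case computation: the composite-MACE rate ratio and the
  # percentage LDL-C reduction (the absolute reduction drives the model)
  used <- setdiff(used, c("effects.rr_mace", "effects.ldl_reduction_pct",
                          "costs.inclisiran_year1", "costs.inclisiran_later"))
  c(used, "baseline.composite", "inclisiran_price_per_dose",
    "settings.discount_rate")
}

# Range for an OWSA label; special labels handled explicitly.
.owsa_range <- function(p, name) {
  if (name == "inclisiran_price_per_dose") {
    return(c(low = 2790 * 0.8, high = 2790))
  }
  if (name == "settings.discount_rate") {
    return(c(low = 0, high = 0.05))
  }
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(p[[parts[1]]][[parts[2]]])) {
    stop("run_owsa: unknown parameter '", name, "'")
  }
  x <- p[[parts[1]]][[parts[2]]]
  c(low = x$low, high = x$high)
}

#' Apply a one-way parameter value, handling linked parameters
#'
#' @param p `ascvd_params` object.
#' @param name Parameter label as in [owsa_default_params()].
#' @param value Value to set.
#' @return Modified parameter object.
#' @export
owsa_set <- function(p, name, value) {
  if (name == "inclisiran_price_per_dose") {
    p <- set_param(p, "costs.inclisiran_year1", annual_drug_cost(value, 5, 3))
    p <- set_param(p, "costs.inclisiran_later", annual_drug_cost(value, 5, 2))
    return(p)
  }
  if (name == "baseline.composite") {
    # scale the component rates proportionally with the composite
    f <- value / p$baseline$composite$point
    p <- set_param(p, "baseline.composite", value)
    for (cmp in c("mi", "is_", "cv_death")) {
      p <- set_param(p, paste0("baseline.", cmp),
                     p$baseline[[cmp]]$point * f)
    }
    return(p)
  }
  set_param(p, name, value)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs both arms with each parameter at its lower and upper bound, all
#' other inputs at base case, and records the two ICERs. Output is sorted
#' by descending ICER spread (ties broken alphabetically), ready for a
#' tornado diagram.
#'
#' @param p Validated `ascvd_params` object.
#' @param lt `life_table`.
#' @param param_list Labels to vary; defaults to [owsa_default_params()].
#' @return `data.frame` with columns `parameter`, `low_value`,
#'   `high_value`, `icer_low`, `icer_high`, `spread`, plus the base ICER as
#'   attribute `"base_icer"`.
#' @export
run_owsa <- function(p, lt, param_list = owsa_default_params(p)) {
  base <- run_base_case(p, lt)
  rows <- lapply(param_list, function(name) {
    rg <- .owsa_range(p, name)
    icers <- vapply(rg, function(v) {
      run_base_case(owsa_set(p, name, v), lt)$icer
    }, numeric(1))
    data.frame(parameter = name, low_value = rg[["low"]],
               high_value = rg[["high"]],
               icer_low = icers[[1]], icer_high = icers[[2]],
               spread = abs(icers[[2]] - icers[[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter independently from its fitted
#' distribution, re-runs both arms per draw, and records the incremental
#' cost/QALY pair. Sampled values violating model bounds (e.g. a utility
#' above 1) are redrawn, capped at 100 attempts; the redraw count is
#' returned. Reproducible given `seed`.
#'
#' @param p Validated `ascvd_params` object.
#' @param lt `life_table`.
#' @param draws Number of Monte Carlo draws (default from settings).
#' @param seed RNG seed (default from settings).
#' @return A `psa_draws` list: `draws` (draws x parameters data frame),
#'   `results` (`inc_cost`, `inc_qaly` per draw), `seed`, `n_resampled`.
#' @export
run_psa <- function(p, lt, draws = p$settings$psa_draws,
                    seed = p$settings$rng_seed) {
  stopifnot(draws >= 1)
  tab <- param_table(p)
  tab <- tab[tab$family != "fixed" & tab$low < tab$high, ]
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    fit_distribution(uparam(tab$point[i], tab$low[i], tab$high[i],
                            tab$family[i]), tab$name[i])
  })
  names(specs) <- tab$name

  set.seed(seed)
  n_resampled <- 0L
  draw_mat <- matrix(NA_real_, draws, nrow(tab),
                     dimnames = list(NULL, tab$name))
  for (j in seq_along(specs)) {
    b <- .sample_bounds(tab$name[j])
    x <- sample_distribution(specs[[j]], draws)
    bad <- which(x < b[1] | x > b[2])
    tries <- 0L
    while (length(bad) && tries < 100L) {
      n_resampled <- n_resampled + length(bad)
      x[bad] <- sample_distribution(specs[[j]], length(bad))
      bad <- which(x < b[1] | x > b[2])
      tries <- tries + 1L
    }
    if (length(bad)) x[bad] <- pmin(pmax(x[bad], b[1]), b[2])
    draw_mat[, j] <- x
  }

  inc_cost <- inc_qaly <- numeric(draws)
  for (i in seq_len(draws)) {
    pi <- p
    for (j in seq_len(ncol(draw_mat))) {
      pi <- set_param(pi, colnames(draw_mat)[j], draw_mat[i, j])
    }
    res <- run_base_case(pi, lt)
    inc_cost[i] <- res$inc_cost
    inc_qaly[i] <- res$inc_qaly
  }

  structure(list(
    draws = as.data.frame(draw_mat),
    results = data.frame(inc_cost = inc_cost, inc_qaly = inc_qaly),
    seed = seed, n_resampled = n_resampled
  ), class = "psa_draws")
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %d resampled values)\n",
              nrow(x$results), x$seed, x$n_resampled))
  cat(sprintf("  mean incremental cost: %.2f\n", mean(x$results$inc_cost)))
  cat(sprintf("  mean incremental QALY: %.4f\n", mean(x$results$inc_qaly)))
  invisible(x)
}

#' Probability of cost-effectiveness at one threshold
#'
#' Fraction of draws with positive net monetary benefit,
#' `wtp * inc_qaly - inc_cost > 0` (strict inequality; the NMB criterion
#' handles dominant draws without sign ambiguity).
#'
#' @param psa `psa_draws` object.
#' @param wtp Threshold (CNY/QALY).
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp) {
  mean(wtp * psa$results$inc_qaly - psa$results$inc_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa `psa_draws` object with at least one draw.
#' @param wtp_grid Thresholds to evaluate (default 0 to 2x the packaged
#'   WTP in 101 steps).
#' @return `data.frame` with columns `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2 * 191498, length.out = 101)) {
  if (!length(wtp_grid)) stop("ceac: empty WTP grid")
  if (!nrow(psa$results)) stop("ceac: no PSA draws")
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(l) {
      prob_cost_effective(psa, l)
    }, numeric(1))
  )
}

#' Time-horizon scenario sweep
#'
#' Re-runs the base case at each horizon, all other inputs unchanged.
#'
#' @param p Validated `ascvd_params` object.
#' @param lt `life_table`.
#' @param horizons Integer vector of horizons in years.
#' @return `data.frame` with columns `horizon`, `inc_cost`, `inc_qaly`,
#'   `icer`.
#' @export
horizon_sweep <- function(p, lt, horizons = seq(5, 30, by = 5)) {
  stopifnot(all(horizons >= 1))
  rows <- lapply(horizons, function(h) {
    ph <- p
    ph$settings$horizon_years <- as.integer(h)
    res <- run_base_case(ph, lt)
    data.frame(horizon = h, inc_cost = res$inc_cost,
               inc_qaly = res$inc_qaly, icer = res$icer)
  })
  do.call(rbind, rows)
}
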