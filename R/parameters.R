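#' Model parameters
#'
#' The complete input set for one model run: patient characteristics,
#' baseline event rates, treatment-effect parameters, costs, utilities and
#' run settings, each uncertain quantity carried as a point estimate with a
#' range and a sampling-distribution family. The packaged defaults are the
#' published base-case inputs for inclisiran added to statin therapy in
#' Chinese ASCVD patients (2024 CNY throughout).
#'
#' @name parameters
NULL

.families <- c("gamma", "lognormal", "normal", "beta", "fixed")

#' Construct an uncertain parameter
#'
#' A point estimate with lower/upper bounds and the distribution family used
#' for probabilistic sampling. Ranges are interpreted as 95% intervals where
#' a CI was published and as plain bounds otherwise; `family = "fixed"`
#' excludes the parameter from probabilistic sampling.
#'
#' @param point Point estimate.
#' @param low,high Lower and upper bounds, `low <= point <= high`.
#' @param family One of `"gamma"`, `"lognormal"`, `"normal"`, `"beta"`,
#'   `"fixed"`.
#' @return An object of class `uparam`.
#' @export
uparam <- function(point, low = point, high = point, family = "fixed") {
  if (!is.numeric(point) || length(point) != 1 || !is.finite(point)) {
    stop("uparam: 'point' must be a finite number")
  }
  if (!(family %in% .families)) {
    stop("uparam: unknown distribution family '", family, "'")
  }
  if (low > point + 1e-12 || high < point - 1e-12) {
    stop("uparam: bounds must satisfy low <= point <= high (got ",
         low, " <= ", point, " <= ", high, ")")
  }
  structure(list(point = unname(point), low = unname(low),
                 high = unname(high), family = family),
            class = "uparam")
}

#' @export
print.uparam <- function(x, ...) {
  cat(sprintf("%g [%g, %g] (%s)\n", x$point, x$low, x$high, x$family))
  invisible(x)
}

#' Annual drug acquisition cost
#'
#' Cost of a dosing schedule: `doses * (price_per_dose + fee_per_dose)`.
#' The modelled regimen is 3 doses in year 1 (days 1, 90, 270) and 2 doses
#' per year thereafter, each with a flat administration fee.
#'
#' @param price_per_dose Drug price per dose (CNY), >= 0.
#' @param fee_per_dose Injection/administration fee per dose (CNY), >= 0.
#' @param doses Number of doses in the year, >= 0.
#' @return Annual cost in CNY.
#' @examples
#' annual_drug_cost(2790, 5, 3) # year 1: 8385
#' annual_drug_cost(2790, 5, 2) # subsequent years: 5590
#' @export
annual_drug_cost <- function(price_per_dose, fee_per_dose, doses) {
  if (any(c(price_per_dose, fee_per_dose, doses) < 0)) {
    stop("annual_drug_cost: all inputs must be non-negative")
  }
  doses * (price_per_dose + fee_per_dose)
}

#' Base-case model parameters
#'
#' Returns the packaged base-case parameterization: ORION-18 patient
#' characteristics; MarketScan-derived, Asian-adjusted baseline event rates;
#' CTTC rate ratios per 1 mmol/L LDL-C reduction; recurrent-event and
#' post-event-mortality hazard ratios; 2024 CNY costs (inclisiran at the
#' negotiated CNY 2,790/dose plus a CNY 5 injection fee); time-trade-off
#' utilities; and run settings (30 annual cycles, 4.5% discount, WTP
#' CNY 191,498/QALY, half-cycle correction, 1,000 PSA draws).
#'
#' @return An object of class `ascvd_params` (nested named lists; see
#'   [validate_parameters()] for the schema).
#' @export
default_parameters <- function() {
  p <- list(
    population = list(
      mean_age       = 59.5,
      male_fraction  = 0.747,
      mean_ldl       = 109.0,   # mg/dL
      statin_fraction = 0.977
    ),
    baseline = list(  # events per 100 patient-years; fixed in PSA
      composite = uparam(6.66, 5.33, 7.99, "fixed"),
      mi        = uparam(3.53, 2.82, 4.24, "fixed"),
      is_       = uparam(1.72, 1.38, 2.06, "fixed"),
      cv_death  = uparam(0.70, 0.56, 0.84, "fixed")
    ),
    effects = list(
      rr_mace      = uparam(0.78, 0.76, 0.80, "lognormal"),
      rr_mi        = uparam(0.73, 0.70, 0.76, "lognormal"),
      rr_is        = uparam(0.79, 0.74, 0.85, "lognormal"),
      rr_cv_death  = uparam(0.84, 0.80, 0.88, "lognormal"),
      rr_all_cause = uparam(0.90, 0.87, 0.93, "lognormal"),
      ldl_reduction_pct = uparam(57.2, 51.3, 63.1, "normal"),
      ldl_reduction_abs = uparam(1.56, 1.50, 1.63, "normal"),  # mmol/L
      hr_recurrent_mi     = uparam(1.13, 1.04, 1.22, "lognormal"),
      hr_recurrent_is     = uparam(1.13, 0.99, 1.30, "lognormal"),
      hr_post_event_death = uparam(1.31, 1.15, 1.49, "lognormal")
    ),
    costs = list(  # 2024 CNY per year; death costs are one-off
      inclisiran_year1 = uparam(8385.0, 6708.0, 8385.0, "gamma"),
      inclisiran_later = uparam(5590.0, 4472.0, 5590.0, "gamma"),
      statin_annual    = uparam(3645.0, 2916.0, 3645.0, "gamma"),
      mi_year1         = uparam(23567.4, 18853.9, 28280.9, "gamma"),
      mi_later         = uparam(3885.2, 3108.2, 4662.2, "gamma"),
      is_year1         = uparam(10005.7, 8004.6, 12006.8, "gamma"),
      is_later         = uparam(4398.0, 3518.4, 5277.6, "gamma"),
      cv_death         = uparam(15212.0, 12169.6, 18254.4, "gamma"),
      non_cv_death     = uparam(6044.1, 4835.3, 7252.9, "gamma")
    ),
    utilities = list(
      baseline_ascvd = uparam(0.824, 0.800, 0.848, "beta"),
      mi_year1       = uparam(0.672, 0.625, 0.719, "beta"),
      mi_later       = uparam(0.824, 0.800, 0.848, "beta"),
      is_year1       = uparam(0.327, 0.264, 0.390, "beta"),
      is_later       = uparam(0.524, 0.472, 0.576, "beta")
    ),
    settings = list(
      horizon_years = 30L,      # lifetime horizon: age 59.5 -> 89.5
      discount_rate = 0.045,
      wtp           = 191498,   # 2 x 2024 per-capita GDP (CNY/QALY)
      half_cycle    = TRUE,
      psa_draws     = 1000L,
      rng_seed      = 1234L,
      # apply the all-cause-mortality rate ratio to the background
      # (non-CV) death channel in the treated arm
      apply_all_cause_effect = TRUE
    )
  )
  class(p) <- "ascvd_params"
  validate_parameters(p)
}

.check_range <- function(x, name, lo = -Inf, hi = Inf) {
  vals <- c(x$low, x$point, x$high)
  if (any(vals < lo) || any(vals > hi)) {
    stop("parameter validation: '", name, "' outside [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a model-parameter object
#'
#' Checks structural completeness (every required field present and of class
#' `uparam` where applicable) and all domain invariants: fractions in
#' `[0, 1]`, utilities in `[0, 1]`, non-negative rates and costs, positive
#' ratios, composite rate at least as large as each component, and
#' well-formed run settings. Errors name the offending field.
#'
#' @param p An `ascvd_params` object (or plain nested list with the same
#'   shape).
#' @return The validated object, invisibly classed as `ascvd_params`.
#' @export
validate_parameters <- function(p) {
  sections <- list(
    population = c("mean_age", "male_fraction", "mean_ldl", "statin_fraction"),
    baseline   = c("composite", "mi", "is_", "cv_death"),
    effects    = c("rr_mace", "rr_mi", "rr_is", "rr_cv_death", "rr_all_cause",
                   "ldl_reduction_pct", "ldl_reduction_abs",
                   "hr_recurrent_mi", "hr_recurrent_is", "hr_post_event_death"),
    costs      = c("inclisiran_year1", "inclisiran_later", "statin_annual",
                   "mi_year1", "mi_later", "is_year1", "is_later",
                   "cv_death", "non_cv_death"),
    utilities  = c("baseline_ascvd", "mi_year1", "mi_later",
                   "is_year1", "is_later"),
    settings   = c("horizon_years", "discount_rate", "wtp", "half_cycle",
                   "psa_draws", "rng_seed", "apply_all_cause_effect")
  )
  for (sec in names(sections)) {
    if (is.null(p[[sec]])) stop("parameter validation: missing section '", sec, "'")
    missing <- setdiff(sections[[sec]], names(p[[sec]]))
    if (length(missing)) {
      stop("parameter validation: missing field(s) in '", sec, "': ",
           paste(missing, collapse = ", "))
    }
  }

  pop <- p$population
  if (pop$mean_age <= 0) stop("parameter validation: population.mean_age must be > 0")
  if (pop$mean_ldl <= 0) stop("parameter validation: population.mean_ldl must be > 0")
  for (f in c("male_fraction", "statin_fraction")) {
    if (pop[[f]] < 0 || pop[[f]] > 1) {
      stop("parameter validation: population.", f, " must be in [0, 1]")
    }
  }

  for (sec in c("baseline", "effects", "costs", "utilities")) {
    for (f in names(p[[sec]])) {
      x <- p[[sec]][[f]]
      if (!inherits(x, "uparam")) {
        if (is.list(x) && all(c("point", "low", "high", "family") %in% names(x))) {
          p[[sec]][[f]] <- x <- uparam(x$point, x$low, x$high, x$family)
        } else {
          stop("parameter validation: '", sec, ".", f, "' is not an uncertain parameter")
        }
      }
    }
  }

  for (f in names(p$baseline)) .check_range(p$baseline[[f]], paste0("baseline.", f), lo = 0)
  if (p$baseline$composite$point <
      max(p$baseline$mi$point, p$baseline$is_$point, p$baseline$cv_death$point)) {
    stop("parameter validation: baseline.composite must be >= each component rate")
  }
  for (f in names(p$effects)) {
    lo <- if (startsWith(f, "ldl_")) 0 else 1e-12
    .check_range(p$effects[[f]], paste0("effects.", f), lo = lo)
  }
  for (f in names(p$costs)) .check_range(p$costs[[f]], paste0("costs.", f), lo = 0)
  for (f in names(p$utilities)) {
    .check_range(p$utilities[[f]], paste0("utilities.", f), lo = 0, hi = 1)
  }

  s <- p$settings
  if (s$horizon_years < 1) stop("parameter validation: settings.horizon_years must be >= 1")
  if (s$discount_rate < 0 || s$discount_rate > 1) {
    stop("parameter validation: settings.discount_rate must be in [0, 1]")
  }
  if (s$psa_draws < 1) stop("parameter validation: settings.psa_draws must be >= 1")
  if (!is.logical(s$half_cycle)) stop("parameter validation: settings.half_cycle must be logical")

  class(p) <- "ascvd_params"
  invisible(p)
}

.uparam_to_list <- function(x) {
  list(point = x$point, low = x$low, high = x$high, family = x$family)
}

#' Save model parameters to a YAML configuration file
#'
#' Writes the full nested parameter set. [load_parameters()] of the written
#' file reproduces every field, so save/load round-trips exactly on the
#' stored decimal representation.
#'
#' @param p Validated `ascvd_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(p, path) {
  p <- validate_parameters(p)
  out <- list(
    population = p$population,
    baseline   = lapply(p$baseline, .uparam_to_list),
    effects    = lapply(p$effects, .uparam_to_list),
    costs      = lapply(p$costs, .uparam_to_list),
    utilities  = lapply(p$utilities, .uparam_to_list),
    settings   = p$settings
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a (possibly partial) YAML document and merges it onto the packaged
#' base case: any field not present in the file keeps its default value.
#' Uncertain parameters may be given either as a scalar (point estimate,
#' keeping the default range and family) or as a mapping with keys `point`,
#' `low`, `high`, `family`. The merged object is fully validated.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `ascvd_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("load_parameters: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("load_parameters: config must be a YAML mapping")
  known <- c("population", "baseline", "effects", "costs", "utilities", "settings")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("load_parameters: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }

  p <- default_parameters()
  for (sec in intersect(names(cfg), known)) {
    bad <- setdiff(names(cfg[[sec]]), names(p[[sec]]))
    if (length(bad)) {
      stop("load_parameters: unknown field(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    for (f in names(cfg[[sec]])) {
      v <- cfg[[sec]][[f]]
      cur <- p[[sec]][[f]]
      if (inherits(cur, "uparam")) {
        if (is.numeric(v) && length(v) == 1) {
          p[[sec]][[f]] <- uparam(v, min(v, cur$low), max(v, cur$high), cur$family)
        } else if (is.list(v)) {
          p[[sec]][[f]] <- uparam(
            point  = if (!is.null(v$point)) v$point else cur$point,
            low    = if (!is.null(v$low)) v$low else v$point,
            high   = if (!is.null(v$high)) v$high else v$point,
            family = if (!is.null(v$family)) v$family else cur$family
          )
        } else {
          stop("load_parameters: field '", sec, ".", f,
               "' must be a number or a point/low/high/family mapping")
        }
      } else {
        p[[sec]][[f]] <- v
      }
    }
  }
  tryCatch(validate_parameters(p),
           error = function(e) stop("load_parameters: ", conditionMessage(e), call. = FALSE))
}

#' Flat table of uncertain parameters
#'
#' Enumerates every uncertain parameter (sections `baseline`, `effects`,
#' `costs`, `utilities`) in `section.field` notation with its point, bounds
#' and distribution family. Used by the one-way and probabilistic
#' sensitivity machinery.
#'
#' @param p Validated `ascvd_params` object.
#' @return `data.frame` with columns `name`, `point`, `low`, `high`, `family`.
#' @export
param_table <- function(p) {
  rows <- list()
  for (sec in c("baseline", "effects", "costs", "utilities")) {
    for (f in names(p[[sec]])) {
      x <- p[[sec]][[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(sec, ".", f), point = x$point, low = x$low,
        high = x$high, family = x$family, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Set one parameter's point value by flat name
#'
#' @param p `ascvd_params` object.
#' @param name Parameter in `section.field` notation (e.g.
#'   `"effects.rr_all_cause"`), or `"settings.discount_rate"`.
#' @param value New point value. Bounds are widened if needed so the
#'   object stays valid; the family is kept.
#' @return Modified `ascvd_params` object.
#' @export
set_param <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(p[[parts[1]]]) ||
      !(parts[2] %in% names(p[[parts[1]]]))) {
    stop("set_param: unknown parameter '", name, "'")
  }
  sec <- parts[1]; f <- parts[2]
  cur <- p[[sec]][[f]]
  if (inherits(cur, "uparam")) {
    p[[sec]][[f]] <- uparam(value, min(value, cur$low), max(value, cur$high),
                            cur$family)
  } else {
    p[[sec]][[f]] <- value
  }
  p
}
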