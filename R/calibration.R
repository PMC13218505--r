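#' Rate calibration arithmetic
#'
#' Event-rate calibration for the cohort model: ethnicity adjustment of a
#' source-population event rate, combined age/LDL-C adjustment, treatment
#' effect mapping via a rate ratio per 1 mmol/L of LDL-C lowering, splitting
#' of a composite event rate into its components, and the exponential
#' rate/probability conversion used to build annual transition probabilities.
#'
#' All rates expressed "per 100 person-years" are handled on that scale by
#' the adjustment functions; `rate_to_prob()`/`prob_to_rate()` work on the
#' per-person-year scale. Arithmetic is carried unrounded; rounding happens
#' only at report time.
#'
#' @name calibration
NULL

#' Adjust an event rate for a higher-risk ethnic group
#'
#' Multiplies a baseline composite cardiovascular event rate by a hazard
#' ratio capturing the excess risk of the target ethnic group relative to
#' the source cohort (e.g. Asian vs. US claims-database populations).
#'
#' @param r0 Baseline event rate (events per 100 person-years), >= 0.
#' @param hr Hazard ratio for the target group, > 0.
#' @return Adjusted rate on the same scale as `r0`.
#' @examples
#' ethnicity_adjust(6.40, 1.04) # 6.656
#' @export
ethnicity_adjust <- function(r0, hr) {
  stopifnot(is.numeric(r0), is.numeric(hr))
  if (any(r0 < 0)) stop("ethnicity_adjust: rate 'r0' must be non-negative")
  if (any(hr <= 0)) stop("ethnicity_adjust: hazard ratio 'hr' must be positive")
  r0 * hr
}

#' Adjust an event rate for age and LDL-C differences between cohorts
#'
#' Transfers a source-cohort event rate to a target population by
#' exponentiating a per-year-of-age hazard ratio by the age difference and a
#' per-mmol/L rate ratio by the LDL-C difference:
#' `ra = r0 * hr_age^delta_age * rr_ldl^delta_ldl`.
#'
#' @param r0 Source event rate (per 100 person-years), >= 0.
#' @param hr_age Hazard ratio per year of age, > 0.
#' @param delta_age Target minus source mean age (years); may be negative.
#' @param rr_ldl Rate ratio per 1 mmol/L LDL-C reduction, > 0.
#' @param delta_ldl LDL-C difference (mmol/L); may be negative.
#' @return Adjusted rate on the same scale as `r0`.
#' @export
adjust_rate <- function(r0, hr_age, delta_age, rr_ldl, delta_ldl) {
  if (r0 < 0) stop("adjust_rate: rate 'r0' must be non-negative")
  if (hr_age <= 0 || rr_ldl <= 0) {
    stop("adjust_rate: hazard and rate ratios must be positive")
  }
  out <- r0 * hr_age^delta_age * rr_ldl^delta_ldl
  if (!is.finite(out)) stop("adjust_rate: non-finite result from exponentiation")
  out
}

#' Map a baseline rate to an on-treatment rate via LDL-C lowering
#'
#' Applies the rate-ratio-per-mmol/L relationship to the achieved absolute
#' LDL-C reduction: `rtx = r0 * rr^delta_ldl`. With `delta_ldl = 0` (the
#' comparator arm) the baseline rate is returned unchanged.
#'
#' @param r0 Baseline event rate, >= 0 (any rate scale).
#' @param rr Rate ratio per 1 mmol/L LDL-C reduction, > 0.
#' @param delta_ldl Achieved absolute LDL-C reduction (mmol/L), >= 0.
#' @return On-treatment event rate on the scale of `r0`.
#' @examples
#' treated_rate(6.66, 0.78, 1.56)
#' @export
treated_rate <- function(r0, rr, delta_ldl) {
  stopifnot(length(rr) == length(r0) || length(rr) == 1 || length(r0) == 1)
  if (any(r0 < 0)) stop("treated_rate: rate 'r0' must be non-negative")
  if (any(rr <= 0)) stop("treated_rate: rate ratio 'rr' must be positive")
  if (any(delta_ldl < 0)) stop("treated_rate: 'delta_ldl' must be non-negative")
  r0 * rr^delta_ldl
}

#' Split a composite event rate into component event rates
#'
#' Disaggregates a composite cardiovascular event rate (MI + IS + CV death)
#' into event-specific rates using fixed outcome fractions, as reported in
#' pooled trial meta-analyses. A residual (fractions summing to < 1) is
#' permitted and simply left unallocated.
#'
#' @param composite Composite event rate (per 100 person-years), >= 0.
#' @param frac_mi,frac_is,frac_cv_death Proportions of the composite rate
#'   attributed to myocardial infarction, ischaemic stroke and
#'   cardiovascular death; each in `[0, 1]`, summing to at most 1.
#' @return Named list with elements `composite`, `mi`, `is_`, `cv_death`
#'   (rates per 100 person-years).
#' @export
split_composite <- function(composite, frac_mi, frac_is, frac_cv_death) {
  if (composite < 0) stop("split_composite: composite rate must be non-negative")
  fr <- c(frac_mi, frac_is, frac_cv_death)
  if (any(fr < 0) || any(fr > 1)) {
    stop("split_composite: fractions must lie in [0, 1]")
  }
  if (sum(fr) > 1 + 1e-12) {
    stop("split_composite: fractions sum to more than 1 (",
         format(sum(fr)), ")")
  }
  list(
    composite = composite,
    mi        = composite * frac_mi,
    is_       = composite * frac_is,
    cv_death  = composite * frac_cv_death
  )
}

#' Convert an annual event rate to a transition probability
#'
#' Standard exponential conversion `P = 1 - exp(-r t)` under a constant
#' hazard within the cycle.
#'
#' @param r Event rate per person-year, >= 0. Vectorised.
#' @param t Cycle length in years, > 0 (default 1).
#' @return Transition probability in `[0, 1)`.
#' @export
rate_to_prob <- function(r, t = 1) {
  if (any(r < 0)) stop("rate_to_prob: rate must be non-negative")
  if (any(t <= 0)) stop("rate_to_prob: time must be positive")
  1 - exp(-r * t)
}

#' Convert a transition probability back to an annual rate
#'
#' Inverse of [rate_to_prob()]: `r = -log(1 - p) / t`. Used to convert
#' life-table annual death probabilities to rates before recombination.
#'
#' @param p Probability in `[0, 1)`. Vectorised.
#' @param t Period length in years, > 0 (default 1).
#' @return Rate per person-year.
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) stop("prob_to_rate: probability must be in [0, 1)")
  if (any(t <= 0)) stop("prob_to_rate: time must be positive")
  -log(1 - p) / t
}
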