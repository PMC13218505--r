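#' Life tables
#'
#' Age-indexed all-cause and cardiovascular mortality rates supplying the
#' model's background (non-CV) death channel. The on-disk format is a plain
#' CSV with header `age,all_cause_rate,cv_rate`; rates are deaths per
#' person-year as decimals. A national yearbook-derived table can be dropped
#' in directly; for fully self-contained runs a synthetic table with the
#' same statistical shape is generated by [generate_life_table()].
#'
#' @name life_table
NULL

.validate_life_table <- function(lt) {
  need <- c("age", "all_cause_rate", "cv_rate")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns: ", paste(need, collapse = ", "))
  }
  lt <- lt[order(lt$age), need, drop = FALSE]
  if (any(diff(lt$age) <= 0)) stop("life table ages must be strictly increasing")
  if (any(lt$all_cause_rate < 0) || any(lt$cv_rate < 0)) {
    stop("life table rates must be non-negative")
  }
  if (any(lt$cv_rate > lt$all_cause_rate + 1e-12)) {
    stop("life table: cv_rate exceeds all_cause_rate at age ",
         lt$age[which(lt$cv_rate > lt$all_cause_rate + 1e-12)[1]])
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read a life table from CSV
#'
#' @param path CSV file with header `age,all_cause_rate,cv_rate` (rates per
#'   person-year).
#' @return A validated `life_table` data frame, sorted by age.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("read_life_table: file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_life_table(lt)
}

#' Write a life table to CSV
#'
#' @param lt A `life_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  lt <- .validate_life_table(as.data.frame(lt))
  df <- as.data.frame(lapply(lt, function(col) format(col, digits = 15, trim = TRUE,
                                                      scientific = FALSE)))
  names(df) <- names(lt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up a life-table row by (integer) age
#'
#' Annual tables, no interpolation: the row for `floor(age)` is used.
#'
#' @param lt `life_table` data frame.
#' @param age Age in years.
#' @return One-row data frame.
#' @keywords internal
life_table_row <- function(lt, age) {
  a <- floor(age)
  i <- match(a, lt$age)
  if (is.na(i)) stop("life table does not cover age ", a)
  lt[i, , drop = FALSE]
}

#' Split all-cause mortality into CV and non-CV rates at an age
#'
#' Background non-cardiovascular mortality is obtained by subtracting the
#' cause-specific CV rate from the all-cause rate; the model's own CV-death
#' channel supplies cardiovascular death, so only the non-CV remainder is
#' used as background mortality (avoiding double counting).
#'
#' @param lt `life_table` data frame.
#' @param age Age in years (row for `floor(age)` is used).
#' @return Named list with `cv_rate` and `non_cv_rate` (per person-year).
#' @export
mortality_split <- function(lt, age) {
  row <- life_table_row(lt, age)
  non_cv <- row$all_cause_rate - row$cv_rate
  if (non_cv < 0) stop("mortality_split: cv_rate exceeds all_cause_rate at age ", floor(age))
  list(cv_rate = row$cv_rate, non_cv_rate = non_cv)
}

#' Default synthetic mortality parameters
#'
#' Gompertz-Makeham parameters and a CV-death fraction chosen to emulate
#' the qualitative shape of contemporary Chinese national mortality
#' schedules: a small age-constant background hazard, an exponentially
#' age-increasing component, and a cardiovascular share of deaths that
#' rises with age.
#'
#' @return Named list with `makeham`, `gompertz_a`, `gompertz_b`, and
#'   `cv_fraction_fn` (a function of age returning the CV share of deaths).
#' @export
default_mortality_params <- function() {
  list(
    makeham    = 5e-4,   # background hazard per year
    gompertz_a = 1.5e-5, # hazard scale at age 0
    gompertz_b = 0.100,  # per-year log-hazard slope
    cv_fraction_fn = function(age) {
      pmin(0.55, pmax(0.25, 0.25 + 0.004 * (age - 40)))
    }
  )
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' All-cause rate at integer age `x` is `makeham + gompertz_a *
#' exp(gompertz_b * x)`; the CV rate is the all-cause rate times the
#' age-specific CV fraction. The output passes the same validation as the
#' CSV reader, so generator output and reader round-trip exactly.
#'
#' @param p Parameter list as returned by [default_mortality_params()].
#' @param age_min,age_max Integer age span (inclusive), `age_min < age_max`.
#' @return A `life_table` data frame.
#' @export
generate_life_table <- function(p = default_mortality_params(),
                                age_min = 40, age_max = 100) {
  if (age_min >= age_max) stop("generate_life_table: age_min must be < age_max")
  if (p$makeham < 0 || p$gompertz_a < 0) {
    stop("generate_life_table: hazards must be non-negative")
  }
  age <- seq(as.integer(age_min), as.integer(age_max))
  all_cause <- p$makeham + p$gompertz_a * exp(p$gompertz_b * age)
  if (any(all_cause > 1)) {
    stop("generate_life_table: parameters give a rate > 1/year before age ",
         age_max, " (first at age ", age[which(all_cause > 1)[1]], ")")
  }
  cvf <- p$cv_fraction_fn(age)
  if (any(cvf < 0) || any(cvf > 1)) {
    stop("generate_life_table: cv_fraction_fn must return values in [0, 1]")
  }
  .validate_life_table(data.frame(
    age = age, all_cause_rate = all_cause, cv_rate = all_cause * cvf
  ))
}

#' Discrete-time life expectancy from a life table
#'
#' Remaining life expectancy at `age` by summing annual survival under the
#' exponential within-year assumption (used as a sanity oracle for the
#' synthetic generator, not by the cohort engine).
#'
#' @param lt `life_table` data frame.
#' @param age Starting age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age) {
  ages <- lt$age[lt$age >= floor(age)]
  q <- rate_to_prob(lt$all_cause_rate[lt$age >= floor(age)])
  surv <- cumprod(1 - q)
  # terminal tail: constant hazard beyond the last tabulated age
  tail_rate <- lt$all_cause_rate[nrow(lt)]
  sum(surv) + surv[length(surv)] * (1 / tail_rate) * exp(-tail_rate)
}
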