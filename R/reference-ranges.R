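#' @title Physiological reference ranges
#' @description
#' Physiological standard-value ranges for a concentration measure are the
#' mean plus/minus two sample standard deviations, [mu - 2*sigma,
#' mu + 2*sigma]. Ranges are stratified by sex when the gender comparison on
#' that measure is significant (in practice: the absolute measure), pooled
#' otherwise (the blood-normalized measures). Blood-normalized ranges apply
#' at the cohort's reference age and shift linearly with age by the fitted
#' regression slope.
#' @name reference-ranges
NULL

MEASURES <- c("absolute", "pv_normalized", "aorta_normalized", "mixed_normalized")
STRATA   <- c("all", "male", "female")

new_reference_range <- function(measure, stratum, mean, sd,
                                slope_per_year = 0, reference_age = NA_real_,
                                n = NA_integer_, age_span = NULL) {
  if (sd < 0) stop("sd must be >= 0")
  structure(list(
    measure        = measure,
    stratum        = stratum,
    mean           = mean,
    sd             = sd,
    lower          = mean - 2 * sd,
    upper          = mean + 2 * sd,
    slope_per_year = slope_per_year,
    reference_age  = reference_age,
    n              = n,
    age_span       = age_span
  ), class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range> %s / %s: [%.3f, %.3f] mg/ml (mean %.3f, sd %.3f)\n",
              x$measure, x$stratum, x$lower, x$upper, x$mean, x$sd))
  if (is.finite(x$reference_age) && x$slope_per_year != 0)
    cat(sprintf("  at reference age %g y; slope %.4f mg/ml per year\n",
                x$reference_age, x$slope_per_year))
  invisible(x)
}

#' Reference range from per-patient values
#'
#' Mean and sample standard deviation (n - 1 denominator) at full precision;
#' bounds exactly mean -/+ 2 * sd. Rounding is applied only at report time.
#'
#' @param values per-patient concentrations in mg/ml, n >= 2, finite.
#' @param measure one of `"absolute"`, `"pv_normalized"`,
#'   `"aorta_normalized"`, `"mixed_normalized"`.
#' @param stratum one of `"all"`, `"male"`, `"female"`.
#' @param slope_per_year signed regression slope in mg/ml per year (0 for a
#'   range that is not age-adjusted).
#' @param reference_age age in years at which the range applies unadjusted.
#' @param age_span observed cohort age range, used to flag extrapolation.
#' @return a `reference_range`.
#' @export
reference_range <- function(values, measure = "absolute", stratum = "all",
                            slope_per_year = 0, reference_age = NA_real_,
                            age_span = NULL) {
  measure <- match.arg(measure, MEASURES)
  stratum <- match.arg(stratum, STRATA)
  if (length(values) < 2) stop("reference range requires n >= 2")
  if (any(!is.finite(values))) stop("values must be finite")
  new_reference_range(measure, stratum,
                      mean = mean(values), sd = stats::sd(values),
                      slope_per_year = slope_per_year,
                      reference_age = reference_age,
                      n = length(values), age_span = age_span)
}

#' Reference range from printed summary moments
#'
#' Constructs the mu -/+ 2*sigma interval directly from a (mean, sd) pair,
#' e.g. to reproduce published ranges from published summary statistics.
#'
#' @param mean,sd summary moments in mg/ml.
#' @inheritParams reference_range
#' @return a `reference_range`.
#' @export
reference_range_from_moments <- function(mean, sd, measure = "absolute",
                                         stratum = "all", slope_per_year = 0,
                                         reference_age = NA_real_) {
  measure <- match.arg(measure, MEASURES)
  stratum <- match.arg(stratum, STRATA)
  new_reference_range(measure, stratum, mean = mean, sd = sd,
                      slope_per_year = slope_per_year,
                      reference_age = reference_age)
}

#' Stratification plan from a gender test
#'
#' Per-sex strata when the gender comparison is significant (strictly
#' p < alpha; a p-value exactly at alpha pools), one pooled stratum
#' otherwise.
#'
#' @param gender_test a `test_result` from [mann_whitney_gender()] computed
#'   on the same measure.
#' @return character vector of strata: `c("male", "female")` or `"all"`.
#' @export
stratification_policy <- function(gender_test) {
  stopifnot(inherits(gender_test, "test_result"))
  if (gender_test$p_value < gender_test$alpha) c("male", "female") else "all"
}

#' Age-adjust a reference range
#'
#' Shifts both bounds (and the mean) by `slope_per_year * (age -
#' reference_age)`; the width is unchanged. With a negative slope a patient
#' older than the reference age gets a lowered range. Ages outside the
#' cohort's observed span trigger an extrapolation warning, not an error.
#'
#' @param base a `reference_range` with `reference_age` set.
#' @param slope_per_year signed slope in mg/ml per year, typically
#'   `effect$slope` of [simple_linear_regression()] on the same measure.
#' @param age patient age in years.
#' @return the shifted `reference_range`.
#' @export
age_adjusted_range <- function(base, slope_per_year, age) {
  stopifnot(inherits(base, "reference_range"))
  if (!is.finite(base$reference_age))
    stop("base range has no reference_age; cannot age-adjust")
  if (!is.null(base$age_span) &&
      (age < base$age_span[1] || age > base$age_span[2]))
    warning(sprintf("age %g outside the cohort's observed span [%g, %g]: extrapolating",
                    age, base$age_span[1], base$age_span[2]))
  shift <- slope_per_year * (age - base$reference_age)
  out <- base
  out$mean  <- base$mean  + shift
  out$lower <- base$lower + shift
  out$upper <- base$upper + shift
  out$slope_per_year <- slope_per_year
  out$reference_age  <- age
  out
}

#' Tabulate reference ranges
#'
#' @param ranges list of `reference_range` objects.
#' @param digits if non-NULL, report rounding: concentrations to
#'   `digits[1]` decimals (default 3), slopes to `digits[2]` (default 4).
#' @return data.frame with header
#'   `measure,stratum,mean,sd,lower,upper,slope_per_year,reference_age`.
#' @export
range_table <- function(ranges, digits = NULL) {
  df <- do.call(rbind, lapply(ranges, function(r) data.frame(
    measure = r$measure, stratum = r$stratum, mean = r$mean, sd = r$sd,
    lower = r$lower, upper = r$upper, slope_per_year = r$slope_per_year,
    reference_age = r$reference_age, stringsAsFactors = FALSE)))
  if (!is.null(digits)) {
    conc <- c("mean", "sd", "lower", "upper")
    df[conc] <- lapply(df[conc], round, digits = digits[1])
    df$slope_per_year <- round(df$slope_per_year,
                               if (length(digits) > 1) digits[2] else 4)
  }
  df
}
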