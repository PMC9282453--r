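#' @title End-to-end analysis and reporting
#' @description
#' `analyze()` orchestrates the pipeline: validate the cohort, blood-
#' normalize, run the gender comparisons, age correlations and regressions
#' per measure, and construct the stratified, age-adjustable reference
#' ranges. The report carries the summary tables familiar from quantitative
#' liver-iodine studies: per-ROI and per-vessel means and SDs by stratum,
#' per-measure means and SDs, and the range table. All values are kept at
#' full precision; report rounding (3 decimals for concentrations, 4 for
#' slopes) is a pure view applied at write time.
#' @name reporting
NULL

mean_sd_by_stratum <- function(df, cols, sex) {
  strata <- list(all = rep(TRUE, length(sex)),
                 male = sex == "male", female = sex == "female")
  do.call(rbind, lapply(cols, function(col) {
    row <- data.frame(variable = col, stringsAsFactors = FALSE)
    for (s in names(strata)) {
      v <- df[[col]][strata[[s]]]
      row[[paste0(s, "_mean")]] <- mean(v)
      row[[paste0(s, "_sd")]]   <- if (length(v) >= 2) stats::sd(v) else NA_real_
    }
    row
  }))
}

#' Analyze a cohort end to end
#'
#' @param cohort an `iodine_cohort`, or a file path passed to
#'   [read_cohort()].
#' @param alpha significance level for all tests.
#' @param weights hepatic supply weights `(w_pv, w_aorta)`.
#' @param reference_age `"auto"` (the cohort mean age rounded to the nearest
#'   year) or a number of years.
#' @param adjust_absolute logical; also attach the age slope to the absolute
#'   ranges (off by default: the age effect is not detectable on the
#'   absolute scale, so absolute ranges are not age-adjusted).
#' @param reference optional external [blood_reference()] calibration.
#' @return object of class `run_report`.
#' @export
analyze <- function(cohort, alpha = 0.05, weights = DEFAULT_SUPPLY_WEIGHTS,
                    reference_age = "auto", adjust_absolute = FALSE,
                    reference = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "iodine_cohort"))
  rec <- cohort$records
  if (nrow(rec) < 2) stop("analysis requires at least 2 patients")

  norm <- normalize_cohort(cohort, reference = reference, weights = weights)
  measures <- c(absolute = "i_l_abs", pv_normalized = "i_pv_n",
                aorta_normalized = "i_a_n", mixed_normalized = "i_mixed_n")

  age_span <- range(rec$age)
  ref_age <- if (identical(reference_age, "auto"))
    round(mean(rec$age)) else as.numeric(reference_age)

  both_sexes <- all(c("male", "female") %in% rec$sex) &&
    min(table(rec$sex)) >= 2

  gender_tests <- age_tests <- regressions <- list()
  ranges <- list()
  for (m in names(measures)) {
    v <- norm[[measures[m]]]
    gt <- if (both_sexes) mann_whitney_gender(v, rec$sex, alpha) else NULL
    at <- pearson_age(v, rec$age, alpha)
    lr <- simple_linear_regression(v, rec$age, alpha)
    gender_tests[[m]] <- gt
    age_tests[[m]] <- at
    regressions[[m]] <- lr

    # age adjustment only where the age correlation is established:
    # the blood-normalized measures (optionally forced onto absolute)
    slope <- if (m != "absolute" || adjust_absolute) lr$effect$slope else 0
    strata <- if (is.null(gt)) "all" else stratification_policy(gt)
    for (s in strata) {
      keep <- if (s == "all") rep(TRUE, nrow(rec)) else rec$sex == s
      ranges[[paste(m, s, sep = ".")]] <-
        reference_range(v[keep], measure = m, stratum = s,
                        slope_per_year = slope, reference_age = ref_age,
                        age_span = age_span)
    }
  }

  structure(list(
    cohort_summary = list(
      n = nrow(rec),
      n_male = sum(rec$sex == "male"),
      n_female = sum(rec$sex == "female"),
      age_mean = mean(rec$age),
      age_range = age_span,
      n_rejected = nrow(cohort$rejects)
    ),
    roi_table     = mean_sd_by_stratum(rec, ROI_COLUMNS, rec$sex),
    vessel_table  = mean_sd_by_stratum(rec, VESSEL_COLUMNS, rec$sex),
    measure_table = mean_sd_by_stratum(norm, unname(measures), rec$sex),
    normalized    = norm,
    blood_reference = attr(norm, "reference"),
    gender_tests  = gender_tests,
    age_tests     = age_tests,
    regressions   = regressions,
    ranges        = ranges,
    reference_age = ref_age,
    alpha         = alpha,
    weights       = unname(weights),
    provenance    = list(
      source = cohort$metadata$source,
      version = as.character(utils::packageVersion("iodinorm")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("<run_report> n = %d (%d male, %d female), age %.2f y (range %g-%g)\n",
              cs$n, cs$n_male, cs$n_female, cs$age_mean,
              cs$age_range[1], cs$age_range[2]))
  cat("\nPer-measure mean (sd) [mg/ml]:\n")
  mt <- x$measure_table
  for (i in seq_len(nrow(mt)))
    cat(sprintf("  %-14s all %.3f (%.3f)  male %.3f (%.3f)  female %.3f (%.3f)\n",
                mt$variable[i], mt$all_mean[i], mt$all_sd[i],
                mt$male_mean[i], mt$male_sd[i],
                mt$female_mean[i], mt$female_sd[i]))
  cat("\nGender comparisons (Mann-Whitney U):\n")
  for (m in names(x$gender_tests)) {
    t <- x$gender_tests[[m]]
    if (!is.null(t))
      cat(sprintf("  %-17s U = %8.1f  p = %.4g%s\n", m, t$statistic, t$p_value,
                  if (t$significant) " *" else ""))
  }
  cat("\nAge correlations (Pearson) and regression slopes:\n")
  for (m in names(x$age_tests)) {
    t <- x$age_tests[[m]]; l <- x$regressions[[m]]
    cat(sprintf("  %-17s r = %+.3f  R^2 = %.3f  p = %.4g%s  slope = %+.4f mg/ml/yr\n",
                m, t$effect$r, t$effect$r_squared, t$p_value,
                if (t$significant) " *" else "  ", l$effect$slope))
  }
  cat(sprintf("\nReference ranges (mean +/- 2 sd; reference age %g y):\n",
              x$reference_age))
  for (r in x$ranges)
    cat(sprintf("  %-17s %-7s [%6.3f, %6.3f]%s\n", r$measure, r$stratum,
                r$lower, r$upper,
                if (r$slope_per_year != 0)
                  sprintf("  (%+.4f mg/ml per year of age)", r$slope_per_year)
                else ""))
  invisible(x)
}

test_table <- function(report) {
  rows <- list()
  for (m in names(report$age_tests)) {
    gt <- report$gender_tests[[m]]
    if (!is.null(gt))
      rows[[paste0(m, ".gender")]] <- data.frame(
        measure = m, test = "mann_whitney_u", statistic = gt$statistic,
        p_value = gt$p_value, r = NA_real_, r_squared = NA_real_,
        slope = NA_real_, n = sum(gt$n), stringsAsFactors = FALSE)
    at <- report$age_tests[[m]]; lr <- report$regressions[[m]]
    rows[[paste0(m, ".age")]] <- data.frame(
      measure = m, test = "pearson", statistic = at$statistic,
      p_value = at$p_value, r = at$effect$r, r_squared = at$effect$r_squared,
      slope = lr$effect$slope, n = at$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a run report to a directory
#'
#' Emits diff-able comma-separated tables (ROI, vessel and measure summary
#' tables, test results, the rounded range table and its full-precision
#' variant, the normalized per-patient table) plus a structured
#' `summary.json`.
#'
#' @param report a `run_report`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE)

  round3 <- function(df) { num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 3); df }
  w(round3(report$roi_table),     "roi_table.csv")
  w(round3(report$vessel_table),  "vessel_table.csv")
  w(round3(report$measure_table), "measure_table.csv")

  tt <- test_table(report)
  tt$statistic <- round(tt$statistic, 4); tt$p_value <- round(tt$p_value, 6)
  tt$r <- round(tt$r, 4); tt$r_squared <- round(tt$r_squared, 4)
  tt$slope <- round(tt$slope, 4)
  w(tt, "tests.csv")

  w(range_table(report$ranges, digits = c(3, 4)), "ranges.csv")
  w(range_table(report$ranges), "ranges_full_precision.csv")
  write_normalized(report$normalized, file.path(dir, "normalized.csv"))

  summary <- list(
    cohort = report$cohort_summary,
    blood_reference = unclass(report$blood_reference),
    reference_age = report$reference_age,
    alpha = report$alpha,
    weights = report$weights,
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
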