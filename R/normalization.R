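#' @title Blood-normalized liver iodine concentrations
#' @description
#' The absolute liver iodine concentration of a patient is confounded by the
#' patient's circulatory state: hemodynamics, blood volume and cardiac output
#' scale the iodine concentration delivered to the liver through its
#' supplying vessels. Blood normalization removes this confounder by
#' dividing the liver concentration by the same patient's vessel
#' concentration and rescaling by the cohort-average vessel concentration so
#' the result keeps mg/ml units:
#'
#'   I_bn(x) = I_abs(x) / I_blood(x) * mean(I_blood)
#'
#' Three choices of I_blood are supported: the portal vein, the aorta, and
#' the mixed hepatic supply 0.75 * portal_vein + 0.25 * aorta reflecting the
#' approximate 75/25 split of hepatic blood flow between the portal vein and
#' the hepatic artery.
#' @name normalization
NULL

DEFAULT_SUPPLY_WEIGHTS <- c(pv = 0.75, aorta = 0.25)

check_weights <- function(weights) {
  if (length(weights) != 2 || any(!is.finite(weights)) || any(weights < 0))
    stop("supply weights must be two finite non-negative numbers")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("supply weights must sum to 1 (got ", sum(weights), ")")
  invisible(weights)
}

#' Absolute liver iodine concentration
#'
#' Unweighted arithmetic mean of the three parenchymal ROI measurements
#' (liver segments 3, 4b and 7).
#'
#' @param roi_s3,roi_s4b,roi_s7 iodine concentrations in mg/ml (vectorized).
#' @return mean concentration in mg/ml.
#' @export
absolute_liver_iodine <- function(roi_s3, roi_s4b, roi_s7) {
  v <- cbind(roi_s3, roi_s4b, roi_s7)
  if (any(!is.finite(v))) stop("ROI concentrations must be finite")
  if (any(v < 0)) stop("ROI concentrations must be >= 0")
  (roi_s3 + roi_s4b + roi_s7) / 3
}

#' Mixed hepatic blood-supply iodine concentration
#'
#' Weighted combination of portal-vein and aortic concentrations modelling
#' the liver's dual blood supply; defaults to the 75/25 portal/arterial
#' flow split.
#'
#' @param portal_vein,aorta vessel iodine concentrations in mg/ml.
#' @param weights length-2 numeric `(w_pv, w_aorta)`, non-negative, summing
#'   to 1 within 1e-9.
#' @return mixed-supply concentration in mg/ml.
#' @export
mixed_blood_iodine <- function(portal_vein, aorta,
                               weights = DEFAULT_SUPPLY_WEIGHTS) {
  check_weights(weights)
  weights[[1]] * portal_vein + weights[[2]] * aorta
}

#' Cohort-average vessel iodine reference
#'
#' Per-vessel arithmetic means over all cohort patients. The mixed-supply
#' mean is derived by linearity (`w_pv * mean_pv + w_a * mean_aorta`), which
#' equals the mean of the per-patient mixed values exactly.
#'
#' @param cohort an `iodine_cohort` with all vessel values > 0.
#' @param weights supply weights, see [mixed_blood_iodine()].
#' @return object of class `blood_reference` with fields `mean_portal_vein`,
#'   `mean_aorta`, `mean_mixed`, `n_patients`, `weights`, `source`.
#' @export
blood_reference <- function(cohort, weights = DEFAULT_SUPPLY_WEIGHTS) {
  stopifnot(inherits(cohort, "iodine_cohort"))
  check_weights(weights)
  rec <- cohort$records
  if (nrow(rec) == 0) stop("cannot compute a blood reference on an empty cohort")
  if (any(rec$aorta <= 0) || any(rec$portal_vein <= 0))
    stop("all vessel concentrations must be > 0")
  m_pv <- mean(rec$portal_vein)
  m_a  <- mean(rec$aorta)
  structure(list(
    mean_portal_vein = m_pv,
    mean_aorta       = m_a,
    mean_mixed       = weights[[1]] * m_pv + weights[[2]] * m_a,
    n_patients       = nrow(rec),
    weights          = unname(weights),
    source           = "computed_from_cohort"
  ), class = "blood_reference")
}

#' Supply an external blood reference
#'
#' Wraps published cohort-average vessel concentrations so a fixed
#' calibration can be applied prospectively to new patients.
#'
#' @param mean_portal_vein,mean_aorta cohort means in mg/ml, > 0.
#' @param weights supply weights.
#' @param n_patients size of the calibration cohort (informational).
#' @return a `blood_reference` with `source = "externally_supplied"`.
#' @export
external_blood_reference <- function(mean_portal_vein, mean_aorta,
                                     weights = DEFAULT_SUPPLY_WEIGHTS,
                                     n_patients = NA_integer_) {
  check_weights(weights)
  if (mean_portal_vein <= 0 || mean_aorta <= 0)
    stop("reference vessel means must be > 0")
  structure(list(
    mean_portal_vein = mean_portal_vein,
    mean_aorta       = mean_aorta,
    mean_mixed       = weights[[1]] * mean_portal_vein + weights[[2]] * mean_aorta,
    n_patients       = n_patients,
    weights          = unname(weights),
    source           = "externally_supplied"
  ), class = "blood_reference")
}

#' @export
print.blood_reference <- function(x, ...) {
  cat(sprintf(paste0("<blood_reference> (%s, n = %s)\n",
                     "  portal vein %.4f  aorta %.4f  mixed %.4f mg/ml ",
                     "(weights %.2f/%.2f)\n"),
              x$source, x$n_patients, x$mean_portal_vein, x$mean_aorta,
              x$mean_mixed, x$weights[1], x$weights[2]))
  invisible(x)
}

#' Blood-normalize a cohort
#'
#' Computes, per patient, the absolute liver iodine (3-ROI mean), the mixed
#' supply concentration, and the three blood-normalized concentrations
#' (portal-vein-, aorta- and mixed-normalized). By default the vessel
#' reference means are recomputed from the analyzed cohort; an externally
#' supplied [blood_reference()] applies a fixed calibration instead.
#'
#' @param cohort an `iodine_cohort`.
#' @param reference optional `blood_reference`; computed from `cohort` when
#'   `NULL`.
#' @param weights supply weights; must agree with `reference$weights` when a
#'   reference is supplied.
#' @return data.frame of class `normalized_cohort` with columns
#'   `patient_id, i_l_abs, i_mixed_blood, i_pv_n, i_a_n, i_mixed_n` (all
#'   mg/ml, full precision, input order preserved) plus pass-through `age`
#'   and `sex` for downstream statistics.
#' @export
normalize_cohort <- function(cohort, reference = NULL,
                             weights = DEFAULT_SUPPLY_WEIGHTS) {
  stopifnot(inherits(cohort, "iodine_cohort"))
  check_weights(weights)
  if (is.null(reference)) {
    reference <- blood_reference(cohort, weights = weights)
  } else {
    stopifnot(inherits(reference, "blood_reference"))
    if (max(abs(reference$weights - unname(weights))) > 1e-12)
      stop("supply weights disagree with the reference's weights")
  }
  rec <- cohort$records
  if (any(rec$aorta <= 0) || any(rec$portal_vein <= 0))
    stop("all vessel concentrations must be > 0 for normalization")
  abs_liver <- absolute_liver_iodine(rec$roi_s3, rec$roi_s4b, rec$roi_s7)
  mixed     <- mixed_blood_iodine(rec$portal_vein, rec$aorta, weights)
  out <- data.frame(
    patient_id    = rec$patient_id,
    i_l_abs       = abs_liver,
    i_mixed_blood = mixed,
    i_pv_n        = abs_liver / rec$portal_vein * reference$mean_portal_vein,
    i_a_n         = abs_liver / rec$aorta       * reference$mean_aorta,
    i_mixed_n     = abs_liver / mixed           * reference$mean_mixed,
    age           = rec$age,
    sex           = rec$sex,
    stringsAsFactors = FALSE
  )
  attr(out, "reference") <- reference
  class(out) <- c("normalized_cohort", "data.frame")
  out
}

#' Write a normalized-cohort table
#'
#' Canonical comma-separated output with header
#' `patient_id,i_l_abs,i_mixed_blood,i_pv_n,i_a_n,i_mixed_n`, full precision.
#'
#' @param normalized a `normalized_cohort`.
#' @param path output file path.
#' @export
write_normalized <- function(normalized, path) {
  cols <- c("i_l_abs", "i_mixed_blood", "i_pv_n", "i_a_n", "i_mixed_n")
  out <- data.frame(patient_id = normalized$patient_id,
                    stringsAsFactors = FALSE)
  for (col in cols) out[[col]] <- sprintf("%.17g", normalized[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
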