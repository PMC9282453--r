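#' @title Cohort data model and delimited-table I/O
#' @description
#' A cohort is the unit every downstream stage consumes: one row per patient
#' with age, sex, iodine concentration (mg/ml) in three liver ROIs (segments
#' 3, 4b and 7 per the standard placement: two in the right lobe, one in the
#' left), and in the two supplying vessels (abdominal aorta, main portal
#' vein) measured at the level of the coeliac axis in portal venous phase.
#' @name cohort-io
NULL

COHORT_COLUMNS <- c("patient_id", "age", "sex",
                    "roi_s3", "roi_s4b", "roi_s7", "aorta", "portal_vein")
ROI_COLUMNS    <- c("roi_s3", "roi_s4b", "roi_s7")
VESSEL_COLUMNS <- c("aorta", "portal_vein")

#' Normalize sex labels to the male/female factor
#'
#' Accepts `"M"`, `"F"`, `"male"`, `"female"` case-insensitively; anything
#' else maps to `NA` (and is rejected by validation).
#'
#' @param x character vector of raw sex labels.
#' @return factor with levels `c("male", "female")`.
#' @export
normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("m", "male")]   <- "male"
  out[key %in% c("f", "female")] <- "female"
  factor(out, levels = c("male", "female"))
}

validate_cohort_rows <- function(df, age_range = c(0, 120)) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(i, msg) reasons[[i]] <<- c(reasons[[i]], msg)

  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  vals <- lapply(c("age", ROI_COLUMNS, VESSEL_COLUMNS), num)
  names(vals) <- c("age", ROI_COLUMNS, VESSEL_COLUMNS)
  sex <- normalize_sex(df$sex)

  for (i in seq_len(n)) {
    if (is.na(df$patient_id[i]) || !nzchar(trimws(df$patient_id[i])))
      add(i, "missing patient_id")
    if (is.na(sex[i])) add(i, "unrecognized sex label")
    for (col in c("age", ROI_COLUMNS, VESSEL_COLUMNS)) {
      v <- vals[[col]][i]
      if (is.na(v) || !is.finite(v)) {
        add(i, sprintf("non-numeric %s", col))
      } else {
        if (col == "age" && (v < age_range[1] || v > age_range[2]))
          add(i, sprintf("age outside plausibility window [%g, %g]",
                         age_range[1], age_range[2]))
        if (col %in% ROI_COLUMNS && v < 0)
          add(i, sprintf("negative ROI concentration %s", col))
        if (col %in% VESSEL_COLUMNS && v <= 0)
          add(i, sprintf("nonpositive vessel concentration %s", col))
      }
    }
  }

  ok <- vapply(reasons, is.null, logical(1))
  accepted <- data.frame(
    patient_id  = as.character(df$patient_id[ok]),
    age         = vals$age[ok],
    sex         = sex[ok],
    roi_s3      = vals$roi_s3[ok],
    roi_s4b     = vals$roi_s4b[ok],
    roi_s7      = vals$roi_s7[ok],
    aorta       = vals$aorta[ok],
    portal_vein = vals$portal_vein[ok],
    stringsAsFactors = FALSE
  )
  rejects <- data.frame(
    row        = which(!ok),
    patient_id = as.character(df$patient_id[!ok]),
    reason     = vapply(reasons[!ok], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  list(accepted = accepted, rejects = rejects)
}

#' Construct a validated cohort
#'
#' @param records data.frame with the canonical columns
#'   `patient_id, age, sex, roi_s3, roi_s4b, roi_s7, aorta, portal_vein`
#'   (concentrations in mg/ml, age in years).
#' @param metadata named list of provenance notes (source file, filters).
#' @param rejects data.frame of rejected input rows (row, patient_id, reason);
#'   populated by [read_cohort()].
#' @return object of class `iodine_cohort`.
#' @export
new_cohort <- function(records, metadata = list(), rejects = NULL) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing))
    stop("cohort records missing required column(s): ",
         paste(missing, collapse = ", "))
  records <- records[COHORT_COLUMNS]
  records$patient_id <- as.character(records$patient_id)
  if (!is.factor(records$sex)) records$sex <- normalize_sex(records$sex)
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient_id in cohort: ",
         paste(unique(records$patient_id[duplicated(records$patient_id)]),
               collapse = ", "))
  if (is.null(rejects))
    rejects <- data.frame(row = integer(), patient_id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  structure(list(records = records, metadata = metadata, rejects = rejects),
            class = "iodine_cohort")
}

#' Number of patients in a cohort
#' @param x an `iodine_cohort`.
#' @return integer count of accepted patient records.
#' @export
cohort_size <- function(x) nrow(x$records)

#' @export
print.iodine_cohort <- function(x, ...) {
  rec <- x$records
  cat(sprintf("<iodine_cohort> %d patients (%d male, %d female)\n",
              nrow(rec), sum(rec$sex == "male"), sum(rec$sex == "female")))
  if (nrow(rec))
    cat(sprintf("  age %g-%g years (mean %.2f)\n",
                min(rec$age), max(rec$age), mean(rec$age)))
  if (nrow(x$rejects))
    cat(sprintf("  %d input row(s) rejected\n", nrow(x$rejects)))
  invisible(x)
}

#' Read a per-patient measurement table
#'
#' Reads the canonical comma-separated layout (UTF-8, header
#' `patient_id,age,sex,roi_s3,roi_s4b,roi_s7,aorta,portal_vein`). Extra
#' columns -- e.g. the Hounsfield-unit columns present in raw exports from a
#' spectral workstation -- are accepted and ignored; the analysis uses iodine
#' values only. Rows failing validation are collected in the cohort's
#' `rejects` table with a per-row reason rather than aborting the run;
#' `strict = TRUE` promotes any reject to an error.
#'
#' @param path file path of the cohort table.
#' @param age_range plausibility window for age in years.
#' @param strict logical; if `TRUE` any rejected row is a fatal error.
#' @return an `iodine_cohort`.
#' @export
read_cohort <- function(path, age_range = c(0, 120), strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing))
    stop("cohort table missing required column(s): ",
         paste(missing, collapse = ", "))
  v <- validate_cohort_rows(df, age_range = age_range)
  if (strict && nrow(v$rejects))
    stop(sprintf("%d row(s) failed validation (strict mode): %s",
                 nrow(v$rejects),
                 paste(sprintf("row %d: %s", v$rejects$row, v$rejects$reason),
                       collapse = " | ")))
  if (anyDuplicated(v$accepted$patient_id))
    stop("duplicate patient_id in cohort file: ", path)
  new_cohort(v$accepted,
             metadata = list(source = path, age_range = age_range),
             rejects = v$rejects)
}

#' Write a cohort table
#'
#' Emits the canonical comma-separated layout. Numeric fields are serialized
#' with 17 significant digits so that `read_cohort(write_cohort(c))`
#' reproduces every field to full double precision.
#'
#' @param cohort an `iodine_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "iodine_cohort"))
  rec <- cohort$records
  out <- data.frame(
    patient_id = rec$patient_id,
    age    = sprintf("%.17g", rec$age),
    sex    = as.character(rec$sex),
    stringsAsFactors = FALSE
  )
  for (col in c(ROI_COLUMNS, VESSEL_COLUMNS))
    out[[col]] <- sprintf("%.17g", rec[[col]])
  utils::write.csv(out[COHORT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
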