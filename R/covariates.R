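# Canonical covariate names.
#
# Cost equations refer to covariates by canonical names ("powered",
# "stage_i", "cm_urological", ...).  Each name maps to a 0/1 indicator
# (or the numeric value, for age and bmi) computed from the patient
# record columns, with BMI-band indicators coded one-vs-rest exactly as
# the reference coefficient table phrases them (e.g. "18.5<=BMI<24
# vs. other BMI ranges"), not as a single factor.

BMI_BREAKS <- c(-Inf, 18.5, 24, 28, 30, 40, Inf)
BMI_BAND_LABELS <- c("<18.5", "18.5-24", "24-28", "28-30", "30-40", ">=40")
.BMI_BAND_COV <- c("bmi_lt_18_5", "bmi_18_5_24", "bmi_24_28", "bmi_28_30",
                   "bmi_30_40", "bmi_ge_40")

#' Derive the BMI band from a continuous BMI
#'
#' Bands are half-open `[lo, hi)` with boundaries 18.5, 24, 28, 30, 40
#' kg/m2.
#'
#' @param bmi Numeric vector of BMI values (kg/m2).
#' @return Character vector of band labels.
#' @export
bmi_band <- function(bmi) {
  as.character(cut(bmi, breaks = BMI_BREAKS, labels = BMI_BAND_LABELS,
                   right = FALSE))
}

# Indicator/value for one canonical covariate name; errors name the
# covariate and, for missing values, the offending patient record.
covariate_column <- function(records, name) {
  need <- function(col) {
    if (is.null(records[[col]]))
      stop_named("covariate '", name, "': required column '", col,
                 "' is missing from the patient records")
    records[[col]]
  }
  v <-
    if (name %in% c("age", "bmi")) need(name)
    else if (name == "powered") need("group") == "powered"
    else if (name == "male") need("sex") == "male"
    else if (name == "married") need("marital") == "married"
    else if (name %in% c("adenocarcinoma", "squamous")) need("histology") == name
    else if (name == "stage_i") need("stage") == "I"
    else if (name %in% .BMI_BAND_COV)
      need("bmi_band") == BMI_BAND_LABELS[match(name, .BMI_BAND_COV)]
    else if (startsWith(name, "residence_"))
      need("residence") == sub("^residence_", "", name)
    else if (startsWith(name, "ins_"))
      need("insurance") == sub("^ins_", "", name)
    else if (startsWith(name, "site_"))
      need("lobectomy_site") == sub("^site_", "", name)
    else if (startsWith(name, "cm_") || startsWith(name, "abn_")) need(name)
    else stop_named("unknown covariate '", name, "'")
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    id <- if (!is.null(records$patient_id)) records$patient_id[bad] else paste("row", bad)
    stop_named("covariate '", name, "' is missing (NA) for patient record '", id, "'")
  }
  as.numeric(v)
}

#' Numeric design data.frame for a set of canonical covariates
#'
#' @param records Patient records.
#' @param covariates Canonical covariate names (see
#'   [candidate_covariates()]).
#' @return A data.frame of numeric columns, one per covariate.
#' @export
covariate_matrix <- function(records, covariates) {
  out <- lapply(covariates, function(nm) covariate_column(records, nm))
  names(out) <- covariates
  as.data.frame(out, optional = TRUE, check.names = FALSE)
}

#' Candidate covariates for univariable screening
#'
#' All canonical patient-characteristic covariates that can be computed
#' from the given records (the stapler-arm indicator is handled
#' separately: it is forced into every multivariable equation).
#'
#' @param records Patient records, as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @return Character vector of canonical covariate names.
#' @export
candidate_covariates <- function(records) {
  cands <- c(
    "male", "age",
    "bmi_18_5_24", "bmi_24_28", "bmi_28_30", "bmi_30_40",
    paste0("residence_", c("provincial_capital", "prefecture", "county")),
    "married",
    paste0("ins_", c("urban_employee", "urban_resident", "new_rural")),
    "adenocarcinoma", "squamous", "stage_i",
    grep("^abn_", names(records), value = TRUE),
    "site_upper_left", "site_bottom_left",
    grep("^cm_", names(records), value = TRUE))
  ok <- vapply(cands, function(nm) {
    !inherits(try(covariate_column(records[0L, , drop = FALSE], nm),
                  silent = TRUE), "try-error")
  }, logical(1L))
  cands[ok]
}
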