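#' Eligibility thresholds for episode inclusion
#'
#' Episodes with extreme clinical course are excluded from the cost
#' analysis: operation time over 8 hours, hospital stay over 21 days,
#' bleeding over 600 ml, post-surgery drainage over 2400 ml, death
#' during surgery, and non-routine discharge.  All comparisons are
#' strict (">"), so an episode exactly at a threshold is retained.
#'
#' @param max_operation_hours,max_los_days,max_bleeding_ml,max_drainage_ml
#'   Positive thresholds (the operation-time threshold is given in hours
#'   and converted to minutes internally).
#' @param require_routine_discharge,exclude_surgical_death Logical flags.
#' @return An object of class `eligibility_thresholds`.
#' @export
eligibility_thresholds <- function(max_operation_hours = 8,
                                   max_los_days = 21,
                                   max_bleeding_ml = 600,
                                   max_drainage_ml = 2400,
                                   require_routine_discharge = TRUE,
                                   exclude_surgical_death = TRUE) {
  for (v in c(max_operation_hours, max_los_days, max_bleeding_ml, max_drainage_ml))
    check_pos(v, "eligibility threshold")
  structure(list(max_operation_hours = max_operation_hours,
                 max_los_days = max_los_days,
                 max_bleeding_ml = max_bleeding_ml,
                 max_drainage_ml = max_drainage_ml,
                 require_routine_discharge = isTRUE(require_routine_discharge),
                 exclude_surgical_death = isTRUE(exclude_surgical_death)),
            class = "eligibility_thresholds")
}

#' Apply the eligibility filters to a cohort
#'
#' A record is excluded iff it violates at least one criterion; every
#' violated criterion is reported.  Record order is preserved and
#' included plus excluded partition the input.
#'
#' @param records Patient records.
#' @param thresholds An [eligibility_thresholds()] object.
#' @return List with `included` (records data.frame) and `exclusions`
#'   (data.frame with `patient_id` and semicolon-separated `reasons`).
#' @export
apply_eligibility <- function(records, thresholds = eligibility_thresholds()) {
  stopifnot(inherits(thresholds, "eligibility_thresholds"))
  need <- c("patient_id", "operation_minutes", "length_of_stay", "bleeding_ml",
            "drainage_ml", "died_in_surgery", "discharge_routine")
  if (nrow(records) == 0L)
    return(list(included = records,
                exclusions = data.frame(patient_id = character(0),
                                        reasons = character(0))))
  for (f in need) {
    if (is.null(records[[f]]))
      stop_named("eligibility filtering requires column '", f, "'")
    if (anyNA(records[[f]])) {
      bad <- records$patient_id[which(is.na(records[[f]]))[1L]]
      stop_named("eligibility field '", f, "' is missing for patient record '",
                 bad, "'")
    }
  }
  th <- thresholds
  crit <- list(
    `operation time > 8 hours` =
      records$operation_minutes > th$max_operation_hours * 60,
    `length of stay > 21 days` = records$length_of_stay > th$max_los_days,
    `bleeding > 600 ml` = records$bleeding_ml > th$max_bleeding_ml,
    `drainage > 2400 ml` = records$drainage_ml > th$max_drainage_ml)
  names(crit) <- c(sprintf("operation time > %g hours", th$max_operation_hours),
                   sprintf("length of stay > %g days", th$max_los_days),
                   sprintf("bleeding > %g ml", th$max_bleeding_ml),
                   sprintf("drainage > %g ml", th$max_drainage_ml))
  if (th$exclude_surgical_death)
    crit[["died during surgery"]] <- records$died_in_surgery
  if (th$require_routine_discharge)
    crit[["non-routine discharge"]] <- !records$discharge_routine
  viol <- do.call(cbind, crit)
  excl <- rowSums(viol) > 0
  reasons <- apply(viol[excl, , drop = FALSE], 1L, function(v)
    paste(colnames(viol)[v], collapse = "; "))
  list(included = records[!excl, , drop = FALSE],
       exclusions = data.frame(patient_id = records$patient_id[excl],
                               reasons = as.character(reasons)))
}

MANDATORY_RECORD_COLS <- c("patient_id", "group", "age", "sex", "bmi",
                           "bmi_band", "staplers_used", "cartridges_used")
COST_COLS <- c("stapler_cost", "cartridge_cost", "disposables_cost",
               "drug_cost", "operation_cost", "laboratory_cost", "other_cost",
               "total_cost")

#' Write / read a patient-level cohort CSV
#'
#' One UTF-8, comma-separated row per episode with a mandatory header;
#' costs are plain CNY decimals.  Records and cost records are stored in
#' a single file and split again on reading.  Reading validates the
#' schema (mandatory columns present) and the cost-conservation
#' invariant (`total_cost` equals the sum of the seven components within
#' 1e-6 relative tolerance); unknown columns are preserved on the
#' records side.
#'
#' @param records,costs Data.frames as produced by [simulate_cohort()]
#'   and [simulate_costs()], aligned by `patient_id`.
#' @param path CSV file path.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a list
#'   with `records` and `costs`.
#' @export
write_cohort <- function(records, costs, path) {
  if (!identical(records$patient_id, costs$patient_id))
    stop_named("'records' and 'costs' must be aligned by patient_id")
  merged <- cbind(records, costs[, setdiff(names(costs), "patient_id"),
                                 drop = FALSE])
  utils::write.csv(merged, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_named("cohort file not found: '", path, "'")
  merged <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing_cols <- setdiff(MANDATORY_RECORD_COLS, names(merged))
  if (length(missing_cols))
    stop_named("cohort CSV is missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  have_costs <- intersect(COST_COLS, names(merged))
  if (!all(COST_COLS %in% names(merged)))
    stop_named("cohort CSV is missing cost column(s): ",
               paste(setdiff(COST_COLS, have_costs), collapse = ", "))
  for (col in c("staplers_used", "cartridges_used", "age", "bmi", COST_COLS)) {
    v <- merged[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop_named("cohort CSV column '", col, "' is not numeric (line ",
                 bad + 1L, ")")
    }
  }
  costs <- merged[, c("patient_id", COST_COLS)]
  comp <- rowSums(costs[, setdiff(COST_COLS, "total_cost")])
  off <- abs(costs$total_cost - comp) > 1e-6 * pmax(1, abs(comp))
  if (any(off))
    stop_named("total_cost does not equal the sum of its components for ",
               "patient record(s): ",
               paste(utils::head(costs$patient_id[off], 5L), collapse = ", "))
  records <- merged[, setdiff(names(merged), COST_COLS), drop = FALSE]
  list(records = records, costs = costs)
}
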