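#' Stapler product: unit prices and mean utilization
#'
#' @param name Product label.
#' @param stapler_unit_price,cartridge_unit_price Unit prices (CNY > 0).
#' @param mean_staplers,mean_cartridges Mean devices per episode (>= 0).
#' @param acquisition_override Optional named vector/list with elements
#'   `stapler` and `cartridge`: externally calibrated acquisition costs
#'   (CNY) used instead of counts times unit prices.
#' @return An object of class `stapler_product`.
#' @export
stapler_product <- function(name, stapler_unit_price, cartridge_unit_price,
                            mean_staplers, mean_cartridges,
                            acquisition_override = NULL) {
  check_pos(stapler_unit_price, "stapler_unit_price")
  check_pos(cartridge_unit_price, "cartridge_unit_price")
  check_pos(mean_staplers, "mean_staplers", strict = FALSE)
  check_pos(mean_cartridges, "mean_cartridges", strict = FALSE)
  if (!is.null(acquisition_override)) {
    acquisition_override <- unlist(acquisition_override)
    if (!all(c("stapler", "cartridge") %in% names(acquisition_override)))
      stop_named("'acquisition_override' needs named elements 'stapler' and 'cartridge'")
  }
  structure(list(name = name, stapler_unit_price = stapler_unit_price,
                 cartridge_unit_price = cartridge_unit_price,
                 mean_staplers = mean_staplers,
                 mean_cartridges = mean_cartridges,
                 acquisition_override = acquisition_override),
            class = "stapler_product")
}

#' Bundled device price list
#'
#' The ECHELON powered, ECHELON manual and Victor Medical manual
#' products with published unit prices and utilization means back-solved
#' from the published base-case acquisition costs.  The Victor product
#' carries its published acquisition calibration as an override (the
#' printed cells disagree with counts times unit prices); see the file
#' `extdata/stapler_products.json` for the derivation.
#'
#' @param path Optional path to an alternative JSON/YAML price list.
#' @return Named list of `stapler_product`s.
#' @export
stapler_price_list <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stapler_products.json",
                                package = "staplercma", mustWork = TRUE)
  obj <- read_config_file(path)
  obj$description <- NULL
  lapply(obj, function(p)
    stapler_product(p$name, p$stapler_unit_price, p$cartridge_unit_price,
                    p$mean_staplers, p$mean_cartridges,
                    acquisition_override = p$acquisition_override))
}

#' Bundled manual-scenario baseline costs
#'
#' Per-category baseline hospital costs (CNY) of the manual-stapler
#' reference scenario, used to calibrate the aggregate mode of the
#' decision model.
#'
#' @param path Optional path to an alternative JSON/YAML calibration.
#' @return Named numeric vector over [COST_CATEGORIES].
#' @export
manual_baseline_costs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "manual_baseline_costs.json",
                                package = "staplercma", mustWork = TRUE)
  obj <- read_config_file(path)
  obj$description <- NULL
  unlist(obj)
}

#' Device acquisition costs of a scenario
#'
#' Mean devices per episode times unit price, per device type.  If the
#' product carries an `acquisition_override` it is returned instead
#' (unless `use_override = FALSE`).
#'
#' @param product A [stapler_product()].
#' @param use_override Honour the product's acquisition override.
#' @return Named numeric vector `c(stapler =, cartridge =)` in CNY.
#' @export
acquisition_cost <- function(product, use_override = TRUE) {
  stopifnot(inherits(product, "stapler_product"))
  if (use_override && !is.null(product$acquisition_override))
    return(c(stapler = unname(product$acquisition_override[["stapler"]]),
             cartridge = unname(product$acquisition_override[["cartridge"]])))
  c(stapler = product$mean_staplers * product$stapler_unit_price,
    cartridge = product$mean_cartridges * product$cartridge_unit_price)
}

#' Predict one category's scenario cost from its equation
#'
#' The manual arm keeps the reference cost; the powered arm multiplies
#' it by `exp(beta)` where `beta` is the equation's stapler-arm
#' coefficient.
#'
#' @param equation A `cost_equation` (must contain a `powered` term).
#' @param reference_cost Manual-arm baseline cost for the category
#'   (CNY > 0).
#' @param stapler_arm `"powered"` or `"manual"`.
#' @return Predicted category cost (CNY).
#' @export
predict_category_cost <- function(equation, reference_cost,
                                  stapler_arm = c("powered", "manual")) {
  stapler_arm <- match.arg(stapler_arm)
  check_pos(reference_cost, "reference_cost")
  if (stapler_arm == "manual") return(reference_cost)
  reference_cost * exp(eq_term(equation, STAPLER_TERM)$estimate)
}

# Manual-arm per-category baseline from a cohort: mean model prediction
# with every episode set to the manual arm.
cohort_baseline <- function(equations, cohort) {
  ref <- cohort
  ref$group <- "manual"
  colMeans(predict(equations, ref))
}

#' Run the base-case cost-minimization comparison
#'
#' Builds the two-scenario decision model: per-category hospital costs
#' for a powered-stapler scenario and a manual-stapler comparator
#' scenario, plus device acquisition costs, and their differences
#' (powered minus comparator).  Regression-driven categories are the
#' manual baseline multiplied by `exp(beta)` for the powered arm; the
#' baseline comes either from an aggregate calibration (named per-
#' category costs) or, in patient-level mode, from averaging the
#' equations' predictions over a cohort with every episode set to the
#' manual arm (so the two scenarios are simulated on the same cohort,
#' as a paired design).
#'
#' @param equations A `cost_equations` object.
#' @param powered_product,comparator_product [stapler_product()]s for
#'   the two scenarios.
#' @param baseline In `mode = "aggregate"`, a named numeric vector of
#'   manual-arm baseline costs over [COST_CATEGORIES] (default: the
#'   bundled calibration).  In `mode = "patient"`, a patient records
#'   data.frame.
#' @param mode `"aggregate"` (calibrated) or `"patient"` (cohort).
#' @return An object of class `cma` whose `table` holds per-category
#'   scenario costs and differences; totals are exact sums of the seven
#'   components.
#' @export
cma <- function(equations, powered_product, comparator_product,
                baseline = manual_baseline_costs(),
                mode = c("aggregate", "patient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(equations, "cost_equations"),
            inherits(powered_product, "stapler_product"),
            inherits(comparator_product, "stapler_product"))
  if (mode == "patient") {
    if (!is.data.frame(baseline))
      stop_named("patient-level mode requires a cohort data.frame as 'baseline'")
    base <- cohort_baseline(equations, baseline)
  } else {
    base <- unlist(baseline)
    missing_cat <- setdiff(COST_CATEGORIES, names(base))
    if (length(missing_cat))
      stop_named("calibration is missing cost categor",
                 if (length(missing_cat) > 1) "ies: " else "y: ",
                 paste(missing_cat, collapse = ", "))
    base <- base[COST_CATEGORIES]
    check_pos(base, "calibration costs")
  }
  beta <- stats::setNames(stapler_terms(equations)$estimate, COST_CATEGORIES)
  powered_cat <- base * exp(beta)
  acq_p <- acquisition_cost(powered_product)
  acq_c <- acquisition_cost(comparator_product)
  tab <- data.frame(
    category = COST_COMPONENTS,
    powered = c(acq_p[["stapler"]], acq_p[["cartridge"]], unname(powered_cat)),
    comparator = c(acq_c[["stapler"]], acq_c[["cartridge"]], unname(base)))
  tab <- rbind(tab, data.frame(category = "total",
                               powered = sum(tab$powered),
                               comparator = sum(tab$comparator)))
  tab$difference <- tab$powered - tab$comparator
  structure(list(table = tab, equations = equations, baseline = base,
                 powered_product = powered_product,
                 comparator_product = comparator_product, mode = mode),
            class = "cma")
}

#' Scenario substitution: swap the comparator product
#'
#' Re-runs a base-case comparison with a substitute comparator device
#' (e.g. the Victor Medical manual stapler).  Regression-driven
#' categories are unchanged — the substitute manual stapler is assumed
#' to have the same hospital costs except acquisition — while the
#' acquisition rows come from the substitute's prices or, when the
#' product carries one, its published acquisition calibration.
#'
#' @param x A fitted `cma` object.
#' @param substitute_product The replacement comparator
#'   [stapler_product()].
#' @return A new `cma` object.
#' @export
cma_substitute <- function(x, substitute_product) {
  stopifnot(inherits(x, "cma"))
  cma(x$equations, x$powered_product, substitute_product,
      baseline = x$baseline, mode = "aggregate")
}

#' Total cost difference of a comparison
#'
#' @param x A `cma` object.
#' @return Powered-minus-comparator total difference (CNY).
#' @export
total_difference <- function(x) {
  stopifnot(inherits(x, "cma"))
  x$table$difference[x$table$category == "total"]
}

#' @export
print.cma <- function(x, ...) {
  cat("Cost-minimization comparison (", x$mode, " mode)\n", sep = "")
  cat("  powered:    ", x$powered_product$name, "\n")
  cat("  comparator: ", x$comparator_product$name, "\n")
  tab <- x$table
  cat(sprintf("  %-12s %10s %10s %10s\n", "category", "powered",
              "comparator", "difference"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %10s %10s %10s\n", tab$category[i],
                fmt_cny(tab$powered[i]), fmt_cny(tab$comparator[i]),
                fmt_cny(tab$difference[i])))
  invisible(x)
}

#' @export
summary.cma <- function(object, ...) {
  td <- total_difference(object)
  cat(sprintf("Base case: powered %s vs. comparator %s; difference %s (%s)\n",
              fmt_cny(object$table$powered[object$table$category == "total"]),
              fmt_cny(object$table$comparator[object$table$category == "total"]),
              fmt_cny(td),
              if (td < 0) "powered scenario saves costs" else "comparator cheaper"))
  invisible(object$table)
}
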