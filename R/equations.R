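#' Construct a per-category cost equation
#'
#' A cost equation is a linear predictor on the log-cost scale: the
#' expected cost of a category is `exp(intercept + sum(coef * x))`, so
#' each coefficient acts multiplicatively on the cost.  When an equation
#' is transcribed from a printed table the standard error of each term
#' is derived from its 95% confidence interval as
#' `(ci_high - ci_low) / 3.92` (normality on the log scale).
#'
#' @param category One of [COST_CATEGORIES].
#' @param terms A data.frame with columns `term`, `estimate`, and
#'   optionally `ci_low`, `ci_high`, `p_value`, `se`.  Must contain an
#'   `"(Intercept)"` row.
#' @param family Fitting family label (default `"gamma log-link"`).
#' @return An object of class `cost_equation`.
#' @export
cost_equation <- function(category, terms, family = "gamma log-link") {
  category <- match.arg(category, COST_CATEGORIES)
  stopifnot(is.data.frame(terms), all(c("term", "estimate") %in% names(terms)))
  if (!"(Intercept)" %in% terms$term)
    stop_named("cost equation for '", category, "' has no intercept term")
  for (col in c("ci_low", "ci_high", "p_value"))
    if (is.null(terms[[col]])) terms[[col]] <- NA_real_
  if (is.null(terms$se))
    terms$se <- (terms$ci_high - terms$ci_low) / (2 * stats::qnorm(0.975))
  bad <- which(is.finite(terms$ci_low) & is.finite(terms$ci_high) &
                 (terms$ci_low > terms$estimate | terms$estimate > terms$ci_high))
  if (length(bad))
    stop_named("cost equation for '", category, "': term '", terms$term[bad[1L]],
               "' has an estimate outside its confidence interval")
  rownames(terms) <- NULL
  structure(list(category = category, terms = terms, family = family),
            class = "cost_equation")
}

eq_intercept <- function(eq) eq$terms$estimate[eq$terms$term == "(Intercept)"]

eq_term <- function(eq, name) {
  i <- match(name, eq$terms$term)
  if (is.na(i))
    stop_named("cost equation for '", eq$category, "' has no '", name, "' term")
  eq$terms[i, ]
}

# Linear predictor (log scale) of an equation over patient records.
linear_predictor <- function(eq, records) {
  lp <- rep_len(eq_intercept(eq), nrow(records))
  covs <- setdiff(eq$terms$term, "(Intercept)")
  for (nm in covs) {
    beta <- eq$terms$estimate[eq$terms$term == nm]
    lp <- lp + beta * covariate_column(records, nm)
  }
  lp
}

#' Bundle one cost equation per modelled category
#'
#' @param equations Named list with one `cost_equation` per category in
#'   [COST_CATEGORIES].
#' @param family,n,alpha,screened Fitting metadata: family label, number
#'   of episodes the equations were fitted on, screening alpha, and the
#'   per-category screened covariate sets.
#' @return An object of class `cost_equations`.
#' @export
cost_equations <- function(equations, family = "gamma log-link", n = NA_integer_,
                           alpha = NA_real_, screened = NULL) {
  if (!setequal(names(equations), COST_CATEGORIES))
    stop_named("'equations' must contain exactly the categories: ",
               paste(COST_CATEGORIES, collapse = ", "))
  equations <- equations[COST_CATEGORIES]
  for (eq in equations) {
    stopifnot(inherits(eq, "cost_equation"))
    eq_term(eq, STAPLER_TERM)  # every equation must carry the stapler-arm term
  }
  structure(equations, class = "cost_equations", family = family, n = n,
            alpha = alpha, screened = screened)
}

# Per-category stapler-arm coefficient with its CI-derived SE.
stapler_terms <- function(equations) {
  stopifnot(inherits(equations, "cost_equations"))
  do.call(rbind, lapply(COST_CATEGORIES, function(cc) {
    tr <- eq_term(equations[[cc]], STAPLER_TERM)
    data.frame(category = cc, estimate = tr$estimate, ci_low = tr$ci_low,
               ci_high = tr$ci_high, se = tr$se)
  }))
}

#' @export
coef.cost_equations <- function(object, ...) {
  do.call(rbind, lapply(COST_CATEGORIES, function(cc) {
    cbind(category = cc, object[[cc]]$terms)
  }))
}

#' @export
print.cost_equations <- function(x, ...) {
  cat("Per-category log-link cost equations (", attr(x, "family"), ")\n", sep = "")
  if (!is.na(attr(x, "n"))) cat("  fitted on n =", attr(x, "n"), "episodes\n")
  st <- stapler_terms(x)
  cat("  stapler-arm (powered vs. manual) coefficients:\n")
  for (i in seq_len(nrow(st)))
    cat(sprintf("    %-12s %+.3f  (95%% CI %+.3f to %+.3f)\n", st$category[i],
                st$estimate[i], st$ci_low[i], st$ci_high[i]))
  invisible(x)
}

#' @export
summary.cost_equations <- function(object, ...) {
  out <- coef(object)
  out$expected_at_intercept <- ifelse(out$term == "(Intercept)",
                                      exp(out$estimate), NA_real_)
  class(out) <- c("summary.cost_equations", "data.frame")
  out
}

#' Predict expected per-category costs for patient records
#'
#' Applies each category's equation to the records and returns the
#' expected (mean) cost `exp(X beta)` per episode and category.
#'
#' @param object A `cost_equations` object.
#' @param newdata Patient records.
#' @param type `"response"` (CNY) or `"link"` (log-CNY).
#' @param ... Unused.
#' @return Numeric matrix, one row per record, one column per category.
#' @export
predict.cost_equations <- function(object, newdata, type = c("response", "link"),
                                   ...) {
  type <- match.arg(type)
  lp <- vapply(COST_CATEGORIES,
               function(cc) linear_predictor(object[[cc]], newdata),
               numeric(nrow(newdata)))
  lp <- matrix(lp, nrow = nrow(newdata),
               dimnames = list(newdata$patient_id, COST_CATEGORIES))
  if (type == "response") exp(lp) else lp
}

#' Serialize / read a coefficient table
#'
#' The JSON (or YAML) layout mirrors the printed coefficient table: one
#' block per category with a list of terms carrying the point estimate,
#' 95% confidence bounds and p-value.
#'
#' @param equations A `cost_equations` object.
#' @param path Output (input) file path; format chosen by extension.
#' @return `write_cost_equations()` the path, invisibly;
#'   `read_cost_equations()` a `cost_equations` object.
#' @export
write_cost_equations <- function(equations, path) {
  stopifnot(inherits(equations, "cost_equations"))
  obj <- list(family = attr(equations, "family"), n = attr(equations, "n"),
              alpha = attr(equations, "alpha"),
              screened = attr(equations, "screened"),
              categories = lapply(unclass(equations), function(eq)
                list(terms = eq$terms)))
  write_json_file(obj, path)
}

#' @rdname write_cost_equations
#' @export
read_cost_equations <- function(path) {
  obj <- read_config_file(path)
  eqs <- lapply(names(obj$categories), function(cc) {
    terms <- as.data.frame(obj$categories[[cc]]$terms)
    cost_equation(cc, terms, family = obj$family %||% "gamma log-link")
  })
  names(eqs) <- names(obj$categories)
  cost_equations(eqs, family = obj$family %||% "gamma log-link",
                 n = obj$n %||% NA_integer_, alpha = obj$alpha %||% NA_real_,
                 screened = obj$screened)
}

#' Reference VATS lobectomy cost equations
#'
#' The multivariable gamma log-link regression estimates from the
#' reference retrospective cost analysis of 388 VATS lobectomy episodes
#' (296 powered, 92 manual stapler), transcribed verbatim: per-category
#' intercepts, covariate coefficients, 95% confidence intervals and
#' p-values.  These equations drive the aggregate-calibrated decision
#' model and serve as the ground truth for synthetic cohorts.
#'
#' @return A `cost_equations` object.
#' @export
vats_cost_equations <- function() {
  read_cost_equations(system.file("extdata", "vats_cost_equations.json",
                                  package = "staplercma", mustWork = TRUE))
}
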