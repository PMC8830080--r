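#' Fit a gamma log-link cost regression
#'
#' Maximum-likelihood fit of a generalized linear model with gamma
#' family and log link via iteratively reweighted least squares
#' (convergence: relative deviance change below 1e-8 within 100
#' iterations; non-convergence is an error).  Dispersion is estimated by
#' the Pearson statistic over the residual degrees of freedom, and Wald
#' 95% confidence intervals and p-values are computed on the log scale.
#'
#' An ordinary least-squares fit of `log(y)` is available as
#' `family = "lognormal"` for sensitivity analyses; its coefficients are
#' comparable on the log scale but its intercept targets the log-scale
#' mean rather than the log of the arithmetic mean.
#'
#' @param design A data.frame of numeric/0-1 covariates (no intercept
#'   column; one is added).  May have zero columns for an
#'   intercept-only model.
#' @param y Strictly positive response costs (CNY).
#' @param category Category label attached to the returned equation.
#' @param family `"gamma"` (default) or `"lognormal"`.
#' @return A `cost_equation`.
#' @export
fit_cost_glm <- function(design, y, category = "other",
                         family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  design <- as.data.frame(design, optional = TRUE)
  if (nrow(design) == 0L) design <- data.frame(row.names = seq_along(y))
  if (length(y) != nrow(design) && ncol(design) > 0L)
    stop_named("'design' and 'y' have different lengths")
  if (any(!is.finite(y)) || any(y <= 0))
    stop_named("cost regression requires strictly positive responses; ",
               "found non-positive or non-finite values in 'y'")
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop_named("design matrix is rank deficient; collinear column(s): ",
               paste(dropped, collapse = ", "))
  }
  dat <- cbind(.y = y, design)
  if (family == "gamma") {
    fit <- stats::glm(.y ~ ., data = dat, family = stats::Gamma(link = "log"),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    if (!fit$converged)
      stop_named("gamma log-link IRLS did not converge in 100 iterations")
    df <- fit$df.residual
    disp <- if (df > 0) sum(stats::residuals(fit, "pearson")^2) / df else 0
    est <- stats::coef(fit)
    se <- sqrt(diag(summary(fit)$cov.unscaled) * disp)
  } else {
    fit <- stats::lm(log(.y) ~ ., data = dat)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  z <- ifelse(se > 0, est / se, NA_real_)
  terms <- data.frame(
    term = names(est),
    estimate = unname(est),
    ci_low = unname(est - stats::qnorm(0.975) * se),
    ci_high = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    se = unname(se))
  cost_equation(category, terms,
                family = if (family == "gamma") "gamma log-link" else "lognormal")
}

cost_col <- function(category) {
  c(disposables = "disposables_cost", drugs = "drug_cost",
    operation = "operation_cost", laboratory = "laboratory_cost",
    other = "other_cost", stapler = "stapler_cost",
    cartridge = "cartridge_cost")[[category]]
}

#' Univariable screening of cost predictors
#'
#' Fits one single-covariate gamma log-link regression per candidate
#' covariate against the chosen cost category and keeps the covariates
#' with Wald p below `alpha`.  The stapler-arm indicator is always
#' returned regardless of its p-value, since the decision model requires
#' it in every equation.  Constant covariates are skipped with a
#' warning.
#'
#' @param records,costs Patient records and their cost records.
#' @param category One of [COST_CATEGORIES].
#' @param alpha Screening significance level (default 0.05).
#' @param candidates Canonical covariate names to screen; defaults to
#'   [candidate_covariates()].
#' @return Character vector of covariate names (always including
#'   `"powered"`).
#' @export
univariable_screen <- function(records, costs, category, alpha = 0.05,
                               candidates = candidate_covariates(records)) {
  category <- match.arg(category, COST_CATEGORIES)
  y <- costs[[cost_col(category)]]
  keep <- character(0)
  for (nm in setdiff(candidates, STAPLER_TERM)) {
    x <- covariate_column(records, nm)
    if (length(unique(x)) < 2L) {
      warning("skipping constant covariate '", nm, "' in univariable screen",
              call. = FALSE)
      next
    }
    eq <- fit_cost_glm(stats::setNames(data.frame(x), nm), y, category)
    p <- eq$terms$p_value[eq$terms$term == nm]
    if (is.finite(p) && p < alpha) keep <- c(keep, nm)
  }
  union(STAPLER_TERM, keep)
}

#' Fit the full per-category coefficient table
#'
#' For each of the five modelled cost categories: univariable screening
#' of patient characteristics, then a multivariable gamma log-link fit
#' on the retained covariates plus the stapler-arm indicator (which is
#' forced into every equation).
#'
#' @inheritParams univariable_screen
#' @param family Passed to [fit_cost_glm()].
#' @return A `cost_equations` object; the screened covariate sets are
#'   recorded in its metadata.
#' @export
fit_cost_equations <- function(records, costs, alpha = 0.05,
                               candidates = candidate_covariates(records),
                               family = "gamma") {
  screened <- list()
  eqs <- lapply(COST_CATEGORIES, function(cc) {
    covs <- univariable_screen(records, costs, cc, alpha, candidates)
    screened[[cc]] <<- covs
    fit_cost_glm(covariate_matrix(records, covs), costs[[cost_col(cc)]],
                 cc, family = family)
  })
  names(eqs) <- COST_CATEGORIES
  cost_equations(eqs, family = eqs[[1L]]$family, n = nrow(records),
                 alpha = alpha, screened = screened)
}
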