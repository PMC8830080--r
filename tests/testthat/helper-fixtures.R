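# Shared builders: small profiles and controlled coefficient tables, so
# tests construct exactly the data-generating conditions they probe.

flat_probs <- function(levels) {
  p <- rep(1 / length(levels), length(levels))
  stats::setNames(as.list(p), levels)
}

make_group <- function(n, male = 0.5, age = c(58, 9), bmi = c(23.8, 3.1),
                       staplers = c(1.2, 0.6), cartridges = c(7.0, 3.9),
                       prev = 0.1) {
  cm <- c("digestive", "urological", "hypertension", "cerebrovascular",
          "bronchial", "endocrine", "sport", "diabetes", "immune", "breast",
          "cardiovascular", "vascular")
  abn <- c("inr", "hemoglobin", "erythrocyte", "leukocyte", "platelet")
  list(
    n = n, male = male,
    age = list(mean = age[1], sd = age[2]),
    bmi = list(mean = bmi[1], sd = bmi[2]),
    staplers = list(mean = staplers[1], sd = staplers[2]),
    cartridges = list(mean = cartridges[1], sd = cartridges[2]),
    residence = flat_probs(c("provincial_capital", "prefecture", "county", "other")),
    insurance = flat_probs(c("urban_employee", "urban_resident", "new_rural", "other")),
    marital = list(married = 0.95, single = 0.05),
    histology = flat_probs(c("squamous", "adenocarcinoma", "other")),
    stage = flat_probs(c("in_situ", "I", "II", "III", "IV")),
    lobectomy_site = flat_probs(c("upper_right", "lower_right", "upper_left",
                                  "bottom_left")),
    comorbidity = stats::setNames(as.list(rep(prev, length(cm))), cm),
    marrow = stats::setNames(as.list(rep(prev, length(abn))), abn))
}

make_profile <- function(n_powered = 100, n_manual = 50, dispersion = 5,
                         male = c(0.5, 0.5), ...) {
  cohort_profile(list(
    dispersion = dispersion,
    groups = list(powered = make_group(n_powered, male = male[1], ...),
                  manual = make_group(n_manual, male = male[2], ...)),
    episode = list(
      operation_minutes = list(mean = 180, sd = 60, min = 30, max = 700),
      length_of_stay = list(mean = 9, sd = 4, min = 2, max = 40),
      bleeding_ml = list(mean = 100, sd = 80, min = 5, max = 2000),
      drainage_ml = list(mean = 900, sd = 450, min = 50, max = 5000),
      p_death_in_surgery = 0.002, p_routine_discharge = 0.98)))
}

# Intercept + stapler-arm equations, optionally with extra covariate
# terms and symmetric CI half-widths around each estimate.
make_equations <- function(betas = c(disposables = 0, drugs = -0.256,
                                     operation = 0, laboratory = 0, other = 0),
                           intercepts = c(disposables = 9.2, drugs = 9.492,
                                          operation = 8.9, laboratory = 9.1,
                                          other = 7.7),
                           ci_halfwidth = 0.1, extra = list()) {
  eqs <- lapply(COST_CATEGORIES, function(cc) {
    terms <- data.frame(
      term = c("(Intercept)", "powered"),
      estimate = c(intercepts[[cc]], betas[[cc]]),
      ci_low = c(intercepts[[cc]], betas[[cc]] - ci_halfwidth),
      ci_high = c(intercepts[[cc]], betas[[cc]] + ci_halfwidth),
      p_value = NA_real_)
    if (!is.null(extra[[cc]]))
      terms <- rbind(terms, data.frame(
        term = names(extra[[cc]]), estimate = unname(extra[[cc]]),
        ci_low = unname(extra[[cc]]), ci_high = unname(extra[[cc]]),
        p_value = NA_real_))
    cost_equation(cc, terms)
  })
  names(eqs) <- COST_CATEGORIES
  cost_equations(eqs)
}

# Simple products for controlled comparisons.
make_product <- function(name = "test", sp = 1000, cp = 500, ms = 1, mc = 5,
                         override = NULL)
  stapler_product(name, sp, cp, ms, mc, acquisition_override = override)

drop_constant_cols <- function(X)
  X[, vapply(X, function(v) length(unique(v)) > 1, logical(1)), drop = FALSE]

y_col <- c(disposables = "disposables_cost", drugs = "drug_cost",
           operation = "operation_cost", laboratory = "laboratory_cost",
           other = "other_cost")

# Direct numerical maximization of the gamma log-likelihood in beta
# (the score in beta is free of the shape parameter), independent of the
# IRLS path it cross-checks.
gamma_ml_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(beta) {
    mu <- exp(drop(X1 %*% beta))
    sum(y / mu + log(mu))
  }
  stats::optim(rep(0, ncol(X1)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Published base-case inputs used across CMA tests.
published_baseline <- c(disposables = 9989, drugs = 13043, operation = 7643,
                        laboratory = 11162, other = 2248)
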