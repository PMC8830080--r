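test_that("intercept-only gamma fit equals the log of the sample mean", {
  y <- c(1, 2, 4, 8)
  eq <- fit_cost_glm(data.frame(row.names = 1:4), y)
  expect_equal(eq$terms$estimate[1], log(3.75), tolerance = 1e-8)
  # degenerate all-equal response: exact log, zero-width uncertainty
  eqc <- suppressWarnings(fit_cost_glm(data.frame(row.names = 1:6), rep(250, 6)))
  expect_equal(eqc$terms$estimate[1], log(250), tolerance = 1e-10)
  expect_equal(eqc$terms$se[1], 0)
})

test_that("IRLS point estimates agree with the likelihood-maximization oracle", {
  set.seed(8)
  n <- 40
  X <- data.frame(arm = rep(0:1, each = n / 2), size = rnorm(n))
  mu <- exp(2 + 0.5 * X$arm - 0.3 * X$size)
  y <- rgamma(n, shape = 5, rate = 5 / mu)
  eq <- fit_cost_glm(X, y)
  oracle <- gamma_ml_oracle(X, y)
  expect_lt(max(abs(eq$terms$estimate - oracle)), 1e-6)
})

test_that("non-positive responses and collinear designs are rejected by name", {
  X <- data.frame(a = c(0, 1, 0, 1))
  expect_error(fit_cost_glm(X, c(1, 2, 0, 3)), "positive")
  X2 <- data.frame(a = c(0, 1, 0, 1, 1, 0), twice_a = 2 * c(0, 1, 0, 1, 1, 0))
  expect_error(fit_cost_glm(X2, exp(rnorm(6))), "twice_a")
})

test_that("noise-free synthetic costs return the generating coefficients exactly", {
  prof <- make_profile(n_powered = 200, n_manual = 100, dispersion = Inf,
                       prev = 0.3)
  truth_eqs <- vats_cost_equations()
  truth <- ground_truth(truth_eqs, prof, seed = 6)
  rec <- simulate_cohort(prof, seed = 6)
  co <- simulate_costs(rec, truth)
  for (cc in COST_CATEGORIES) {
    eqc <- truth_eqs[[cc]]
    covs <- setdiff(eqc$terms$term, "(Intercept)")
    X <- drop_constant_cols(covariate_matrix(rec, covs))
    fit <- suppressWarnings(fit_cost_glm(X, co[[y_col[[cc]]]], cc))
    keep <- names(X)  # identifiable covariates in this replicate
    err <- abs(fit$terms$estimate[match(keep, fit$terms$term)] -
                 eqc$terms$estimate[match(keep, eqc$terms$term)])
    expect_lt(max(err), 1e-6)
    if (length(keep) == length(covs)) {  # nothing dropped: intercept exact too
      b0_fit <- fit$terms$estimate[fit$terms$term == "(Intercept)"]
      b0_true <- eqc$terms$estimate[eqc$terms$term == "(Intercept)"]
      expect_lt(abs(b0_fit - b0_true), 1e-6)
    }
  }
})

test_that("univariable screening keeps the active covariate and the stapler term", {
  prof <- make_profile(n_powered = 1000, n_manual = 1000, dispersion = 5)
  eqs <- make_equations(extra = list(drugs = c(cm_diabetes = 0.5)))
  cands <- c("male", "age", "cm_diabetes", "cm_digestive", "stage_i",
             "adenocarcinoma")
  for (seed in c(3, 17, 29)) {
    truth <- ground_truth(eqs, prof, seed = seed)
    rec <- simulate_cohort(prof, seed = seed)
    co <- simulate_costs(rec, truth)
    kept <- univariable_screen(rec, co, "drugs", candidates = cands)
    expect_true(all(c("powered", "cm_diabetes") %in% kept))
  }
})

test_that("screening alpha limits behave as degenerate thresholds", {
  sim <- simulate_study(profile = make_profile(n_powered = 60, n_manual = 40),
                        equations = make_equations(), seed = 23)
  cands <- c("male", "cm_diabetes", "stage_i")
  all_in <- univariable_screen(sim$records, sim$costs, "drugs", alpha = 1,
                               candidates = cands)
  expect_setequal(all_in, c("powered", cands))
  only_forced <- univariable_screen(sim$records, sim$costs, "drugs", alpha = 0,
                                    candidates = cands)
  expect_identical(only_forced, "powered")
})

test_that("constant covariates are skipped with a warning during screening", {
  sim <- simulate_study(profile = make_profile(n_powered = 30, n_manual = 20),
                        equations = make_equations(), seed = 24)
  sim$records$cm_breast <- FALSE
  expect_warning(
    univariable_screen(sim$records, sim$costs, "drugs",
                       candidates = c("male", "cm_breast")),
    "cm_breast")
})

test_that("the fitted coefficient table has five equations with forced stapler terms", {
  sim <- simulate_study(profile = make_profile(n_powered = 120, n_manual = 60),
                        equations = make_equations(), seed = 25)
  eqs <- fit_cost_equations(sim$records, sim$costs, alpha = 0.05)
  expect_s3_class(eqs, "cost_equations")
  expect_setequal(names(eqs), COST_CATEGORIES)
  for (cc in COST_CATEGORIES)
    expect_true("powered" %in% eqs[[cc]]$terms$term)
  # round trip through the serialization layer
  path <- withr::local_tempfile(fileext = ".json")
  write_cost_equations(eqs, path)
  back <- read_cost_equations(path)
  expect_equal(coef(back)$estimate, coef(eqs)$estimate, tolerance = 1e-12)
})

test_that("confidence intervals tighten with sample size for every term", {
  prof_small <- make_profile(n_powered = 35, n_manual = 15, dispersion = 5)
  prof_large <- make_profile(n_powered = 296, n_manual = 92, dispersion = 5)
  eqs <- make_equations(extra = list(drugs = c(cm_diabetes = 0.3, stage_i = -0.2)))
  covs <- c("powered", "cm_diabetes", "stage_i")
  width <- function(prof, seed) {
    truth <- ground_truth(eqs, prof, seed = seed)
    rec <- simulate_cohort(prof, seed = seed)
    co <- simulate_costs(rec, truth)
    fit <- fit_cost_glm(covariate_matrix(rec, covs), co$drug_cost, "drugs")
    with(fit$terms, ci_high - ci_low)
  }
  w50 <- width(prof_small, 41)
  w388 <- width(prof_large, 41)
  expect_true(all(w50 > w388))
})

test_that("a covariate absent from the generating model is estimated near zero", {
  prof <- make_profile(n_powered = 296, n_manual = 92, dispersion = 5)
  eqs <- make_equations()  # drug model: intercept + stapler only
  covs <- c("powered", "cm_bullae")
  est <- vapply(1:200, function(r) {
    truth <- ground_truth(eqs, prof, seed = r)
    rec <- simulate_cohort(prof, seed = r)
    rec$cm_bullae <- simulate_cohort(prof, seed = r + 10000)$cm_diabetes
    co <- simulate_costs(rec, truth)
    fit <- fit_cost_glm(covariate_matrix(rec, covs), co$drug_cost, "drugs")
    fit$terms$estimate[fit$terms$term == "cm_bullae"]
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * stats::sd(est) / sqrt(length(est)))
})

test_that("the lognormal sensitivity family returns comparable slope coefficients", {
  prof <- make_profile(n_powered = 250, n_manual = 150, dispersion = 20)
  eqs <- make_equations()
  truth <- ground_truth(eqs, prof, seed = 55)
  rec <- simulate_cohort(prof, seed = 55)
  co <- simulate_costs(rec, truth)
  g <- fit_cost_glm(covariate_matrix(rec, "powered"), co$drug_cost, "drugs")
  l <- fit_cost_glm(covariate_matrix(rec, "powered"), co$drug_cost, "drugs",
                    family = "lognormal")
  bg <- g$terms$estimate[g$terms$term == "powered"]
  bl <- l$terms$estimate[l$terms$term == "powered"]
  expect_lt(abs(bg - bl), 0.05)
})
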