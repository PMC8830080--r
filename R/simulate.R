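# Truncated-normal draws via the inverse-CDF method: one uniform per
# observation, so the RNG stream length does not depend on the bounds.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep_len(pmin(pmax(mean, lo), hi), n))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, a, b), mean, sd)
}

sample_level <- function(n, probs) {
  pr <- unlist(probs)
  names(pr)[1L + findInterval(stats::runif(n), cumsum(pr) / sum(pr))]
}

#' Simulate a patient-level cohort
#'
#' Draws one surgical episode per patient from the marginal
#' distributions in a [cohort_profile()]: binary covariates are
#' independent Bernoulli draws, categorical fields are drawn from the
#' profile's level probabilities, age and BMI are truncated normals (18
#' to 100 years, 15 to 45 kg/m2) with the BMI band derived from the
#' sampled BMI, and device counts are normal draws truncated below at
#' zero and rounded to integers.  Output is bit-identical for identical
#' profile and seed.
#'
#' @param profile A `cohort_profile`.
#' @param seed Integer RNG seed.
#' @return A data.frame of patient records, one row per episode.
#' @export
simulate_cohort <- function(profile, seed = 1L) {
  profile <- if (inherits(profile, "cohort_profile")) profile else cohort_profile(profile)
  set.seed(seed)
  ep <- profile$episode
  groups <- lapply(names(profile$groups), function(g) {
    grp <- profile$groups[[g]]
    n <- grp$n
    bmi <- rnorm_trunc(n, grp$bmi$mean, grp$bmi$sd, 15, 45)
    rec <- data.frame(
      patient_id = NA_character_,
      group = g,
      age = rnorm_trunc(n, grp$age$mean, grp$age$sd, 18, 100),
      sex = ifelse(stats::runif(n) < grp$male, "male", "female"),
      bmi = bmi,
      bmi_band = bmi_band(bmi),
      residence = sample_level(n, grp$residence),
      insurance = sample_level(n, grp$insurance),
      marital = sample_level(n, grp$marital),
      histology = sample_level(n, grp$histology),
      stage = sample_level(n, grp$stage),
      lobectomy_site = sample_level(n, grp$lobectomy_site))
    for (nm in names(grp$comorbidity))
      rec[[paste0("cm_", nm)]] <- stats::runif(n) < grp$comorbidity[[nm]]
    for (nm in names(grp$marrow))
      rec[[paste0("abn_", nm)]] <- stats::runif(n) < grp$marrow[[nm]]
    rec$staplers_used <- round(pmax(0, stats::rnorm(n, grp$staplers$mean, grp$staplers$sd)))
    rec$cartridges_used <- round(pmax(0, stats::rnorm(n, grp$cartridges$mean, grp$cartridges$sd)))
    rec$operation_minutes <- rnorm_trunc(n, ep$operation_minutes$mean,
                                         ep$operation_minutes$sd,
                                         ep$operation_minutes$min %||% 0,
                                         ep$operation_minutes$max %||% Inf)
    rec$length_of_stay <- round(rnorm_trunc(n, ep$length_of_stay$mean,
                                            ep$length_of_stay$sd,
                                            ep$length_of_stay$min %||% 0,
                                            ep$length_of_stay$max %||% Inf))
    rec$bleeding_ml <- rnorm_trunc(n, ep$bleeding_ml$mean, ep$bleeding_ml$sd,
                                   ep$bleeding_ml$min %||% 0,
                                   ep$bleeding_ml$max %||% Inf)
    rec$drainage_ml <- rnorm_trunc(n, ep$drainage_ml$mean, ep$drainage_ml$sd,
                                   ep$drainage_ml$min %||% 0,
                                   ep$drainage_ml$max %||% Inf)
    rec$died_in_surgery <- stats::runif(n) < ep$p_death_in_surgery
    rec$discharge_routine <- stats::runif(n) < ep$p_routine_discharge
    rec
  })
  out <- do.call(rbind, groups)
  out$patient_id <- sprintf("P%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Ground truth for synthetic cost generation
#'
#' Bundles the coefficient table used to simulate costs, the cohort
#' profile (whose `dispersion` is the gamma shape of the cost noise),
#' the device products whose unit prices convert device counts into
#' acquisition costs, and the seed.
#'
#' @param equations A `cost_equations` object.
#' @param profile A `cohort_profile`.
#' @param seed Integer RNG seed used by [simulate_costs()].
#' @param prices Named list of `stapler_product`s keyed by group name;
#'   defaults to the bundled ECHELON powered and manual products.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(equations, profile, seed = 1L, prices = NULL) {
  stopifnot(inherits(equations, "cost_equations"))
  profile <- if (inherits(profile, "cohort_profile")) profile else cohort_profile(profile)
  if (is.null(prices)) {
    pl <- stapler_price_list()
    prices <- list(powered = pl$echelon_powered, manual = pl$echelon_manual)
  }
  if (!all(names(profile$groups) %in% names(prices)))
    stop_named("'prices' must carry a stapler_product for every profile group: ",
               paste(names(profile$groups), collapse = ", "))
  # every covariate referenced by the equations must be generable
  pp <- profile
  for (g in names(pp$groups)) pp$groups[[g]]$n <- 1L
  probe <- simulate_cohort(pp, seed = 0L)
  for (cc in COST_CATEGORIES)
    for (nm in setdiff(equations[[cc]]$terms$term, "(Intercept)"))
      covariate_column(probe, nm)
  structure(list(equations = equations, profile = profile, seed = seed,
                 prices = prices),
            class = "ground_truth")
}

#' Simulate per-category hospital costs for a cohort
#'
#' For each episode and each of the five modelled categories the cost is
#' a gamma draw with mean `exp(X beta)` (linear predictor from the
#' ground-truth equations) and shape equal to the profile's
#' `dispersion`; an infinite dispersion gives the noise-free mean
#' itself, which is the exact inversion oracle for the regression
#' module.  Stapler and cartridge costs are the episode's device counts
#' times the group's unit prices, and the total is the sum of all seven
#' components.
#'
#' @param cohort Patient records from [simulate_cohort()].
#' @param truth A [ground_truth()] object.
#' @return A data.frame of cost records aligned with `cohort`.
#' @export
simulate_costs <- function(cohort, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  n <- nrow(cohort)
  k <- truth$profile$dispersion
  out <- data.frame(patient_id = cohort$patient_id)
  prod <- truth$prices[cohort$group]
  out$stapler_cost <- cohort$staplers_used *
    vapply(prod, function(p) p$stapler_unit_price, numeric(1L))
  out$cartridge_cost <- cohort$cartridges_used *
    vapply(prod, function(p) p$cartridge_unit_price, numeric(1L))
  for (cc in COST_CATEGORIES) {
    mu <- exp(linear_predictor(truth$equations[[cc]], cohort))
    out[[cost_col(cc)]] <- if (is.finite(k))
      stats::rgamma(n, shape = k, rate = k / mu) else mu
  }
  out$total_cost <- rowSums(out[, vapply(COST_COMPONENTS, cost_col, character(1L))])
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study (records, costs, ground truth)
#'
#' Convenience wrapper: builds the ground truth, simulates the cohort
#' and its costs with a single seed, and returns all three.
#'
#' @inheritParams ground_truth
#' @return List with elements `records`, `costs`, `truth`.
#' @export
simulate_study <- function(profile = default_cohort_profile(),
                           equations = vats_cost_equations(),
                           seed = 1L, prices = NULL) {
  truth <- ground_truth(equations, profile, seed = seed, prices = prices)
  records <- simulate_cohort(truth$profile, seed = seed)
  costs <- simulate_costs(records, truth)
  list(records = records, costs = costs, truth = truth)
}

#' Write the ground truth sidecar next to a cohort CSV
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(seed = truth$seed,
              dispersion = truth$profile$dispersion,
              profile = unclass(truth$profile),
              prices = lapply(truth$prices, unclass),
              equations = lapply(unclass(truth$equations),
                                 function(eq) list(terms = eq$terms)))
  write_json_file(obj, path)
}
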