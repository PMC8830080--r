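test_that("acquisition cost is mean devices times unit price", {
  p <- make_product(sp = 3970, cp = 2441, ms = 1.2, mc = 7.5)
  acq <- acquisition_cost(p)
  expect_equal(acq[["cartridge"]], 18307.5)  # 7.5 x 2441
  expect_equal(acq[["stapler"]], 4764)       # 1.2 x 3970
  expect_equal(acquisition_cost(make_product(mc = 0))[["cartridge"]], 0)
})

test_that("acquisition overrides are honoured and can be bypassed", {
  p <- make_product(sp = 3800, cp = 2987, ms = 1.20654911838791,
                    mc = 7.50020483408439,
                    override = c(stapler = 4882, cartridge = 20974))
  expect_equal(acquisition_cost(p), c(stapler = 4882, cartridge = 20974))
  raw <- acquisition_cost(p, use_override = FALSE)
  # price-only arithmetic disagrees with the published calibration cells
  expect_equal(raw[["stapler"]], 4584.89, tolerance = 1e-4)
  expect_equal(raw[["cartridge"]], 22403.1, tolerance = 1e-4)
})

test_that("category prediction multiplies the manual baseline by exp(beta)", {
  eqs <- vats_cost_equations()
  expect_equal(predict_category_cost(eqs$drugs, 13043, "manual"), 13043)
  expect_equal(predict_category_cost(eqs$drugs, 13043, "powered"),
               13043 * exp(-0.256))
  eq0 <- make_equations()$operation  # beta = 0: identity
  expect_equal(predict_category_cost(eq0, 7643, "powered"), 7643)
  no_stapler <- cost_equation("drugs", data.frame(term = "(Intercept)",
                                                  estimate = 9))
  expect_error(predict_category_cost(no_stapler, 1000, "powered"), "powered")
})

test_that("scenario totals conserve the sum of their seven components", {
  pl <- stapler_price_list()
  base <- cma(vats_cost_equations(), pl$echelon_powered, pl$echelon_manual)
  tab <- base$table
  for (col in c("powered", "comparator", "difference")) {
    tot <- tab[[col]][tab$category == "total"]
    expect_equal(tot, sum(tab[[col]][tab$category != "total"]), tolerance = 1e-12)
  }
})

test_that("comparing identical scenarios yields exactly zero differences", {
  p <- make_product()
  null_eqs <- make_equations(betas = c(disposables = 0, drugs = 0,
                                       operation = 0, laboratory = 0, other = 0))
  out <- cma(null_eqs, p, p, baseline = published_baseline)
  expect_true(all(out$table$difference == 0))
})

test_that("doubling unit prices scales acquisition rows and nothing else", {
  eqs <- vats_cost_equations()
  p1 <- make_product("a", 1000, 500, 1.2, 7)
  p2 <- make_product("b", 2000, 1000, 1.2, 7)
  c1 <- cma(eqs, p1, p1, baseline = published_baseline)
  c2 <- cma(eqs, p2, p2, baseline = published_baseline)
  acq <- c1$table$category %in% c("stapler", "cartridge")
  reg <- !acq & c1$table$category != "total"
  expect_equal(c2$table$powered[acq], 2 * c1$table$powered[acq])
  expect_equal(c2$table$powered[reg], c1$table$powered[reg])
})

test_that("swapping the two products negates differences when arms are equivalent", {
  null_eqs <- make_equations(betas = c(disposables = 0, drugs = 0,
                                       operation = 0, laboratory = 0, other = 0))
  pa <- make_product("a", 1000, 500, 1, 5)
  pb <- make_product("b", 1500, 400, 2, 4)
  ab <- cma(null_eqs, pa, pb, baseline = published_baseline)
  ba <- cma(null_eqs, pb, pa, baseline = published_baseline)
  expect_equal(ab$table$difference, -ba$table$difference)
})

test_that("missing calibration categories are reported by name", {
  pl <- stapler_price_list()
  expect_error(cma(vats_cost_equations(), pl$echelon_powered,
                   pl$echelon_manual, baseline = published_baseline[-2]),
               "drugs")
})

test_that("patient-level mode equals aggregate mode on a calibrated cohort", {
  # intercept-only equations whose exp(intercept) is the calibration value:
  # the cohort-mean manual baseline then equals the aggregate calibration.
  eqs <- make_equations(
    betas = c(disposables = -0.007, drugs = -0.256, operation = 0.004,
              laboratory = -0.094, other = -0.008),
    intercepts = log(published_baseline))
  pl <- stapler_price_list()
  rec <- simulate_cohort(make_profile(n_powered = 50, n_manual = 25), seed = 9)
  agg <- cma(eqs, pl$echelon_powered, pl$echelon_manual,
             baseline = published_baseline)
  pat <- cma(eqs, pl$echelon_powered, pl$echelon_manual, baseline = rec,
             mode = "patient")
  expect_equal(pat$table$powered, agg$table$powered, tolerance = 1e-9)
  expect_equal(total_difference(pat), total_difference(agg), tolerance = 1e-9)
})

test_that("substituting the comparator keeps regression-driven categories fixed", {
  pl <- stapler_price_list()
  base <- cma(vats_cost_equations(), pl$echelon_powered, pl$echelon_manual)
  vic <- cma_substitute(base, pl$victor_manual)
  reg <- !vic$table$category %in% c("stapler", "cartridge", "total")
  expect_equal(vic$table$comparator[reg], base$table$comparator[reg])
  expect_equal(vic$table$powered, base$table$powered)
  # substituting the original comparator reproduces the base comparison
  same <- cma_substitute(base, pl$echelon_manual)
  expect_equal(same$table, base$table)
})

test_that("tornado entries bracket the base case and sort by swing", {
  pl <- stapler_price_list()
  base <- cma(vats_cost_equations(), pl$echelon_powered, pl$echelon_manual)
  tn <- tornado(base)
  bd <- attr(tn, "base_difference")
  expect_equal(bd, total_difference(base))
  lo <- pmin(tn$low_total_difference, tn$high_total_difference)
  hi <- pmax(tn$low_total_difference, tn$high_total_difference)
  expect_true(all(lo <= bd + 1e-9 & bd <= hi + 1e-9))
  expect_true(all(diff(tn$span) <= 1e-9))
})

test_that("tornado collapses to the base case under zero-width bounds", {
  eqs <- make_equations(ci_halfwidth = 0)
  p <- make_product()
  base <- cma(eqs, p, p, baseline = published_baseline)
  tn <- tornado(base, price_range = 0, count_range = 0)
  bd <- attr(tn, "base_difference")
  expect_true(all(tn$low_total_difference == bd))
  expect_true(all(tn$high_total_difference == bd))
})

test_that("a coefficient bound reproduces the closed-form total difference", {
  pl <- stapler_price_list()
  eqs <- vats_cost_equations()
  base <- cma(eqs, pl$echelon_powered, pl$echelon_manual)
  tn <- tornado(base)
  entry <- tn[tn$parameter == "stapler-arm coefficient (drugs)", ]
  # closed form: swap the drugs coefficient for its upper CI bound
  beta <- c(disposables = -0.007, drugs = -0.139, operation = 0.004,
            laboratory = -0.094, other = -0.008)
  acq <- acquisition_cost(pl$echelon_powered) - acquisition_cost(pl$echelon_manual)
  expected <- sum(published_baseline * (exp(beta) - 1)) + sum(acq)
  expect_equal(entry$high_total_difference, expected, tolerance = 1e-9)
  # the stapler-arm coefficients should be led by the drugs equation
  coefs <- tn[grepl("^stapler-arm", tn$parameter), ]
  expect_equal(coefs$parameter[1], "stapler-arm coefficient (drugs)")
})
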