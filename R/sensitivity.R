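# Total difference as an explicit function of the varied inputs.
td_components <- function(x) {
  beta <- stats::setNames(stapler_terms(x$equations)$estimate, COST_CATEGORIES)
  list(base = x$baseline, beta = beta,
       acq_p = acquisition_cost(x$powered_product),
       acq_c = acquisition_cost(x$comparator_product))
}

td_eval <- function(cmp) {
  sum(cmp$base * (exp(cmp$beta) - 1)) + sum(cmp$acq_p) - sum(cmp$acq_c)
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the base-case total cost difference with one parameter at
#' a time set to its lower and upper bound, all others at base case.
#' Stapler-arm coefficients vary over their 95% confidence intervals;
#' device unit prices and utilization means vary by ±`price_range` and
#' ±`count_range` (products with an acquisition override expose their
#' two override cells instead).  Entries are sorted by the width of the
#' induced swing, i.e. tornado order.
#'
#' @param x A fitted [cma()] object.
#' @param price_range,count_range Relative half-widths for prices and
#'   device counts (default ±20%).
#' @return A data.frame of class `cma_tornado` with columns `parameter`,
#'   `low_value`, `high_value`, `low_total_difference`,
#'   `high_total_difference`, `span`; the base-case difference is in
#'   `attr(, "base_difference")`.
#' @export
tornado <- function(x, price_range = 0.2, count_range = 0.2) {
  stopifnot(inherits(x, "cma"))
  cmp0 <- td_components(x)
  base_td <- td_eval(cmp0)
  st <- stapler_terms(x$equations)

  entries <- list()
  add <- function(parameter, lo_val, hi_val, modify) {
    c_lo <- modify(cmp0, lo_val)
    c_hi <- modify(cmp0, hi_val)
    entries[[length(entries) + 1L]] <<- data.frame(
      parameter = parameter, low_value = lo_val, high_value = hi_val,
      low_total_difference = td_eval(c_lo),
      high_total_difference = td_eval(c_hi))
  }

  for (i in seq_len(nrow(st))) {
    cc <- st$category[i]
    add(sprintf("stapler-arm coefficient (%s)", cc), st$ci_low[i], st$ci_high[i],
        function(cmp, v) { cmp$beta[[cc]] <- v; cmp })
  }
  acq_product <- function(role, product, field) {
    if (!is.null(product$acquisition_override)) {
      for (dev in c("stapler", "cartridge")) {
        v0 <- product$acquisition_override[[dev]]
        add(sprintf("%s %s acquisition cost (%s)", role, dev, product$name),
            v0 * (1 - price_range), v0 * (1 + price_range),
            function(cmp, v) { cmp[[field]][[dev]] <- v; cmp })
      }
      return(invisible())
    }
    specs <- list(
      c("stapler unit price", "stapler_unit_price", "mean_staplers", "stapler", price_range),
      c("cartridge unit price", "cartridge_unit_price", "mean_cartridges", "cartridge", price_range),
      c("mean staplers per episode", "stapler_unit_price", "mean_staplers", "stapler", count_range),
      c("mean cartridges per episode", "cartridge_unit_price", "mean_cartridges", "cartridge", count_range))
    for (k in c(1L, 2L)) {
      s <- specs[[k]]
      v0 <- product[[s[2L]]]
      m <- product[[s[3L]]]; dev <- s[4L]; rr <- as.numeric(s[5L])
      add(sprintf("%s %s (%s)", role, s[1L], product$name),
          v0 * (1 - rr), v0 * (1 + rr),
          function(cmp, v) { cmp[[field]][[dev]] <- m * v; cmp })
    }
    for (k in c(3L, 4L)) {
      s <- specs[[k]]
      price <- product[[s[2L]]]
      m0 <- product[[s[3L]]]; dev <- s[4L]; rr <- as.numeric(s[5L])
      add(sprintf("%s %s (%s)", role, s[1L], product$name),
          m0 * (1 - rr), m0 * (1 + rr),
          function(cmp, v) { cmp[[field]][[dev]] <- price * v; cmp })
    }
  }
  acq_product("powered", x$powered_product, "acq_p")
  acq_product("comparator", x$comparator_product, "acq_c")

  out <- do.call(rbind, entries)
  out$span <- abs(out$high_total_difference - out$low_total_difference)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_difference = base_td,
            class = c("cma_tornado", "data.frame"))
}

#' @export
print.cma_tornado <- function(x, ...) {
  cat("One-way sensitivity analysis (base-case difference ",
      fmt_cny(attr(x, "base_difference")), ")\n", sep = "")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Propagates the uncertainty of the stapler-arm coefficients through
#' the decision model.  Per iteration, each of the `n_patients` model
#' patients receives an independent draw of each category's cost
#' multiplier; per-patient scenario costs are averaged into one
#' total-difference draw per iteration (scheme `"patient"`).  Scheme
#' `"cohort"` draws each multiplier once per iteration instead, which
#' widens the output distribution by about `sqrt(n_patients)`.
#'
#' Two draw scales are available.  The default, `"cost"`, draws the
#' multiplier `exp(beta)` from a normal with SD
#' `(exp(ci_high) - exp(ci_low)) / 3.92`: it is mean-preserving, so the
#' PSA distribution is centred on the base-case difference.  `"log"`
#' draws `beta` itself from a normal (SD from the log-scale CI) and
#' exponentiates, i.e. lognormal multipliers; that displaces each
#' category mean by `exp(se^2/2)` and with it the PSA median.  Draws are
#' untruncated.  Only the stapler-arm coefficients are sampled:
#' in the calibrated model the scenario difference depends on no other
#' coefficient.
#'
#' Draw order is iteration-major within each category (category by
#' category, each as an `n_iterations` x `n_patients` matrix), so runs
#' are reproducible given the seed.
#'
#' @param x A fitted [cma()] object.
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param n_patients Model cohort size per iteration (default 388).
#' @param seed Integer RNG seed.
#' @param scheme `"patient"` or `"cohort"` sampling (see above).
#' @param draw_scale `"cost"` (mean-preserving, default) or `"log"`.
#' @param se_scale Multiplier on every SE (for continuity checks; 0
#'   collapses the PSA onto the base case).
#' @return An object of class `cma_psa` with the draw vector, median,
#'   2.5/97.5 percentiles, and `probability_saving` (share of draws
#'   below zero).
#' @export
psa <- function(x, n_iterations = 10000L, n_patients = 388L, seed = NULL,
                scheme = c("patient", "cohort"),
                draw_scale = c("cost", "log"), se_scale = 1) {
  stopifnot(inherits(x, "cma"), n_iterations >= 1L, n_patients >= 1L)
  scheme <- match.arg(scheme)
  draw_scale <- match.arg(draw_scale)
  if (!is.null(seed)) set.seed(seed)
  st <- stapler_terms(x$equations)
  if (anyNA(st$se))
    stop_named("PSA requires a finite CI-derived SE for every stapler-arm term")
  cmp <- td_components(x)
  npat <- if (scheme == "cohort") 1L else as.integer(n_patients)
  acq_diff <- sum(cmp$acq_p) - sum(cmp$acq_c)
  draws <- rep_len(acq_diff, n_iterations)
  for (i in seq_len(nrow(st))) {
    cc <- st$category[i]
    if (draw_scale == "cost") {
      m <- exp(st$estimate[i])
      s <- (exp(st$ci_high[i]) - exp(st$ci_low[i])) / (2 * stats::qnorm(0.975))
      f <- matrix(stats::rnorm(n_iterations * npat, m, s * se_scale),
                  nrow = n_iterations)
    } else {
      b <- matrix(stats::rnorm(n_iterations * npat, st$estimate[i],
                               st$se[i] * se_scale), nrow = n_iterations)
      f <- exp(b)
    }
    if (any(!is.finite(f)))
      stop_named("non-finite PSA draw for category '", cc, "'")
    fbar <- rowMeans(f)
    draws <- draws + cmp$base[[cc]] * (fbar - 1)
  }
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(draws = draws, n_iterations = as.integer(n_iterations),
                 n_patients = npat, seed = seed, scheme = scheme,
                 draw_scale = draw_scale,
                 base_difference = td_eval(cmp),
                 median = qs[2L], percentile_2_5 = qs[1L],
                 percentile_97_5 = qs[3L],
                 probability_saving = mean(draws < 0)),
            class = "cma_psa")
}

#' @export
print.cma_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis (%d iterations, %s scheme)\n",
              x$n_iterations, x$scheme))
  cat(sprintf("  median difference %s (95%% CrI %s to %s)\n",
              fmt_cny(x$median), fmt_cny(x$percentile_2_5),
              fmt_cny(x$percentile_97_5)))
  cat(sprintf("  probability that the powered scenario saves costs: %.1f%%\n",
              100 * x$probability_saving))
  invisible(x)
}

#' @export
summary.cma_psa <- function(object, ...) {
  data.frame(n_iterations = object$n_iterations,
             median = object$median,
             percentile_2_5 = object$percentile_2_5,
             percentile_97_5 = object$percentile_97_5,
             probability_saving = object$probability_saving,
             base_difference = object$base_difference)
}
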