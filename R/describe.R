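group_comparison <- function(variable, summary1, summary2, test, statistic, p) {
  data.frame(variable = variable, group1 = summary1, group2 = summary2,
             test = test, statistic = statistic, p_value = p,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance (two-sided); Welch's unequal
#' variance version is available behind `pooled = FALSE`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param pooled Use the pooled-variance statistic (default TRUE).
#' @param variable Label for the output row.
#' @return A one-row comparison data.frame (statistic, p-value,
#'   mean±SD summaries).
#' @export
pooled_t_test <- function(x, y, pooled = TRUE, variable = "continuous") {
  if (length(x) < 2L || length(y) < 2L)
    stop_named("t test requires at least 2 observations per sample")
  if (stats::var(x) + stats::var(y) == 0)
    stop_named("t test is degenerate: both samples have zero variance")
  ht <- stats::t.test(x, y, var.equal = pooled)
  group_comparison(variable, msd(x), msd(y),
                   if (pooled) "t (pooled)" else "t (Welch)",
                   unname(ht$statistic), ht$p.value)
}

msd <- function(x) sprintf("%.1f±%.1f", mean(x), stats::sd(x))

#' Chi-square test for a 2x2 proportion comparison
#'
#' Pearson chi-square without continuity correction (df = 1, two-sided).
#' When any expected cell count is below 5 the chi-square approximation
#' is invalid and Fisher's exact test is used instead; the returned
#' `test` label records which was applied.
#'
#' @param x1,n1 Successes and sample size in group 1.
#' @param x2,n2 Successes and sample size in group 2.
#' @param variable Label for the output row.
#' @return A one-row comparison data.frame.
#' @export
chisq_2x2 <- function(x1, n1, x2, n2, variable = "proportion") {
  counts <- c(x1, n1, x2, n2)
  if (any(counts < 0) || x1 > n1 || x2 > n2)
    stop_named("invalid 2x2 counts")
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_named("chi-square test is undefined: a margin of the 2x2 table is zero")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  s1 <- sprintf("%.1f%%", 100 * x1 / n1)
  s2 <- sprintf("%.1f%%", 100 * x2 / n2)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    return(group_comparison(variable, s1, s2, "Fisher exact", NA_real_,
                            ht$p.value))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  group_comparison(variable, s1, s2, "chi-square", unname(ht$statistic),
                   ht$p.value)
}

# Exact null distribution of the rank-sum of the first sample, with
# mid-ranks for ties: dynamic programme over subsets of size n1 of the
# doubled ranks (doubling keeps mid-ranks integral).  Returns
# P(W <= w) and P(W >= w).
rank_sum_exact_tail <- function(r2, n1, w2) {
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      idx <- seq_len(maxs + 1L - v)
      f[k + 1L, idx + v] <- f[k + 1L, idx + v] + f[k, idx]
    }
  }
  dist <- f[n1 + 1L, ]
  total <- sum(dist)
  sums <- seq_along(dist) - 1L
  c(p_le = sum(dist[sums <= w2]) / total,
    p_ge = sum(dist[sums >= w2]) / total)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties.  For combined sample
#' sizes up to 25 the exact permutation distribution of the rank sum is
#' enumerated (a dynamic programme over the tied rank multiset, so ties
#' are handled exactly); for larger samples the normal approximation
#' with tie correction is used.  The two-sided exact p-value is twice
#' the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default chooses by `length(x) + length(y) <= 25`.
#' @param variable Label for the output row.
#' @return A one-row comparison data.frame; `statistic` is the rank sum
#'   of `x`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, variable = "cost") {
  if (!length(x) || !length(y))
    stop_named("rank-sum test requires non-empty samples")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (is.null(exact)) exact <- n <= 25
  s1 <- sprintf("median %.4g", stats::median(x))
  s2 <- sprintf("median %.4g", stats::median(y))
  if (exact) {
    tails <- rank_sum_exact_tail(as.integer(round(2 * r)), n1,
                                 as.integer(round(2 * w)))
    p <- min(1, 2 * min(tails))
    return(group_comparison(variable, s1, s2, "Wilcoxon rank-sum (exact)", w, p))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0)
    return(group_comparison(variable, s1, s2,
                            "Wilcoxon rank-sum (normal approx.)", w, 1))
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  group_comparison(variable, s1, s2, "Wilcoxon rank-sum (normal approx.)", w, p)
}

#' Group-comparison summary of a cohort
#'
#' Builds the descriptive comparison of the two stapler groups: t tests
#' for continuous characteristics and device counts, chi-square (Fisher
#' fallback for sparse cells) for categorical characteristics, and
#' Wilcoxon rank-sum tests for the cost columns.
#'
#' @param records,costs Patient records and cost records.
#' @param groups The two group labels to compare (default powered vs
#'   manual).
#' @return A data.frame with one row per compared variable.
#' @export
summarize_cohort <- function(records, costs, groups = c("powered", "manual")) {
  g1 <- records$group == groups[1L]
  g2 <- records$group == groups[2L]
  if (!any(g1) || !any(g2))
    stop_named("both groups must be present in the records")
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  for (v in c("age", "bmi"))
    add(pooled_t_test(records[[v]][g1], records[[v]][g2], variable = v))

  cat_var <- function(flag, name) {
    tryCatch(add(chisq_2x2(sum(flag[g1]), sum(g1), sum(flag[g2]), sum(g2),
                           variable = name)),
             error = function(e) NULL)  # zero-margin rows are skipped
  }
  cat_var(records$sex == "male", "male")
  for (b in BMI_BAND_LABELS) cat_var(records$bmi_band == b, paste0("bmi ", b))
  for (f in c("residence", "insurance", "marital", "histology", "stage",
              "lobectomy_site"))
    for (lev in sort(unique(records[[f]])))
      cat_var(records[[f]] == lev, paste0(f, ": ", lev))
  for (f in grep("^(cm|abn)_", names(records), value = TRUE))
    cat_var(records[[f]], f)

  for (v in c("staplers_used", "cartridges_used"))
    add(pooled_t_test(records[[v]][g1], records[[v]][g2], variable = v))
  for (v in intersect(COST_COLS, names(costs)))
    add(rank_sum_test(costs[[v]][g1], costs[[v]][g2], variable = v))

  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- groups[1L]
  names(out)[names(out) == "group2"] <- groups[2L]
  rownames(out) <- NULL
  out
}
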